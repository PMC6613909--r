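#' Read a BED3/BED4 file of genomic intervals
#'
#' Reads whitespace-delimited BED with at least three columns. Coordinates
#' are kept in the BED convention used throughout the package: 0-based
#' half-open `[start, end)`. `track`, `browser` and `#` comment lines are
#' skipped.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`
#'   (`NA` where the file has no fourth column), one row per data line,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("track name=se", "chr1\t100\t200\tSE_1"), f)
#' read_bed(f)
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 3L)) {
    stop("BED parse error at line ", lineno[which(ncol < 3L)[1]],
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("BED parse error at line ", lineno[bad[1]],
         ": non-integer coordinates")
  }
  bad <- which(end <= start | start < 0L)
  if (length(bad) > 0L) {
    stop("BED parse error at line ", lineno[bad[1]],
         ": requires 0 <= start < end")
  }
  name <- ifelse(ncol >= 4L,
                 vapply(fields, function(x) if (length(x) >= 4L) x[[4L]] else NA_character_,
                        character(1)),
                 NA_character_)
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`; coordinates 0-based half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  lines <- paste(intervals$chrom, intervals$start, intervals$end, sep = "\t")
  if ("name" %in% names(intervals)) {
    named <- !is.na(intervals$name)
    lines[named] <- paste(lines[named], intervals$name[named], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-annotation table
#'
#' Tab-separated table with header columns `gene_id`, `symbol`, `chrom`,
#' `tss`, `strand`. The TSS is stored 0-based; convert 1-based dialects
#' before or at this boundary.
#'
#' @param path Path to the TSV.
#' @return data.frame with one row per gene.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gene_id", "symbol", "chrom", "tss", "strand")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("gene table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, required]
  tab$tss <- suppressWarnings(as.integer(tab$tss))
  if (nrow(tab) > 0L) {
    if (anyNA(tab$tss) || any(tab$tss < 0L)) {
      stop("gene table parse error: tss must be a non-negative integer")
    }
    if (!all(tab$strand %in% c("+", "-"))) {
      stop("gene table parse error: strand must be '+' or '-'")
    }
    dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
    if (length(dup) > 0L) {
      stop("duplicate gene_id: ", paste(dup, collapse = ", "))
    }
  }
  tab
}

#' Write a gene-annotation table
#' @param genes data.frame as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "symbol", "chrom", "tss", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an RBP catalog (one gene symbol per line)
#'
#' @param path Path to the catalog file.
#' @return Character vector of symbols (blank lines and `#` comments dropped).
#' @export
read_rbp_catalog <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

# rMATS JC-table column order (SE/A5SS/A3SS/RI dialect); MXE inserts the
# second exon pair after the target exon.
rmats_base_cols <- c(
  "ID", "GeneID", "geneSymbol", "chr", "strand",
  "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
  "downstreamES", "downstreamEE", "ID.1",
  "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
  "IncFormLen", "SkipFormLen", "PValue", "FDR",
  "IncLevel1", "IncLevel2", "IncLevelDifference"
)
rmats_mxe_cols <- append(rmats_base_cols,
                         c("X2ndExonStart_0base", "X2ndExonEnd"), after = 7L)

parse_count_field <- function(x, field, what = "count") {
  parts <- strsplit(trimws(x), ",", fixed = TRUE)
  lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (what == "count") {
      if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
        stop("rMATS parse error in ", field, ", row ", i,
             ": counts must be non-negative integers")
      }
      as.integer(v)
    } else {
      # PSI field: "NA" entries become missing
      raw <- parts[[i]]
      v[raw == "NA"] <- NA_real_
      if (any(is.na(v) & raw != "NA")) {
        stop("rMATS parse error in ", field, ", row ", i,
             ": unparseable inclusion level")
      }
      if (any(v < 0 | v > 1, na.rm = TRUE)) {
        stop("rMATS parse error in ", field, ", row ", i,
             ": inclusion levels must lie in [0,1]")
      }
      v
    }
  })
}

#' Read an rMATS junction-count (JC) table
#'
#' Parses the tab-separated `*.MATS.JC.txt` dialect of rMATS v3.2.5.
#' Per-replicate fields (junction counts, inclusion levels) are comma-joined
#' in the file and returned as list columns of per-replicate vectors;
#' `"NA"` inclusion levels become missing values. The `IncLevelDifference`
#' column is kept as `delta_psi` (condition 1 minus condition 2).
#'
#' @param path Path to the table.
#' @param event_type One of `"SE"`, `"MXE"`, `"A5SS"`, `"A3SS"`, `"RI"`.
#' @return data.frame with scalar columns (`event_type`, `gene_id`, `symbol`,
#'   `chrom`, `strand`, exon coordinates, `inc_form_len`, `skip_form_len`,
#'   `pvalue`, `fdr`, `delta_psi`) and list columns `ijc_1`, `sjc_1`,
#'   `ijc_2`, `sjc_2`, `inc_level_1`, `inc_level_2`.
#' @export
read_rmats_table <- function(path, event_type = c("SE", "MXE", "A5SS", "A3SS", "RI")) {
  event_type <- match.arg(event_type)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = TRUE)
  expected <- if (event_type == "MXE") rmats_mxe_cols else rmats_base_cols
  if (!identical(ncol(tab), length(expected))) {
    stop("rMATS schema error: expected ", length(expected),
         " columns for ", event_type, " table, found ", ncol(tab))
  }
  names(tab) <- expected
  n <- nrow(tab)
  int_col <- function(col) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (n > 0L && anyNA(v)) stop("rMATS parse error: non-integer ", col)
    v
  }
  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (n > 0L && anyNA(v)) stop("rMATS parse error: non-numeric ", col)
    v
  }
  out <- data.frame(
    event_type = rep(event_type, n),
    gene_id = tab$GeneID, symbol = tab$geneSymbol,
    chrom = tab$chr, strand = tab$strand,
    target_start = int_col("exonStart_0base"), target_end = int_col("exonEnd"),
    upstream_start = int_col("upstreamES"), upstream_end = int_col("upstreamEE"),
    downstream_start = int_col("downstreamES"), downstream_end = int_col("downstreamEE"),
    inc_form_len = int_col("IncFormLen"), skip_form_len = int_col("SkipFormLen"),
    pvalue = num_col("PValue"), fdr = num_col("FDR"),
    delta_psi = num_col("IncLevelDifference"),
    stringsAsFactors = FALSE
  )
  if (event_type == "MXE") {
    out$second_start <- int_col("X2ndExonStart_0base")
    out$second_end <- int_col("X2ndExonEnd")
  }
  out$ijc_1 <- parse_count_field(tab$IJC_SAMPLE_1, "IJC_SAMPLE_1")
  out$sjc_1 <- parse_count_field(tab$SJC_SAMPLE_1, "SJC_SAMPLE_1")
  out$ijc_2 <- parse_count_field(tab$IJC_SAMPLE_2, "IJC_SAMPLE_2")
  out$sjc_2 <- parse_count_field(tab$SJC_SAMPLE_2, "SJC_SAMPLE_2")
  out$inc_level_1 <- parse_count_field(tab$IncLevel1, "IncLevel1", what = "psi")
  out$inc_level_2 <- parse_count_field(tab$IncLevel2, "IncLevel2", what = "psi")
  nrep <- function(col) vapply(out[[col]], length, integer(1))
  if (n > 0L) {
    reps <- cbind(nrep("ijc_1"), nrep("sjc_1"), nrep("inc_level_1"))
    if (any(reps != reps[, 1L])) {
      stop("rMATS parse error: replicate counts differ across fields")
    }
  }
  out
}

#' Write an rMATS-dialect junction-count table
#'
#' Inverse of [read_rmats_table()]; used mainly to serialize synthetic
#' tables in the exact file dialect the readers expect.
#'
#' @param events data.frame as returned by [read_rmats_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmats_table <- function(events, path) {
  join <- function(col, digits = NA) {
    vapply(events[[col]], function(v) {
      if (!is.na(digits)) v <- round(v, digits)
      paste(ifelse(is.na(v), "NA", as.character(v)), collapse = ",")
    }, character(1))
  }
  mxe <- identical(events$event_type[1], "MXE")
  tab <- data.frame(
    ID = seq_len(nrow(events)), GeneID = events$gene_id,
    geneSymbol = events$symbol, chr = events$chrom, strand = events$strand,
    exonStart_0base = events$target_start, exonEnd = events$target_end,
    stringsAsFactors = FALSE
  )
  if (mxe) {
    tab$X2ndExonStart_0base <- events$second_start
    tab$X2ndExonEnd <- events$second_end
  }
  tab <- cbind(tab, data.frame(
    upstreamES = events$upstream_start, upstreamEE = events$upstream_end,
    downstreamES = events$downstream_start, downstreamEE = events$downstream_end,
    ID.1 = seq_len(nrow(events)),
    IJC_SAMPLE_1 = join("ijc_1"), SJC_SAMPLE_1 = join("sjc_1"),
    IJC_SAMPLE_2 = join("ijc_2"), SJC_SAMPLE_2 = join("sjc_2"),
    IncFormLen = events$inc_form_len, SkipFormLen = events$skip_form_len,
    PValue = events$pvalue, FDR = events$fdr,
    IncLevel1 = join("inc_level_1", digits = 3),
    IncLevel2 = join("inc_level_2", digits = 3),
    IncLevelDifference = events$delta_psi,
    stringsAsFactors = FALSE
  ))
  header <- if (mxe) rmats_mxe_cols else rmats_base_cols
  header[header == "ID.1"] <- "ID"
  header[header == "X2ndExonStart_0base"] <- "2ndExonStart_0base"
  header[header == "X2ndExonEnd"] <- "2ndExonEnd"
  writeLines(paste(header, collapse = "\t"), path)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read FASTA sequences as a named character vector
#'
#' Sequences are normalized to upper case DNA (U becomes T). Wrapped and
#' unwrapped records are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector over the alphabet `A,C,G,T,N`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("illegal character in sequence '", ids[i], "' at position ", bad[i])
  }
  names(seqs) <- ids
  seqs
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
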