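#' Configuration for super-enhancer/gene association
#'
#' Holds the parameters of the two association rules: the GREAT-style
#' basal-plus-extension regulatory domain (5 kb upstream / 1 kb downstream
#' of the TSS, extended up to 1 Mb toward neighboring genes) and the
#' stricter dbSUPER-style closest-TSS rule within a 50 kb window.
#'
#' @param basal_up Basal domain extent upstream of the TSS, bp.
#' @param basal_down Basal domain extent downstream of the TSS, bp.
#' @param max_extension Maximum extension from the TSS in each direction, bp.
#' @param proximal_window Maximum TSS-to-enhancer distance for the
#'   closest-TSS rule, bp.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(basal_up = 5000L, basal_down = 1000L,
                          max_extension = 1000000L, proximal_window = 50000L) {
  stopifnot(basal_up > 0, basal_down > 0, max_extension > 0,
            proximal_window > 0,
            max_extension >= basal_up, max_extension >= basal_down)
  structure(list(basal_up = as.numeric(basal_up),
                 basal_down = as.numeric(basal_down),
                 max_extension = as.numeric(max_extension),
                 proximal_window = as.numeric(proximal_window)),
            class = "screen_config")
}

#' Strand-aware basal regulatory domain around a TSS
#'
#' For a + strand gene the basal domain is `[tss - basal_up, tss + basal_down)`;
#' for a - strand gene the window is mirrored. Coordinates are clipped at 0.
#'
#' @param genes data.frame with columns `tss` and `strand` (vectorized).
#' @param cfg A [screen_config()].
#' @return data.frame with columns `start`, `end` (0-based half-open).
#' @export
basal_domain <- function(genes, cfg = screen_config()) {
  stopifnot(all(genes$strand %in% c("+", "-")), all(genes$tss >= 0))
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - cfg$basal_up, genes$tss - cfg$basal_down)
  end <- ifelse(plus, genes$tss + cfg$basal_down, genes$tss + cfg$basal_up)
  data.frame(start = pmax(start, 0), end = end)
}

#' Basal-plus-extension regulatory domains
#'
#' Each gene's basal domain is extended on each side to the nearer of the
#' closest other gene's basal-domain boundary on that side or
#' `tss +/- max_extension`, never shrinking below the gene's own basal
#' domain, and clipped to the chromosome. Extension stops at neighbor basal
#' *boundaries* (GREAT v3 semantics), irrespective of the neighbor's strand.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`
#'   (one TSS per gene).
#' @param cfg A [screen_config()].
#' @param chrom_sizes Named numeric vector of chromosome lengths, bp.
#' @return data.frame with `gene_id`, `chrom`, `basal_start`, `basal_end`,
#'   `ext_start`, `ext_end`.
#' @export
extend_domains <- function(genes, cfg = screen_config(), chrom_sizes) {
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  basal <- basal_domain(genes, cfg)
  n <- nrow(genes)
  ext_start <- ext_end <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i])
    others <- setdiff(same, i)
    bs <- basal$start[i]; be <- basal$end[i]
    # nearest other basal boundary to the right of own basal end
    right_limit <- Inf
    left_limit <- -Inf
    if (length(others) > 0L) {
      os <- basal$start[others]; oe <- basal$end[others]
      right_block <- oe > be            # occupies space right of own basal
      if (any(right_block)) {
        right_limit <- min(pmax(os[right_block], be))
      }
      left_block <- os < bs
      if (any(left_block)) {
        left_limit <- max(pmin(oe[left_block], bs))
      }
    }
    ext_end[i] <- max(be, min(genes$tss[i] + cfg$max_extension, right_limit))
    ext_start[i] <- min(bs, max(genes$tss[i] - cfg$max_extension, left_limit))
    csize <- chrom_sizes[[genes$chrom[i]]]
    ext_start[i] <- max(ext_start[i], 0)
    ext_end[i] <- min(ext_end[i], csize)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             basal_start = basal$start, basal_end = pmin(basal$end, chrom_sizes[genes$chrom]),
             ext_start = ext_start, ext_end = ext_end,
             stringsAsFactors = FALSE)
}

#' Associate super-enhancers with genes by regulatory-domain overlap
#'
#' A super-enhancer is associated with every gene whose extended regulatory
#' domain overlaps it by at least 1 bp; one enhancer may map to several
#' genes.
#'
#' @param ses data.frame with `chrom`, `start`, `end`, `se_id`.
#' @param domains Output of [extend_domains()].
#' @return Named list mapping `gene_id` to a character vector of `se_id`s;
#'   genes with no associated enhancer are absent.
#' @export
associate_by_domain <- function(ses, domains) {
  if (nrow(ses) == 0L || nrow(domains) == 0L) return(list())
  se_gr <- GenomicRanges::GRanges(
    ses$chrom, IRanges::IRanges(start = ses$start + 1L, end = ses$end))
  dom_gr <- GenomicRanges::GRanges(
    domains$chrom,
    IRanges::IRanges(start = domains$ext_start + 1L, end = domains$ext_end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(dom_gr, se_gr, minoverlap = 1L))
  if (length(hits) == 0L) return(list())
  split(ses$se_id[S4Vectors::subjectHits(hits)],
        domains$gene_id[S4Vectors::queryHits(hits)])
}

# distance from a TSS (0-based position) to a 0-based half-open interval:
# 0 when the TSS lies inside, otherwise the gap to the nearest end.
tss_interval_distance <- function(tss, start, end) {
  ifelse(tss < start, start - tss,
         ifelse(tss >= end, tss - (end - 1), 0))
}

#' Associate super-enhancers with their closest TSS within a window
#'
#' Each enhancer is assigned to the single gene whose TSS is nearest to the
#' enhancer interval (distance 0 when the TSS falls inside it), provided the
#' distance does not exceed `proximal_window`; more distant enhancers are
#' dropped. Ties break toward the lexicographically smaller `gene_id`.
#'
#' @inheritParams associate_by_domain
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @param cfg A [screen_config()].
#' @return Named list mapping `gene_id` to a character vector of `se_id`s.
#' @export
associate_by_proximity <- function(ses, genes, cfg = screen_config()) {
  if (nrow(ses) == 0L || nrow(genes) == 0L) return(list())
  assigned_gene <- character(0)
  assigned_se <- character(0)
  for (i in seq_len(nrow(ses))) {
    cand <- which(genes$chrom == ses$chrom[i])
    if (length(cand) == 0L) next
    d <- tss_interval_distance(genes$tss[cand], ses$start[i], ses$end[i])
    ok <- d <= cfg$proximal_window
    if (!any(ok)) next
    cand <- cand[ok]; d <- d[ok]
    best <- cand[d == min(d)]
    best <- best[order(genes$gene_id[best])][1]
    assigned_gene <- c(assigned_gene, genes$gene_id[best])
    assigned_se <- c(assigned_se, ses$se_id[i])
  }
  if (length(assigned_se) == 0L) return(list())
  split(assigned_se, assigned_gene)
}

#' Turn an association mapping into a gene-symbol set
#'
#' @param assoc Named list from [associate_by_domain()] or
#'   [associate_by_proximity()] (names are `gene_id`s).
#' @param genes Gene table with `gene_id` and `symbol`.
#' @return Character vector of upper-cased symbols of associated genes.
#' @export
associated_symbols <- function(assoc, genes) {
  ids <- names(assoc)
  unique(toupper(genes$symbol[match(ids, genes$gene_id)]))
}
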