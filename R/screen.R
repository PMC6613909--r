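#' Candidate master-regulator screen over tissue super-enhancer gene sets
#'
#' Intersects the super-enhancer-associated gene sets of the target tissues,
#' removes genes also associated in the outlier tissue, and intersects the
#' remainder with a catalog of RNA-binding proteins. All matching is on
#' upper-cased gene symbols.
#'
#' @param target_sets Named list of character vectors: SE-associated gene
#'   symbols per target tissue (at least one tissue).
#' @param outlier_set Character vector of symbols associated in the outlier
#'   tissue.
#' @param rbp_catalog Character vector of RBP gene symbols (non-empty).
#' @return A list of class `candidate_report` with elements
#'   `per_tissue_sets`, `target_intersection`, `outlier_excluded`,
#'   `rbp_candidates`.
#' @export
candidate_screen <- function(target_sets, outlier_set, rbp_catalog) {
  stopifnot(length(target_sets) >= 1L)
  if (length(rbp_catalog) == 0L) {
    stop("empty RBP catalog: the screen would be degenerate")
  }
  target_sets <- lapply(target_sets, function(s) unique(toupper(s)))
  outlier_set <- unique(toupper(outlier_set))
  rbp_catalog <- unique(toupper(rbp_catalog))
  inter <- Reduce(intersect, target_sets)
  excl <- setdiff(inter, outlier_set)
  cand <- intersect(excl, rbp_catalog)
  structure(list(per_tissue_sets = target_sets,
                 target_intersection = sort(inter),
                 outlier_excluded = sort(excl),
                 rbp_candidates = sort(cand)),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Super-enhancer RBP screen\n")
  cat("  target tissues:        ", length(x$per_tissue_sets), "\n")
  cat("  target intersection:   ", length(x$target_intersection), "genes\n")
  cat("  after outlier removal: ", length(x$outlier_excluded), "genes\n")
  cat("  RBP candidates:        ",
      if (length(x$rbp_candidates)) paste(x$rbp_candidates, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Consensus between two candidate sets
#'
#' Intersection of the candidates from two association rules (for example
#' the regulatory-domain rule and the closest-TSS rule), matched on
#' upper-cased symbols.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @return Sorted character vector of shared symbols.
#' @export
consensus_candidates <- function(set_a, set_b) {
  sort(intersect(unique(toupper(set_a)), unique(toupper(set_b))))
}

#' Rank candidates by expression, keeping those down-regulated
#'
#' Keeps candidates whose mean abundance in the high condition exceeds
#' `min_fold` times the mean in the low condition (with the default
#' `min_fold = 1`, any decrease from `cond_high` to `cond_low` counts),
#' and ranks them by descending mean abundance in `cond_high`. The intended
#' use is tissue (high) versus cell culture (low): the top-ranked candidate
#' is the most highly expressed of the down-regulated ones.
#'
#' @param candidates Character vector of gene symbols.
#' @param values Numeric matrix, genes in rows (rownames are symbols),
#'   samples in columns.
#' @param conditions Character vector of condition tags, one per column.
#' @param cond_high,cond_low Condition tags to compare.
#' @param min_fold Minimum `mean(high)/mean(low)` ratio to keep a candidate.
#' @return data.frame with `symbol`, `abundance` (mean in `cond_high`) and
#'   `fold_change` (`mean(high)/mean(low)`, `Inf` when the low mean is 0),
#'   sorted by descending abundance. Candidates absent from `values` are
#'   attached as the character attribute `missing`.
#' @export
rank_candidates <- function(candidates, values, conditions,
                            cond_high, cond_low, min_fold = 1) {
  stopifnot(length(conditions) == ncol(values))
  if (!cond_high %in% conditions) stop("unknown condition tag: ", cond_high)
  if (!cond_low %in% conditions) stop("unknown condition tag: ", cond_low)
  idx <- match(toupper(candidates), toupper(rownames(values)))
  missing <- candidates[is.na(idx)]
  present <- candidates[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  hi <- values[idx, conditions == cond_high, drop = FALSE]
  lo <- values[idx, conditions == cond_low, drop = FALSE]
  mean_hi <- rowMeans(hi)
  mean_lo <- rowMeans(lo)
  fold <- ifelse(mean_lo == 0, Inf, mean_hi / mean_lo)
  keep <- mean_hi > min_fold * mean_lo
  out <- data.frame(symbol = present[keep],
                    abundance = unname(mean_hi[keep]),
                    fold_change = unname(fold[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}

#' Normalize expression values by the geometric mean of housekeepers
#'
#' Divides each target value by the geometric mean of the housekeeper
#' values measured in the same sample, the usual qRT-PCR normalization
#' with two or more housekeeping genes.
#'
#' @param values Numeric vector (one sample) or matrix (genes x samples)
#'   of target abundances.
#' @param housekeepers Numeric vector (one sample) or matrix
#'   (housekeepers x samples) of strictly positive housekeeper abundances.
#' @return Normalized values with the shape of `values`.
#' @export
relative_expression <- function(values, housekeepers) {
  hk <- if (is.matrix(housekeepers)) housekeepers else
    matrix(housekeepers, ncol = 1)
  if (any(hk <= 0)) stop("housekeeper values must be strictly positive")
  geo <- exp(colMeans(log(hk)))
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(geo))
    sweep(values, 2, geo, "/")
  } else {
    stopifnot(length(geo) == 1L)
    values / geo
  }
}
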