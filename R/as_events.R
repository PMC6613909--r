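#' Filter thresholds for alternative-splicing events
#'
#' Defaults follow common rMATS post-processing practice: events are kept
#' for any analysis only when total junction reads exceed `min_total_count`
#' across replicates in at least one condition; significant events
#' additionally need `fdr < fdr_sig` and `|delta PSI| >= dpsi_sig`;
#' background (unregulated) events need `fdr > fdr_bg` and
#' `|delta PSI| < dpsi_bg`.
#'
#' @param min_total_count Total read-count threshold (reads).
#' @param fdr_sig FDR threshold for significant events.
#' @param dpsi_sig Minimum |delta PSI| for significant events (PSI units).
#' @param fdr_bg Minimum FDR for background events.
#' @param dpsi_bg Maximum |delta PSI| for background events.
#' @return A list of class `event_filter_config`.
#' @export
event_filter_config <- function(min_total_count = 50, fdr_sig = 0.05,
                                dpsi_sig = 0.10, fdr_bg = 0.10,
                                dpsi_bg = 0.05) {
  stopifnot(min_total_count >= 0, fdr_sig > 0, fdr_sig <= 1,
            fdr_bg >= 0, fdr_bg <= 1, dpsi_sig > 0, dpsi_sig <= 1,
            dpsi_bg >= 0, dpsi_bg < dpsi_sig)
  structure(list(min_total_count = min_total_count, fdr_sig = fdr_sig,
                 dpsi_sig = dpsi_sig, fdr_bg = fdr_bg, dpsi_bg = dpsi_bg),
            class = "event_filter_config")
}

#' Percent spliced in from junction counts
#'
#' `PSI = (ijc/inc_form_len) / (ijc/inc_form_len + sjc/skip_form_len)`,
#' the rMATS effective-length-normalized inclusion level. Both counts zero
#' gives a missing value.
#'
#' @param ijc,sjc Inclusion/skipping junction read counts (vectorized).
#' @param inc_form_len,skip_form_len Effective junction lengths, nt.
#' @return Numeric vector of PSI values in `[0,1]` (`NA` where undefined).
#' @export
compute_psi <- function(ijc, sjc, inc_form_len = 2, skip_form_len = 1) {
  if (any(ijc < 0) || any(sjc < 0)) stop("junction counts must be >= 0")
  stopifnot(all(inc_form_len > 0), all(skip_form_len > 0))
  inc <- ijc / inc_form_len
  skp <- sjc / skip_form_len
  ifelse(inc + skp == 0, NA_real_, inc / (inc + skp))
}

event_total_counts_pass <- function(events, cfg) {
  tot1 <- vapply(seq_len(nrow(events)),
                 function(i) sum(events$ijc_1[[i]]) + sum(events$sjc_1[[i]]),
                 numeric(1))
  tot2 <- vapply(seq_len(nrow(events)),
                 function(i) sum(events$ijc_2[[i]]) + sum(events$sjc_2[[i]]),
                 numeric(1))
  tot1 > cfg$min_total_count | tot2 > cfg$min_total_count
}

#' Significant (regulated) events
#'
#' Keeps events passing the read-count filter with `fdr < fdr_sig` and
#' `|delta_psi| >= dpsi_sig`.
#'
#' @param events data.frame from [read_rmats_table()].
#' @param cfg An [event_filter_config()].
#' @return Filtered data.frame.
#' @export
filter_significant <- function(events, cfg = event_filter_config()) {
  if (nrow(events) == 0L) return(events)
  keep <- event_total_counts_pass(events, cfg) &
    events$fdr < cfg$fdr_sig & abs(events$delta_psi) >= cfg$dpsi_sig
  events[keep, , drop = FALSE]
}

#' Background (unregulated) events
#'
#' Keeps events passing the read-count filter with `fdr > fdr_bg` and
#' `|delta_psi| < dpsi_bg`.
#'
#' @inheritParams filter_significant
#' @return Filtered data.frame.
#' @export
filter_background <- function(events, cfg = event_filter_config()) {
  if (nrow(events) == 0L) return(events)
  keep <- event_total_counts_pass(events, cfg) &
    events$fdr > cfg$fdr_bg & abs(events$delta_psi) < cfg$dpsi_bg
  events[keep, , drop = FALSE]
}

#' Reproducible unique event identifiers
#'
#' Builds a deterministic ID from the event type, gene symbol, chromosome,
#' strand and the coordinates of the regulated and flanking exons
#' (`TYPE|symbol|chrom:strand|target|upstream|downstream`, MXE appending
#' its second exon pair), so that the same event found in different
#' comparisons gets the same ID.
#'
#' @param events data.frame from [read_rmats_table()].
#' @return Character vector of IDs, one per event.
#' @export
event_uid <- function(events) {
  coords <- c("target_start", "target_end", "upstream_start", "upstream_end",
              "downstream_start", "downstream_end")
  if (nrow(events) > 0L && anyNA(events[, coords])) {
    stop("missing exon coordinates; cannot build unique event IDs")
  }
  uid <- sprintf("%s|%s|%s:%s|%d-%d|%d-%d|%d-%d",
                 events$event_type, events$symbol, events$chrom, events$strand,
                 events$target_start, events$target_end,
                 events$upstream_start, events$upstream_end,
                 events$downstream_start, events$downstream_end)
  mxe <- events$event_type == "MXE"
  if (any(mxe)) {
    uid[mxe] <- sprintf("%s|%d-%d", uid[mxe],
                        events$second_start[mxe], events$second_end[mxe])
  }
  uid
}

#' Overlap event sets by unique ID (Venn partition)
#'
#' Matches events across named sets by [event_uid()] and counts every
#' region of the Venn partition. For pairs of sets the matched events carry
#' the per-set delta PSI (condition 1 minus condition 2, per each
#' comparison's own condition order) and a sign-concordance flag.
#'
#' @param sets Named list (length >= 2) of event data.frames.
#' @return A list with `counts` (named integer vector; names are
#'   `+`/`-`-patterns over the set names, e.g. `A&B` for events in both),
#'   `pairs` (for each pair of sets, a data.frame of shared `uid`,
#'   `dpsi_<name>` columns and `concordant`), and `uids` (per-set ID lists).
#' @export
overlap_events <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  uids <- lapply(sets, function(ev) {
    u <- event_uid(ev)
    dup <- unique(u[duplicated(u)])
    if (length(dup) > 0L) {
      stop("duplicate event uid within one set: ", dup[1])
    }
    u
  })
  all_uids <- unique(unlist(uids))
  member <- vapply(uids, function(u) all_uids %in% u,
                   logical(length(all_uids)))
  member <- matrix(member, nrow = length(all_uids),
                   dimnames = list(all_uids, names(sets)))
  pattern <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  counts <- table(pattern)
  counts <- stats::setNames(as.integer(counts), names(counts))
  pairs <- list()
  nm <- names(sets)
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i >= j) next
      shared <- intersect(uids[[i]], uids[[j]])
      da <- sets[[i]]$delta_psi[match(shared, uids[[i]])]
      db <- sets[[j]]$delta_psi[match(shared, uids[[j]])]
      pairs[[paste(nm[i], nm[j], sep = "&")]] <-
        stats::setNames(
          data.frame(uid = shared, a = da, b = db,
                     concordant = sign(da) == sign(db),
                     stringsAsFactors = FALSE),
          c("uid", paste0("dpsi_", nm[i]), paste0("dpsi_", nm[j]),
            "concordant"))
    }
  }
  list(counts = counts, pairs = pairs, uids = uids)
}

#' Pearson correlation of delta PSI between two comparisons
#'
#' @param dpsi_a,dpsi_b Numeric vectors of delta PSI values in `[-1,1]`,
#'   matched by event (length >= 3); pairs with a missing value are dropped.
#' @return data.frame with `n`, `r`, `r2`, `slope`, `intercept`, `p`.
#' @export
delta_psi_correlation <- function(dpsi_a, dpsi_b) {
  stopifnot(length(dpsi_a) == length(dpsi_b))
  ok <- !is.na(dpsi_a) & !is.na(dpsi_b)
  x <- dpsi_a[ok]; y <- dpsi_b[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in delta PSI; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  data.frame(n = length(x), r = unname(ct$estimate),
             r2 = unname(ct$estimate)^2,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             p = ct$p.value)
}

#' Z-scored hierarchical clustering of a PSI matrix
#'
#' Rows (events) are standardized to mean 0, sd 1; constant rows are left
#' at 0 and flagged rather than standardized. Rows and columns are then
#' clustered agglomeratively (Euclidean distance, complete linkage by
#' default).
#'
#' @param mat Numeric matrix, events x samples (>= 2 of each). Missing
#'   values are imputed with the row mean before standardization; all-`NA`
#'   rows are an error.
#' @param distance Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list of class `psi_clustering` with `row_order`, `col_order`,
#'   `z_matrix`, `row_hclust`, `col_hclust`, `constant_rows`.
#' @export
cluster_psi <- function(mat, distance = "euclidean", linkage = "complete") {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, ncol(mat) >= 2L)
  all_na <- apply(mat, 1L, function(r) all(is.na(r)))
  if (any(all_na)) stop("row(s) with no observed PSI: ",
                        paste(which(all_na), collapse = ", "))
  for (i in seq_len(nrow(mat))) {
    miss <- is.na(mat[i, ])
    if (any(miss)) mat[i, miss] <- mean(mat[i, ], na.rm = TRUE)
  }
  sds <- apply(mat, 1L, stats::sd)
  constant <- sds == 0
  z <- mat
  z[!constant, ] <- t(scale(t(mat[!constant, , drop = FALSE])))
  z[constant, ] <- 0
  row_hc <- stats::hclust(stats::dist(z, method = distance), method = linkage)
  col_hc <- stats::hclust(stats::dist(t(z), method = distance), method = linkage)
  structure(list(row_order = row_hc$order, col_order = col_hc$order,
                 z_matrix = z, row_hclust = row_hc, col_hclust = col_hc,
                 constant_rows = which(constant)),
            class = "psi_clustering")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a thin validated wrapper around
#' [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in `[0,1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
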