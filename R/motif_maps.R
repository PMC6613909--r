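#' Spacer-constrained dimeric motif specification
#'
#' The default describes the optimal binding element of an RBPMS dimer:
#' two CAC trinucleotides separated by a 1-12 nt spacer (CACN1-12CAC).
#'
#' @param core Core motif string over `A,C,G,T`.
#' @param spacer_min,spacer_max Allowed spacer lengths between the two core
#'   occurrences, nt.
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(core = "CAC", spacer_min = 1L, spacer_max = 12L) {
  stopifnot(nchar(core) > 0, grepl("^[ACGT]+$", core),
            spacer_min > 0, spacer_min <= spacer_max)
  structure(list(core = core, spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max)),
            class = "motif_spec")
}

#' Configuration for motif enrichment and RNA maps
#'
#' @param flank_len Intron flank length scanned on each side of the exon, nt.
#' @param exon_scan_len Exon length scanned (splice-site-anchored halves
#'   when the exon is longer), nt.
#' @param window Sliding-window width for RNA maps, nt (odd).
#' @param n_perm_enrich Permutations for region-thirds enrichment.
#' @param n_perm_map Permutations for RNA-map significance.
#' @param bg_downsample Background size for RNA maps (events).
#' @param alpha Significance level.
#' @param seed RNG seed used for permutations and downsampling.
#' @return A list of class `motif_map_config`.
#' @export
motif_map_config <- function(flank_len = 250L, exon_scan_len = 135L,
                             window = 31L, n_perm_enrich = 50000L,
                             n_perm_map = 1000L, bg_downsample = 2000L,
                             alpha = 0.05, seed = 1L) {
  stopifnot(flank_len > 0, exon_scan_len > 0, window > 0, window %% 2 == 1,
            n_perm_enrich > 0, n_perm_map > 0, bg_downsample > 0,
            alpha > 0, alpha < 1)
  structure(list(flank_len = as.integer(flank_len),
                 exon_scan_len = as.integer(exon_scan_len),
                 window = as.integer(window),
                 n_perm_enrich = as.integer(n_perm_enrich),
                 n_perm_map = as.integer(n_perm_map),
                 bg_downsample = as.integer(bg_downsample),
                 alpha = alpha, seed = as.integer(seed)),
            class = "motif_map_config")
}

#' Scan a sequence for spacer-constrained motif dimers
#'
#' A match starts at every position where the core occurs and occurs again
#' after a spacer of `spacer_min` to `spacer_max` nt; for each start the
#' smallest qualifying spacer is recorded, so every start yields at most
#' one match. Matches at distinct starts may overlap. `N` never matches.
#'
#' @param seq A single sequence string, upper-case DNA (T, not U).
#' @param spec A [motif_spec()].
#' @return data.frame with 1-based inclusive `start`, `end` and `spacer`
#'   columns, ordered by `start`.
#' @examples
#' scan_motif("CACACAC")    # one match at 1, spacer 1
#' scan_motif("CACCAC")     # none: a spacer of at least 1 nt is required
#' @export
scan_motif <- function(seq, spec = motif_spec()) {
  empty <- data.frame(start = integer(), end = integer(), spacer = integer())
  L <- nchar(spec$core)
  n <- nchar(seq)
  if (n < 2L * L + spec$spacer_min) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  core <- strsplit(spec$core, "", fixed = TRUE)[[1]]
  nstart <- n - L + 1L
  ok <- rep(TRUE, nstart)
  for (j in seq_len(L)) {
    ok <- ok & (chars[seq_len(nstart) + j - 1L] == core[j])
  }
  is_core <- c(ok, rep(FALSE, L - 1L))   # padded to length n
  hits <- which(ok)
  if (length(hits) == 0L) return(empty)
  spacer <- rep(NA_integer_, length(hits))
  for (s in spec$spacer_min:spec$spacer_max) {
    second <- hits + L + s
    found <- second <= n & is_core[pmin(second, n)]
    spacer[is.na(spacer) & found] <- s
  }
  keep <- !is.na(spacer)
  data.frame(start = hits[keep],
             end = hits[keep] + 2L * L + spacer[keep] - 1L,
             spacer = spacer[keep])
}

# Exon scan region: splice-site-anchored halves of length ceil(k/2) and
# floor(k/2) when the exon exceeds exon_scan_len, otherwise the whole exon
# split at its midpoint. Returns the two pieces plus the axis offsets of
# their first positions within the exon segment of the composite axis.
exon_scan_pieces <- function(exon, exon_scan_len) {
  len <- nchar(exon)
  left_target <- ceiling(exon_scan_len / 2)
  right_target <- floor(exon_scan_len / 2)
  if (len >= exon_scan_len) {
    left <- substr(exon, 1L, left_target)
    right <- substr(exon, len - right_target + 1L, len)
  } else {
    left <- substr(exon, 1L, ceiling(len / 2))
    right <- substr(exon, ceiling(len / 2) + 1L, len)
  }
  list(left = left, right = right,
       left_offset = 0L,
       right_offset = exon_scan_len - nchar(right))
}

region_names <- function() {
  as.vector(outer(c("first", "middle", "last"),
                  c("upstream", "exon", "downstream"),
                  function(t, r) paste(r, t, sep = "_")))
}

# thirds boundaries of a region of length len: first two thirds of length
# len %/% 3, remainder to the last third
thirds_lengths <- function(len) {
  base <- len %/% 3L
  c(base, base, len - 2L * base)
}

count_in_thirds <- function(starts, len) {
  tl <- thirds_lengths(len)
  b1 <- tl[1]; b2 <- tl[1] + tl[2]
  c(sum(starts <= b1), sum(starts > b1 & starts <= b2), sum(starts > b2))
}

#' Per-event motif counts and densities by region thirds
#'
#' Splits the scanned upstream flank, exon region and downstream flank of
#' each event into thirds by length (remainder to the last third), counts
#' motif matches whose start lies in each third, and converts counts to
#' per-nt densities. When the exon is longer than `exon_scan_len`, only
#' splice-site-anchored halves are scanned and the two exon pieces are
#' scanned separately so that no match is fabricated across the junction.
#'
#' @param events data.frame with columns `event_id`, `upstream_flank`,
#'   `exon`, `downstream_flank` (sequences) and optionally `group`.
#' @param spec A [motif_spec()].
#' @param cfg A [motif_map_config()].
#' @return A list with `density` and `count` (numeric matrices, events x
#'   9 regions, `NA` density where a third has length 0) and `lengths`
#'   (matrix of third lengths).
#' @export
region_density <- function(events, spec = motif_spec(), cfg = motif_map_config()) {
  stopifnot(nrow(events) > 0L)
  n <- nrow(events)
  regions <- region_names()
  density <- count <- lengths <- matrix(NA_real_, n, 9L,
                                        dimnames = list(events$event_id, regions))
  for (i in seq_len(n)) {
    up <- events$upstream_flank[i]
    dn <- events$downstream_flank[i]
    ex <- exon_scan_pieces(events$exon[i], cfg$exon_scan_len)
    ex_len <- nchar(ex$left) + nchar(ex$right)
    ex_starts <- c(scan_motif(ex$left, spec)$start,
                   if (nchar(ex$right) > 0L)
                     scan_motif(ex$right, spec)$start + nchar(ex$left))
    per_region <- list(
      upstream = list(starts = scan_motif(up, spec)$start, len = nchar(up)),
      exon = list(starts = ex_starts, len = ex_len),
      downstream = list(starts = scan_motif(dn, spec)$start, len = nchar(dn))
    )
    for (r in names(per_region)) {
      len <- per_region[[r]]$len
      tl <- thirds_lengths(len)
      cts <- count_in_thirds(per_region[[r]]$starts, len)
      cols <- paste(r, c("first", "middle", "last"), sep = "_")
      count[i, cols] <- cts
      lengths[i, cols] <- tl
      density[i, cols] <- ifelse(tl > 0L, cts / tl, NA_real_)
    }
  }
  list(density = density, count = count, lengths = lengths)
}

# group/background mean densities per region with NA-aware permutation
# machinery shared by thirds_enrichment
perm_region_means <- function(dens, idx_a) {
  a <- colMeans(dens[idx_a, , drop = FALSE], na.rm = TRUE)
  b <- colMeans(dens[-idx_a, , drop = FALSE], na.rm = TRUE)
  list(a = a, b = b)
}

#' Region-thirds motif enrichment with a permutation null
#'
#' For each of the nine region thirds the enrichment score is the ratio of
#' mean per-nt motif density in the regulated set to the background set,
#' stabilized by a pseudocount `eps = 1 / (flank_len * pooled event count)`.
#' Significance is a two-sided permutation test on the log score: group
#' labels of the pooled events are reshuffled `n_perm_enrich` times with
#' group sizes preserved.
#'
#' @param regulated,background Event data.frames (see [region_density()]).
#' @param spec A [motif_spec()].
#' @param cfg A [motif_map_config()]; `cfg$seed` seeds the permutations.
#' @return data.frame with one row per region: `region`, `score`,
#'   `p_value`, `direction` (`enriched` when score >= 1).
#' @export
thirds_enrichment <- function(regulated, background,
                              spec = motif_spec(), cfg = motif_map_config()) {
  if (nrow(regulated) == 0L || nrow(background) == 0L) {
    stop("both the regulated and the background group must be non-empty")
  }
  dens_r <- region_density(regulated, spec, cfg)$density
  dens_b <- region_density(background, spec, cfg)$density
  dens <- rbind(dens_r, dens_b)
  n_r <- nrow(dens_r); n <- nrow(dens)
  eps <- 1 / (cfg$flank_len * n)
  obs <- perm_region_means(dens, seq_len(n_r))
  score <- (obs$a + eps) / (obs$b + eps)
  set.seed(cfg$seed)
  # densities are ratios of small integers, so the permutation statistic is
  # heavily tied; an infinitesimal per-event jitter (used only to rank the
  # statistic, never reported) breaks ties at random, which keeps the
  # permutation test exact instead of conservative
  jitter_m <- matrix(stats::runif(length(dens), 0, 1e-9), nrow(dens))
  dens_j <- dens + jitter_m
  obs_j <- perm_region_means(dens_j, seq_len(n_r))
  log_obs <- abs(log((obs_j$a + eps) / (obs_j$b + eps)))
  exceed <- numeric(9L)
  vals <- ifelse(is.na(dens_j), 0, dens_j)
  has <- !is.na(dens_j)
  tot_sum <- colSums(vals); tot_cnt <- colSums(has)
  for (t in seq_len(cfg$n_perm_enrich)) {
    idx <- sample.int(n, n_r)
    s_a <- colSums(vals[idx, , drop = FALSE])
    c_a <- colSums(has[idx, , drop = FALSE])
    m_a <- ifelse(c_a > 0, s_a / c_a, 0)
    c_b <- tot_cnt - c_a
    m_b <- ifelse(c_b > 0, (tot_sum - s_a) / c_b, 0)
    lp <- abs(log((m_a + eps) / (m_b + eps)))
    exceed <- exceed + (lp >= log_obs - 1e-12)
  }
  p <- (1 + exceed) / (cfg$n_perm_enrich + 1)
  # a region whose pooled densities are all equal carries no information:
  # report p = 1 rather than a random tie-broken value
  constant <- apply(dens, 2L, function(x)
    all(is.na(x)) || diff(range(x, na.rm = TRUE)) == 0)
  p[constant] <- 1
  data.frame(region = region_names(),
             score = unname(score),
             p_value = unname(p),
             direction = ifelse(score >= 1, "enriched", "depleted"),
             stringsAsFactors = FALSE)
}

# Composite-axis occupancy for one event. Axis layout:
# [upstream flank | exon left half + exon right half | downstream flank],
# flanks anchored at the splice sites (short upstream flanks are
# right-aligned, short downstream flanks left-aligned); absent positions NA.
event_occupancy <- function(up, exon, dn, spec, cfg) {
  fl <- cfg$flank_len; exl <- cfg$exon_scan_len
  axis_len <- 2L * fl + exl
  occ <- rep(NA_real_, axis_len)
  mark <- function(occ, seq_str, axis_start, max_len) {
    len <- min(nchar(seq_str), max_len)
    if (len <= 0L) return(occ)
    pos <- axis_start + seq_len(len) - 1L
    occ[pos] <- 0
    m <- scan_motif(substr(seq_str, 1L, len), spec)
    if (nrow(m) > 0L) {
      for (k in seq_len(nrow(m))) {
        lo <- m$start[k]; hi <- min(m$end[k], len)
        occ[axis_start + (lo:hi) - 1L] <- 1
      }
    }
    occ
  }
  # upstream: right-aligned so its last nt abuts the exon's 3' splice site
  lu <- min(nchar(up), fl)
  if (lu > 0L) {
    up_seq <- substr(up, nchar(up) - lu + 1L, nchar(up))
    occ <- mark(occ, up_seq, fl - lu + 1L, fl)
  }
  ex <- exon_scan_pieces(exon, exl)
  occ <- mark(occ, ex$left, fl + 1L + ex$left_offset, nchar(ex$left))
  if (nchar(ex$right) > 0L) {
    occ <- mark(occ, ex$right, fl + 1L + ex$right_offset, nchar(ex$right))
  }
  occ <- mark(occ, dn, fl + exl + 1L, fl)
  occ
}

# centered running mean with truncation at the ends, NA-aware
window_mean <- function(x, w) {
  n <- length(x); h <- (w - 1L) %/% 2L
  v <- ifelse(is.na(x), 0, x)
  k <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(v)); ck <- c(0, cumsum(k))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- ck[hi + 1L] - ck[lo]
  ifelse(den > 0, num / den, NA_real_)
}

occupancy_matrix <- function(events, spec, cfg) {
  axis_len <- 2L * cfg$flank_len + cfg$exon_scan_len
  out <- matrix(NA_real_, nrow(events), axis_len)
  for (i in seq_len(nrow(events))) {
    occ <- event_occupancy(events$upstream_flank[i], events$exon[i],
                           events$downstream_flank[i], spec, cfg)
    out[i, ] <- window_mean(occ, cfg$window)
  }
  out
}

#' RNA splicing maps: positional motif coverage with permutation significance
#'
#' Computes, for each group of events, the mean sliding-window motif
#' coverage along a composite axis (upstream intron flank, splice-site
#' anchored exon halves, downstream intron flank) and marks positions where
#' the group differs from a background of unregulated events by a two-sided
#' permutation test (`n_perm_map` label reshuffles, significant when
#' `p < alpha`). The background is downsampled without replacement to
#' `bg_downsample` events when larger.
#'
#' @param groups Named list of event data.frames (see [region_density()]),
#'   e.g. `up`, `down`.
#' @param background Event data.frame of unregulated events.
#' @param spec A [motif_spec()].
#' @param cfg A [motif_map_config()]; `cfg$seed` drives downsampling and
#'   permutations.
#' @return A list of class `rna_map` with one data.frame per group
#'   (`position`, `region`, `rel_pos` in nt relative to the nearest splice
#'   site, `coverage`, `bg_coverage`, `p_value`, `significant`) and the
#'   background size as attribute `n_background`.
#' @export
rna_map <- function(groups, background, spec = motif_spec(),
                    cfg = motif_map_config()) {
  stopifnot(length(groups) >= 1L, nrow(background) > 0L)
  set.seed(cfg$seed)
  if (nrow(background) > cfg$bg_downsample) {
    background <- background[sample.int(nrow(background), cfg$bg_downsample), ,
                             drop = FALSE]
  }
  fl <- cfg$flank_len; exl <- cfg$exon_scan_len
  axis_len <- 2L * fl + exl
  region <- c(rep("upstream", fl), rep("exon", exl), rep("downstream", fl))
  left_half <- ceiling(exl / 2)
  rel_pos <- c(-(fl:1),                                  # intron, 3'ss at -1
               seq_len(left_half),                       # exon from 3'ss
               -rev(seq_len(exl - left_half)),           # exon from 5'ss
               seq_len(fl))                              # intron, 5'ss at +1
  W_bg <- occupancy_matrix(background, spec, cfg)
  out <- list()
  for (g in names(groups)) {
    ev <- groups[[g]]
    if (nrow(ev) < 5L) {
      warning("group '", g, "' has fewer than 5 events; map is unreliable")
    }
    W_g <- occupancy_matrix(ev, spec, cfg)
    W <- rbind(W_g, W_bg)
    n_g <- nrow(W_g); n <- nrow(W)
    A <- ifelse(is.na(W), 0, W)
    K <- matrix(as.numeric(!is.na(W)), n, axis_len)
    tot_s <- colSums(A); tot_k <- colSums(K)
    mean_div <- function(s, k) ifelse(k > 0, s / k, 0)
    cov_g <- mean_div(colSums(A[seq_len(n_g), , drop = FALSE]),
                      colSums(K[seq_len(n_g), , drop = FALSE]))
    cov_b <- mean_div(tot_s - colSums(A[seq_len(n_g), , drop = FALSE]),
                      tot_k - colSums(K[seq_len(n_g), , drop = FALSE]))
    d_obs <- abs(cov_g - cov_b)
    # permutation indicator matrix: one matrix product per statistic
    P <- matrix(0, cfg$n_perm_map, n)
    for (t in seq_len(cfg$n_perm_map)) P[t, sample.int(n, n_g)] <- 1
    S_g <- P %*% A; K_g <- P %*% K
    M_g <- ifelse(K_g > 0, S_g / K_g, 0)
    K_b <- matrix(tot_k, cfg$n_perm_map, axis_len, byrow = TRUE) - K_g
    S_b <- matrix(tot_s, cfg$n_perm_map, axis_len, byrow = TRUE) - S_g
    M_b <- ifelse(K_b > 0, S_b / K_b, 0)
    exceed <- colSums(abs(M_g - M_b) >= matrix(d_obs, cfg$n_perm_map,
                                               axis_len, byrow = TRUE) - 1e-12)
    p <- (1 + exceed) / (cfg$n_perm_map + 1)
    out[[g]] <- data.frame(position = seq_len(axis_len), region = region,
                           rel_pos = rel_pos,
                           coverage = cov_g, bg_coverage = cov_b,
                           p_value = p, significant = p < cfg$alpha,
                           stringsAsFactors = FALSE)
  }
  structure(out, class = "rna_map", n_background = nrow(background))
}
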