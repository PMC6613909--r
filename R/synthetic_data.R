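#' Configuration of the synthetic-data generators
#'
#' Defaults emulate the statistical structure of the study conditions the
#' pipeline targets: three target tissues sharing one super-enhancer-
#' associated RBP that the outlier tissue lacks, cassette-exon sequence
#' sets with CAC diclusters planted at position-specific densities
#' (repressed events in the exon and the ~80 nt of intron immediately
#' upstream, activated events in the downstream flank), and junction-count
#' tables with congruent/reciprocal delta-PSI structure and binomial count
#' noise around the generative PSI.
#'
#' @param seed RNG seed; every generator is deterministic given
#'   `(seed, config)`.
#' @param n_genes Genes on the synthetic chromosome.
#' @param chrom_len Chromosome length, bp.
#' @param min_tss_spacing Minimum distance between TSSs, bp.
#' @param tissues Target tissue labels.
#' @param outlier Outlier tissue label.
#' @param planted_rbp Symbol of the planted regulator.
#' @param n_decoy_rbps Decoy RBP genes that fail the screen by design
#'   (half miss one target tissue, half are also super-enhancer-associated
#'   in the outlier).
#' @param n_noise_ses Non-RBP genes per tissue that receive a
#'   super-enhancer.
#' @param motif_density Planted diclusters per kb, by group and region:
#'   list with elements `down` (named `exon`, `upstream`), `up`
#'   (named `downstream`), `unregulated` (scalar).
#' @param upstream_plant_len Length of the exon-proximal upstream-intron
#'   segment that receives planted motifs in the `down` group, nt.
#' @param flank_len Intron flank length emitted per event, nt.
#' @param exon_len_range Exon length range, nt.
#' @param n_events Events per group (`up`, `down`, `unregulated`).
#' @param read_depth Mean skipping-junction read depth per replicate.
#' @param psi_noise_sd Replicate-level PSI noise, PSI units.
#' @param n_replicates Replicates per condition.
#' @param n_congruent,n_reciprocal,n_null Events per concordance class in
#'   the paired junction-count tables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 60L, chrom_len = 1e7,
                       min_tss_spacing = 10000L,
                       tissues = c("aorta", "bladder", "stomach"),
                       outlier = "skeletal",
                       planted_rbp = "RBPMS", n_decoy_rbps = 6L,
                       n_noise_ses = 12L,
                       motif_density = list(down = c(exon = 5, upstream = 5),
                                            up = c(downstream = 5),
                                            unregulated = 0),
                       upstream_plant_len = 80L,
                       flank_len = 250L, exon_len_range = c(80L, 200L),
                       n_events = c(up = 60L, down = 60L, unregulated = 300L),
                       read_depth = 100L, psi_noise_sd = 0.03,
                       n_replicates = 3L,
                       n_congruent = 100L, n_reciprocal = 50L, n_null = 300L) {
  stopifnot(n_genes >= 2L, psi_noise_sd >= 0, psi_noise_sd <= 0.2,
            n_replicates >= 2L, all(unlist(motif_density) >= 0),
            all(n_events > 0L), read_depth > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Synthetic gene annotation and chromosome sizes
#'
#' TSS positions are drawn uniformly with a guaranteed minimum spacing;
#' strands are Bernoulli(0.5). One gene carries the planted RBP symbol
#' (placed mid-chromosome) and `n_decoy_rbps` genes at least 1 Mb away
#' carry decoy RBP symbols.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genes` (data.frame `gene_id`, `symbol`, `chrom`,
#'   `tss`, `strand`) and `chrom_sizes` (named vector).
#' @export
make_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  spacing <- cfg$min_tss_spacing
  slack <- cfg$chrom_len - (n + 1) * spacing
  if (slack <= 0) stop("chromosome too short for ", n,
                       " genes at ", spacing, " bp spacing")
  # sorted uniform draws plus fixed gaps guarantee >= spacing between TSSs
  tss <- floor(sort(stats::runif(n)) * slack) + spacing * seq_len(n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  symbol <- sprintf("GENE%03d", seq_len(n))
  planted_idx <- which.min(abs(tss - cfg$chrom_len / 2))
  symbol[planted_idx] <- cfg$planted_rbp
  far <- setdiff(which(abs(tss - tss[planted_idx]) >= 1e6), planted_idx)
  if (length(far) < cfg$n_decoy_rbps) {
    stop("chromosome too short to place ", cfg$n_decoy_rbps,
         " decoy RBPs at least 1 Mb from the planted gene")
  }
  decoy_idx <- sort(sample(far, cfg$n_decoy_rbps))
  symbol[decoy_idx] <- sprintf("DRBP%02d", seq_along(decoy_idx))
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n)),
                      symbol = symbol, chrom = "chr1",
                      tss = as.integer(tss), strand = strand,
                      stringsAsFactors = FALSE)
  list(genes = genes, chrom_sizes = c(chr1 = cfg$chrom_len))
}

#' The RBP catalog matching a synthetic genome
#' @param genes Gene table from [make_genome()].
#' @param cfg A [sim_config()].
#' @return Character vector: the planted RBP plus all decoy RBP symbols.
#' @export
make_rbp_catalog <- function(genes, cfg = sim_config()) {
  sort(c(cfg$planted_rbp, grep("^DRBP", genes$symbol, value = TRUE)))
}

# one SE interval placed inside the host gene's basal domain regardless of
# its strand (so both association rules assign it to the host and to no
# other gene)
se_near <- function(tss, width = 1200L) {
  start <- tss - 900L + sample.int(400L, 1L)
  data.frame(start = start, end = start + width)
}

#' Synthetic per-tissue super-enhancer sets
#'
#' In every target tissue one super-enhancer is placed at the planted RBP
#' gene; the outlier tissue gets no super-enhancer within 1 Mb of it.
#' Decoy RBP genes receive enhancers that defeat the screen in one of two
#' ways (absent from one target tissue, or present in the outlier too),
#' and random non-RBP genes receive noise enhancers. All enhancers are
#' placed within their host gene's basal domain, and the construction is
#' verified post hoc by running the closest-TSS association and the screen.
#'
#' @param genes Gene table from [make_genome()].
#' @param cfg A [sim_config()].
#' @return data.frame with `chrom`, `start`, `end`, `se_id`, `tissue`.
#' @export
make_superenhancers <- function(genes, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  planted_idx <- which(genes$symbol == cfg$planted_rbp)
  stopifnot(length(planted_idx) == 1L)
  decoy_idx <- which(grepl("^DRBP", genes$symbol))
  all_tissues <- c(cfg$tissues, cfg$outlier)
  far_of_planted <- which(abs(genes$tss - genes$tss[planted_idx]) >= 1e6)
  rows <- list()
  add <- function(gene_i, tissue) {
    iv <- se_near(genes$tss[gene_i])
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = genes$chrom[gene_i], start = iv$start, end = iv$end,
      se_id = sprintf("SE_%s_%d", tissue, length(rows) + 1L),
      tissue = tissue, stringsAsFactors = FALSE)
  }
  for (t in cfg$tissues) add(planted_idx, t)
  for (k in seq_along(decoy_idx)) {
    if (k %% 2L == 0L) {
      # present everywhere incl. outlier -> removed by outlier subtraction
      for (t in all_tissues) add(decoy_idx[k], t)
    } else {
      # missing one target tissue -> removed by the intersection
      drop_t <- cfg$tissues[1L + (k %% length(cfg$tissues))]
      for (t in setdiff(cfg$tissues, drop_t)) add(decoy_idx[k], t)
    }
  }
  non_rbp <- setdiff(seq_len(nrow(genes)), c(planted_idx, decoy_idx))
  for (t in all_tissues) {
    pool <- if (t == cfg$outlier) intersect(non_rbp, far_of_planted) else non_rbp
    hosts <- sample(pool, min(cfg$n_noise_ses, length(pool)))
    for (g in hosts) add(g, t)
  }
  ses <- do.call(rbind, rows)
  # post-hoc guarantee: closest-TSS association must recover the plant
  scfg <- screen_config()
  sets <- lapply(all_tissues, function(t) {
    assoc <- associate_by_proximity(ses[ses$tissue == t, , drop = FALSE],
                                    genes, scfg)
    associated_symbols(assoc, genes)
  })
  names(sets) <- all_tissues
  rep <- candidate_screen(sets[cfg$tissues], sets[[cfg$outlier]],
                          make_rbp_catalog(genes, cfg))
  if (!identical(rep$rbp_candidates, toupper(cfg$planted_rbp))) {
    stop("super-enhancer placement failed its post-hoc screen check")
  }
  ses
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant CAC-N(1-12)-CAC diclusters into a sequence at an expected density
# (diclusters per kb) without overlaps; returns the sequence and positions
plant_diclusters <- function(seq_str, density_per_kb, spec = motif_spec(),
                             window = NULL) {
  len <- nchar(seq_str)
  lo <- if (is.null(window)) 1L else window[1]
  hi <- if (is.null(window)) len else window[2]
  region_len <- hi - lo + 1L
  n_plant <- stats::rpois(1L, density_per_kb * region_len / 1000)
  if (n_plant == 0L) {
    return(list(seq = seq_str, truth = data.frame(start = integer(),
                                                  end = integer())))
  }
  chars <- strsplit(seq_str, "", fixed = TRUE)[[1]]
  core <- strsplit(spec$core, "", fixed = TRUE)[[1]]
  L <- length(core)
  occupied <- rep(FALSE, len)
  starts <- ends <- integer(0)
  tries <- 0L
  while (length(starts) < n_plant) {
    tries <- tries + 1L
    if (tries > 200L * n_plant) {
      stop("motif density too high: cannot place ", n_plant,
           " non-overlapping diclusters in ", region_len, " nt")
    }
    s <- sample(seq.int(spec$spacer_min, spec$spacer_max), 1L)
    w <- 2L * L + s
    if (hi - w + 1L < lo) next
    p <- lo + sample.int(hi - w + 2L - lo, 1L) - 1L
    if (any(occupied[p:(p + w - 1L)])) next
    spacer <- sample(c("A", "C", "G", "T"), s, replace = TRUE)
    chars[p:(p + w - 1L)] <- c(core, spacer, core)
    occupied[p:(p + w - 1L)] <- TRUE
    starts <- c(starts, p); ends <- c(ends, p + w - 1L)
  }
  list(seq = paste(chars, collapse = ""),
       truth = data.frame(start = starts, end = ends))
}

#' Synthetic cassette-exon sequence sets with planted motif geometry
#'
#' Background sequence is i.i.d. uniform over `A,C,G,T`. The `down`
#' (repressed) group receives planted CAC diclusters in the exon and in
#' the `upstream_plant_len` nt of upstream intron adjacent to the 3'
#' splice site; the `up` (activated) group receives them in the downstream
#' intron flank; the `unregulated` group is planted at
#' `motif_density$unregulated` (0 by default). Planted positions are
#' recorded as ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A list with `events` (data.frame `event_id`, `group`,
#'   `upstream_flank`, `exon`, `downstream_flank`) and `truth`
#'   (data.frame `event_id`, `group`, `region`, `start`, `end`,
#'   1-based within the region sequence).
#' @export
make_event_sequences <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 2L)
  spec <- motif_spec()
  rows <- list(); truths <- list()
  for (g in names(cfg$n_events)) {
    for (i in seq_len(cfg$n_events[[g]])) {
      id <- sprintf("%s_%04d", g, i)
      exon_len <- sample(seq.int(cfg$exon_len_range[1], cfg$exon_len_range[2]), 1L)
      up <- random_seq(cfg$flank_len)
      ex <- random_seq(exon_len)
      dn <- random_seq(cfg$flank_len)
      tr <- list()
      if (g == "down") {
        pl <- plant_diclusters(ex, cfg$motif_density$down[["exon"]], spec)
        ex <- pl$seq
        if (nrow(pl$truth)) tr$exon <- pl$truth
        win <- c(max(1L, cfg$flank_len - cfg$upstream_plant_len + 1L),
                 cfg$flank_len)
        pl <- plant_diclusters(up, cfg$motif_density$down[["upstream"]], spec,
                               window = win)
        up <- pl$seq
        if (nrow(pl$truth)) tr$upstream <- pl$truth
      } else if (g == "up") {
        pl <- plant_diclusters(dn, cfg$motif_density$up[["downstream"]], spec)
        dn <- pl$seq
        if (nrow(pl$truth)) tr$downstream <- pl$truth
      } else {
        d0 <- cfg$motif_density$unregulated
        if (length(d0) == 1L && d0 > 0) {
          for (rg in c("upstream", "exon", "downstream")) {
            sq <- switch(rg, upstream = up, exon = ex, downstream = dn)
            pl <- plant_diclusters(sq, d0, spec)
            if (rg == "upstream") up <- pl$seq
            if (rg == "exon") ex <- pl$seq
            if (rg == "downstream") dn <- pl$seq
            if (nrow(pl$truth)) tr[[rg]] <- pl$truth
          }
        }
      }
      rows[[id]] <- data.frame(event_id = id, group = g,
                               upstream_flank = up, exon = ex,
                               downstream_flank = dn,
                               stringsAsFactors = FALSE)
      for (rg in names(tr)) {
        truths[[paste(id, rg)]] <- data.frame(
          event_id = id, group = g, region = rg,
          start = tr[[rg]]$start, end = tr[[rg]]$end,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truths)) do.call(rbind, c(truths, make.row.names = FALSE))
           else data.frame(event_id = character(), group = character(),
                           region = character(), start = integer(),
                           end = integer())
  events <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(events = events, truth = truth)
}

welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
}

#' Paired synthetic rMATS-dialect tables with planted concordance structure
#'
#' Draws a generative PSI per event and condition: congruent events share
#' the sign and magnitude of their delta PSI across both comparisons,
#' reciprocal events flip sign, null events have delta PSI 0. Observed
#' per-replicate PSI adds truncated Gaussian noise; inclusion junction
#' counts are Binomial(2 x read_depth, PSI) and skipping counts
#' Binomial(read_depth, 1 - PSI), with effective form lengths 2 and 1, so
#' [compute_psi()] inverts the generative model in expectation. P-values
#' come from a Welch test on per-replicate PSI (an emulation of a
#' differential-splicing test, not the rMATS likelihood model) and FDR
#' from [bh_adjust()].
#'
#' @param cfg A [sim_config()].
#' @return A list with `table_a`, `table_b` (data.frames in the
#'   [read_rmats_table()] layout, each carrying the generative
#'   per-replicate PSI matrices as attribute `replicate_psi`) and `truth`
#'   (per-event class, generative PSI and delta PSI for both comparisons).
#' @export
make_rmats_tables <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_congruent + cfg$n_reciprocal + cfg$n_null
  class_lab <- rep(c("congruent", "reciprocal", "null"),
                   c(cfg$n_congruent, cfg$n_reciprocal, cfg$n_null))
  base <- stats::runif(n, 0.25, 0.75)
  effect <- stats::runif(n, 0.15, 0.40) * sample(c(-1, 1), n, replace = TRUE)
  effect[class_lab == "null"] <- 0
  clip <- function(x) pmin(pmax(x, 0.02), 0.98)
  psi_a1 <- clip(base + effect / 2); psi_a2 <- clip(base - effect / 2)
  # comparison B: same magnitude, sign flipped for reciprocal events
  eff_b <- ifelse(class_lab == "reciprocal", -effect, effect)
  psi_b1 <- clip(base + eff_b / 2); psi_b2 <- clip(base - eff_b / 2)

  one_table <- function(psi1, psi2) {
    nr <- cfg$n_replicates
    draw <- function(truth) {
      psi_obs <- matrix(pmin(pmax(stats::rnorm(n * nr, rep(truth, each = nr),
                                               cfg$psi_noise_sd), 0), 1),
                        nrow = n, byrow = TRUE)
      ijc <- matrix(stats::rbinom(n * nr, 2L * cfg$read_depth, t(psi_obs)),
                    nrow = n, byrow = TRUE)
      sjc <- matrix(stats::rbinom(n * nr, cfg$read_depth, 1 - t(psi_obs)),
                    nrow = n, byrow = TRUE)
      list(psi = psi_obs, ijc = ijc, sjc = sjc)
    }
    d1 <- draw(psi1); d2 <- draw(psi2)
    replicate_psi <- list(cond1 = d1$psi, cond2 = d2$psi)
    inc1 <- lapply(seq_len(n), function(i)
      compute_psi(d1$ijc[i, ], d1$sjc[i, ], 2, 1))
    inc2 <- lapply(seq_len(n), function(i)
      compute_psi(d2$ijc[i, ], d2$sjc[i, ], 2, 1))
    pv <- vapply(seq_len(n), function(i)
      welch_p(d1$psi[i, ], d2$psi[i, ]), numeric(1))
    base_coord <- seq_len(n) * 10000L
    tab <- data.frame(
      event_type = "SE",
      gene_id = sprintf("SYN%04d", seq_len(n)),
      symbol = sprintf("Syn%04d", seq_len(n)),
      chrom = "chr1", strand = "+",
      target_start = base_coord + 1000L, target_end = base_coord + 1150L,
      upstream_start = base_coord + 100L, upstream_end = base_coord + 300L,
      downstream_start = base_coord + 2000L, downstream_end = base_coord + 2200L,
      inc_form_len = 2L, skip_form_len = 1L,
      pvalue = pv, fdr = bh_adjust(pv),
      delta_psi = vapply(seq_len(n), function(i)
        mean(inc1[[i]], na.rm = TRUE) - mean(inc2[[i]], na.rm = TRUE),
        numeric(1)),
      ijc_1 = I(lapply(seq_len(n), function(i) d1$ijc[i, ])),
      sjc_1 = I(lapply(seq_len(n), function(i) d1$sjc[i, ])),
      ijc_2 = I(lapply(seq_len(n), function(i) d2$ijc[i, ])),
      sjc_2 = I(lapply(seq_len(n), function(i) d2$sjc[i, ])),
      inc_level_1 = I(inc1), inc_level_2 = I(inc2),
      stringsAsFactors = FALSE
    )
    # generative per-replicate PSI (the binomial success probabilities)
    # travels with the table as ground truth
    attr(tab, "replicate_psi") <- replicate_psi
    tab
  }
  table_a <- one_table(psi_a1, psi_a2)
  table_b <- one_table(psi_b1, psi_b2)
  truth <- data.frame(gene_id = table_a$gene_id, class = class_lab,
                      base_psi = base,
                      psi_a1 = psi_a1, psi_a2 = psi_a2,
                      psi_b1 = psi_b1, psi_b2 = psi_b2,
                      dpsi_a = psi_a1 - psi_a2, dpsi_b = psi_b1 - psi_b2,
                      stringsAsFactors = FALSE)
  list(table_a = table_a, table_b = table_b, truth = truth)
}

#' Synthetic expression table with a planted ranking winner
#'
#' Log-normal abundances over tissue and culture replicates. The planted
#' RBP is down-regulated from tissue to culture and has the highest tissue
#' abundance among the down-regulated RBP candidates; odd decoys are
#' down-regulated at lower abundance, even decoys are up-regulated.
#' Housekeeper rows `Gapdh` and `Rpl32` have fold change 1 by
#' construction.
#'
#' @param genes Gene table from [make_genome()].
#' @param cfg A [sim_config()].
#' @return A list with `values` (matrix, genes+housekeepers x samples),
#'   `conditions` (per-column tags, `tissue`/`culture`) and `truth`.
#' @export
make_expression <- function(genes, cfg = sim_config()) {
  set.seed(cfg$seed + 4L)
  nrep <- 3L
  symbols <- c(genes$symbol, "Gapdh", "Rpl32")
  n <- length(symbols)
  mean_tissue <- stats::rlnorm(n, log(20), 1)
  fold <- stats::rlnorm(n, 0, 0.5)
  planted <- symbols == cfg$planted_rbp
  decoys <- grepl("^DRBP", symbols)
  mean_tissue[planted] <- 150
  fold[planted] <- 5
  k <- which(decoys)
  down_decoy <- k[seq_along(k) %% 2L == 1L]
  up_decoy <- setdiff(k, down_decoy)
  mean_tissue[down_decoy] <- stats::runif(length(down_decoy), 10, 80)
  fold[down_decoy] <- stats::runif(length(down_decoy), 1.5, 4)
  mean_tissue[up_decoy] <- stats::runif(length(up_decoy), 10, 200)
  fold[up_decoy] <- stats::runif(length(up_decoy), 0.2, 0.8)
  hk <- symbols %in% c("Gapdh", "Rpl32")
  mean_tissue[hk] <- 50
  fold[hk] <- 1
  mean_culture <- mean_tissue / fold
  noise <- function(mu) {
    matrix(stats::rlnorm(n * nrep, log(rep(mu, nrep)), 0.1), nrow = n)
  }
  values <- cbind(noise(mean_tissue), noise(mean_culture))
  rownames(values) <- symbols
  colnames(values) <- c(paste0("tissue_", 1:nrep), paste0("culture_", 1:nrep))
  conditions <- rep(c("tissue", "culture"), each = nrep)
  truth <- data.frame(symbol = symbols, mean_tissue = mean_tissue,
                      mean_culture = mean_culture, fold_change = fold,
                      stringsAsFactors = FALSE)
  list(values = values, conditions = conditions, truth = truth)
}
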