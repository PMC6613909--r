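# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: domains are found by scanning individual base pairs,
# overlaps by all-pairs checks, motifs by a double loop over start and
# spacer. They are slow on purpose.

# strand-aware basal window, written out directly
oracle_basal <- function(tss, strand, cfg) {
  if (strand == "+") {
    c(max(0, tss - cfg$basal_up), tss + cfg$basal_down)
  } else {
    c(max(0, tss - cfg$basal_down), tss + cfg$basal_up)
  }
}

# per-bp scan: walk outwards from the basal domain until a bp inside any
# other gene's basal domain is hit, the max extension is reached, or the
# chromosome ends
oracle_extend <- function(genes, cfg, chrom_len) {
  n <- nrow(genes)
  basal <- t(mapply(function(t, s) oracle_basal(t, s, cfg),
                    genes$tss, genes$strand))
  cover <- integer(chrom_len)  # how many basal domains cover each bp
  for (j in seq_len(n)) {
    lo <- basal[j, 1] + 1L; hi <- min(basal[j, 2], chrom_len)
    if (hi >= lo) cover[lo:hi] <- cover[lo:hi] + 1L
  }
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    bs <- basal[i, 1]; be <- min(basal[i, 2], chrom_len)
    own <- integer(chrom_len)
    lo <- bs + 1L
    if (be >= lo) own[lo:be] <- 1L
    blocked <- (cover - own) > 0L
    lim_r <- min(genes$tss[i] + cfg$max_extension, chrom_len)
    ext_end <- lim_r
    if (lim_r > be) {
      rng <- (be + 1L):lim_r          # 1-based indices for bp be..lim_r-1
      hit <- which(blocked[rng])
      if (length(hit) > 0L) ext_end <- be + hit[1] - 1L
    }
    lim_l <- max(genes$tss[i] - cfg$max_extension, 0)
    ext_start <- lim_l
    if (bs > lim_l) {
      rng <- bs:(lim_l + 1L)           # bp bs-1 downwards (1-based index)
      hit <- which(blocked[rng])
      if (length(hit) > 0L) ext_start <- bs - hit[1] + 1L
    }
    out[i, ] <- c(min(ext_start, bs), max(ext_end, be))
  }
  out
}

# all-pairs 1 bp overlap check
oracle_associate_domain <- function(ses, domains) {
  res <- list()
  for (i in seq_len(nrow(domains))) {
    hits <- character(0)
    for (j in seq_len(nrow(ses))) {
      if (domains$chrom[i] == ses$chrom[j] &&
          domains$ext_start[i] < ses$end[j] &&
          ses$start[j] < domains$ext_end[i]) {
        hits <- c(hits, ses$se_id[j])
      }
    }
    if (length(hits) > 0L) res[[domains$gene_id[i]]] <- hits
  }
  res
}

oracle_tss_distance <- function(tss, start, end) {
  if (tss >= start && tss < end) return(0)
  min(abs(tss - start), abs(tss - (end - 1)))
}

oracle_associate_proximity <- function(ses, genes, cfg) {
  res <- list()
  for (j in seq_len(nrow(ses))) {
    best_gene <- NA_character_; best_d <- Inf
    for (i in seq_len(nrow(genes))) {
      if (genes$chrom[i] != ses$chrom[j]) next
      d <- oracle_tss_distance(genes$tss[i], ses$start[j], ses$end[j])
      if (d < best_d || (d == best_d && !is.na(best_gene) &&
                         genes$gene_id[i] < best_gene)) {
        best_d <- d; best_gene <- genes$gene_id[i]
      }
    }
    if (!is.na(best_gene) && best_d <= cfg$proximal_window) {
      res[[best_gene]] <- c(res[[best_gene]], ses$se_id[j])
    }
  }
  res
}

# double loop over (start, spacer); smallest spacer kept per start
oracle_scan_motif <- function(seq, core = "CAC", smin = 1, smax = 12) {
  chars <- strsplit(seq, "")[[1]]
  cc <- strsplit(core, "")[[1]]
  L <- length(cc); n <- length(chars)
  res <- data.frame(start = integer(), end = integer(), spacer = integer())
  core_at <- function(p) {
    p + L - 1 <= n && all(chars[p:(p + L - 1)] == cc)
  }
  for (i in seq_len(max(0, n - L + 1))) {
    if (!core_at(i)) next
    for (s in smin:smax) {
      if (core_at(i + L + s)) {
        res <- rbind(res, data.frame(start = i, end = i + 2 * L + s - 1,
                                     spacer = s))
        break
      }
    }
  }
  res
}

# automaton DP: probability that a uniform iid DNA string long enough to
# host `w` consecutive start positions contains no core occurrence
# starting at any of them (the enumeration oracle for chance rates)
oracle_no_core_prob <- function(w, core = "CAC") {
  if (w <= 0) return(1)
  cc <- strsplit(core, "")[[1]]
  L <- length(cc)
  nts <- c("A", "C", "G", "T")
  # delta[state+1, ch]: longest core prefix matched after appending ch to a
  # suffix matching the length-`state` prefix; L is absorbing (occurrence)
  delta <- matrix(0L, L, 4, dimnames = list(NULL, nts))
  for (st in 0:(L - 1)) {
    for (ch in nts) {
      cand <- c(cc[seq_len(st)], ch)
      k_best <- 0L
      for (k in seq_len(min(st + 1L, L))) {
        if (all(cand[(length(cand) - k + 1L):length(cand)] == cc[seq_len(k)]))
          k_best <- k
      }
      delta[st + 1L, ch] <- k_best
    }
  }
  probs <- numeric(L + 1); probs[1] <- 1
  for (pos in seq_len(w + L - 1L)) {
    nxt <- numeric(L + 1)
    for (st in 0:(L - 1)) {
      if (probs[st + 1] == 0) next
      for (ch in nts) {
        ns <- delta[st + 1L, ch]
        nxt[ns + 1L] <- nxt[ns + 1L] + probs[st + 1L] / 4
      }
    }
    probs <- nxt  # mass reaching state L (an occurrence) is dropped
  }
  sum(probs[seq_len(L)])
}

# expected dicluster-match count for a uniform iid sequence of length n
oracle_chance_matches <- function(n, core = "CAC", smin = 1, smax = 12) {
  L <- nchar(core)
  p_core <- (1 / 4)^L
  total <- 0
  for (i in seq_len(max(0, n - L + 1))) {
    first_second <- i + L + smin
    last_second <- min(i + L + smax, n - L + 1)
    w <- last_second - first_second + 1
    if (w <= 0) next
    total <- total + p_core * (1 - oracle_no_core_prob(w, core))
  }
  total
}

# row-wise re-application of the filter rules, written independently
oracle_filter <- function(events, cfg, which = c("significant", "background")) {
  which <- match.arg(which)
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    t1 <- sum(events$ijc_1[[i]]) + sum(events$sjc_1[[i]])
    t2 <- sum(events$ijc_2[[i]]) + sum(events$sjc_2[[i]])
    counts_ok <- (t1 > cfg$min_total_count) || (t2 > cfg$min_total_count)
    keep[i] <- if (which == "significant") {
      counts_ok && events$fdr[i] < cfg$fdr_sig &&
        abs(events$delta_psi[i]) >= cfg$dpsi_sig
    } else {
      counts_ok && events$fdr[i] > cfg$fdr_bg &&
        abs(events$delta_psi[i]) < cfg$dpsi_bg
    }
  }
  events[keep, , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random gene/SE layout on one small chromosome, for the interval oracles
random_layout <- function(n_genes, n_ses, chrom_len = 100000,
                          cfg = screen_config(basal_up = 500, basal_down = 100,
                                              max_extension = 3000,
                                              proximal_window = 2000)) {
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n_genes)),
    symbol = sprintf("S%03d", seq_len(n_genes)),
    chrom = "chr1",
    tss = sort(sample.int(chrom_len - 1L, n_genes)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  start <- sample.int(chrom_len - 50L, n_ses)
  width <- sample(20:2000, n_ses, replace = TRUE)
  ses <- data.frame(chrom = "chr1", start = start,
                    end = pmin(start + width, chrom_len),
                    se_id = sprintf("SE%03d", seq_len(n_ses)),
                    stringsAsFactors = FALSE)
  list(genes = genes, ses = ses, cfg = cfg,
       chrom_sizes = c(chr1 = chrom_len))
}

# normalize an association mapping for comparison
sorted_assoc <- function(a) {
  if (length(a) == 0L) return(list())
  a <- lapply(a, function(x) sort(unname(x)))
  a[order(names(a))]
}
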