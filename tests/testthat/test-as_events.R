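# minimal event row builder in the read_rmats_table layout
make_event <- function(event_type = "SE", symbol = "Actn1", chrom = "chr1",
                       strand = "+", target = c(100, 200), up = c(0, 50),
                       down = c(300, 350), second = c(400, 450),
                       ijc_1 = c(30, 28, 35), sjc_1 = c(10, 9, 12),
                       ijc_2 = c(5, 6, 4), sjc_2 = c(20, 22, 18),
                       fdr = 0.01, pvalue = 0.001, delta_psi = 0.5) {
  ev <- data.frame(event_type = event_type, gene_id = "G1", symbol = symbol,
                   chrom = chrom, strand = strand,
                   target_start = target[1], target_end = target[2],
                   upstream_start = up[1], upstream_end = up[2],
                   downstream_start = down[1], downstream_end = down[2],
                   inc_form_len = 2L, skip_form_len = 1L,
                   pvalue = pvalue, fdr = fdr, delta_psi = delta_psi,
                   stringsAsFactors = FALSE)
  if (event_type == "MXE") {
    ev$second_start <- second[1]; ev$second_end <- second[2]
  }
  ev$ijc_1 <- I(list(ijc_1)); ev$sjc_1 <- I(list(sjc_1))
  ev$ijc_2 <- I(list(ijc_2)); ev$sjc_2 <- I(list(sjc_2))
  ev$inc_level_1 <- I(list(compute_psi(ijc_1, sjc_1)))
  ev$inc_level_2 <- I(list(compute_psi(ijc_2, sjc_2)))
  ev
}

test_that("PSI follows the effective-length-normalized formula", {
  expect_equal(compute_psi(30, 10, 1, 1), 0.75)
  expect_equal(compute_psi(0, 5, 1, 1), 0)
  expect_equal(compute_psi(20, 10, 2, 1), 0.5)
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(-1, 5), ">= 0")
  # scale invariance
  set.seed(3)
  for (i in 1:20) {
    ijc <- sample(0:500, 1); sjc <- sample(1:500, 1); k <- sample(2:9, 1)
    expect_equal(compute_psi(ijc, sjc, 2, 1),
                 compute_psi(k * ijc, k * sjc, 2, 1))
  }
})

test_that("significant and background filters apply count, FDR and dPSI rules", {
  cfg <- event_filter_config()
  kept <- make_event(ijc_1 = c(20, 20), sjc_1 = c(10, 10), fdr = 0.01,
                     delta_psi = 0.2)
  expect_equal(nrow(filter_significant(kept, cfg)), 1L)

  low_counts <- make_event(ijc_1 = c(10, 5), sjc_1 = c(10, 5),
                           ijc_2 = c(10, 10), sjc_2 = c(10, 10),
                           fdr = 0.001, delta_psi = 0.5)
  expect_equal(nrow(filter_significant(low_counts, cfg)), 0L)

  small_dpsi <- make_event(fdr = 0.04, delta_psi = 0.09)
  expect_equal(nrow(filter_significant(small_dpsi, cfg)), 0L)
  boundary <- make_event(fdr = 0.04, delta_psi = 0.10)
  expect_equal(nrow(filter_significant(boundary, cfg)), 1L)

  expect_equal(nrow(filter_background(
    make_event(fdr = 0.5, delta_psi = 0.01), cfg)), 1L)
  expect_equal(nrow(filter_background(
    make_event(fdr = 0.5, delta_psi = 0.06), cfg)), 0L)
  expect_equal(nrow(filter_background(
    make_event(fdr = 0.08, delta_psi = 0.0), cfg)), 0L)
})

test_that("filters match the brute-force oracle and are mutually exclusive", {
  cfg <- event_filter_config()
  for (seed in c(2, 9)) {
    tabs <- make_rmats_tables(sim_config(seed = seed, n_congruent = 40,
                                         n_reciprocal = 20, n_null = 80))
    for (tab in list(tabs$table_a, tabs$table_b)) {
      sig <- filter_significant(tab, cfg)
      bg <- filter_background(tab, cfg)
      expect_identical(rownames(sig), rownames(oracle_filter(tab, cfg, "significant")))
      expect_identical(rownames(bg), rownames(oracle_filter(tab, cfg, "background")))
      expect_length(intersect(event_uid(sig), event_uid(bg)), 0L)
    }
  }
})

test_that("event uids encode type, gene and exon coordinates", {
  ev <- make_event()
  expect_equal(event_uid(ev), "SE|Actn1|chr1:+|100-200|0-50|300-350")
  mxe <- make_event(event_type = "MXE")
  expect_equal(event_uid(mxe),
               "MXE|Actn1|chr1:+|100-200|0-50|300-350|400-450")
  # same event through a file round trip keeps its uid
  f <- withr::local_tempfile()
  write_rmats_table(ev, f)
  expect_identical(event_uid(read_rmats_table(f, "SE")), event_uid(ev))
  # injectivity: perturbing any single field changes the uid
  set.seed(11)
  base <- make_event()
  for (field in c("event_type", "symbol", "chrom", "strand", "target_start",
                  "target_end", "upstream_start", "upstream_end",
                  "downstream_start", "downstream_end")) {
    e <- base
    e[[field]] <- if (is.numeric(e[[field]])) e[[field]] + 7L else
      paste0(e[[field]], "x")
    if (field == "event_type") e[[field]] <- "RI"
    expect_false(event_uid(e) == event_uid(base), label = field)
  }
  bad <- make_event(); bad$target_start <- NA
  expect_error(event_uid(bad), "missing")
})

test_that("event overlap produces a conserved Venn partition with matched dPSI", {
  mk <- function(ids, dpsi) {
    do.call(rbind, lapply(seq_along(ids), function(i)
      make_event(target = c(ids[i] * 10, ids[i] * 10 + 5),
                 delta_psi = dpsi[i])))
  }
  a <- mk(1:3, c(0.2, 0.3, -0.4))
  b <- mk(2:4, c(0.25, 0.35, 0.5))
  ov <- overlap_events(list(A = a, B = b))
  expect_equal(unname(ov$counts[c("A", "A&B", "B")]), c(1L, 2L, 1L))
  expect_equal(sum(ov$counts), length(unique(c(event_uid(a), event_uid(b)))))
  pair <- ov$pairs[["A&B"]]
  expect_equal(nrow(pair), 2L)
  expect_equal(pair$dpsi_A, c(0.3, -0.4))
  expect_equal(pair$dpsi_B, c(0.25, 0.35))
  expect_equal(pair$concordant, c(TRUE, FALSE))

  # three sets sharing one uid count once in the center
  c3 <- mk(3, 0.1)
  ov3 <- overlap_events(list(A = a, B = b, C = c3))
  expect_equal(unname(ov3$counts["A&B&C"]), 1L)
  # disjoint sets have no pairwise overlap
  d <- mk(10:11, c(0.1, 0.2))
  ovd <- overlap_events(list(A = a, D = d))
  expect_false("A&D" %in% names(ovd$counts))
  expect_equal(nrow(ovd$pairs[["A&D"]]), 0L)
  # duplicated uid within one set is an error
  expect_error(overlap_events(list(A = rbind(a, a[1, ]), B = b)), "duplicate")
})

test_that("delta-PSI correlation recovers exact linear relations", {
  x <- c(-0.5, -0.1, 0.2, 0.4)
  r <- delta_psi_correlation(x, x)
  expect_equal(r$r, 1); expect_equal(r$r2, 1)
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0)
  r2 <- delta_psi_correlation(x, -x)
  expect_equal(r2$r, -1)
  expect_error(delta_psi_correlation(x, rep(0.1, 4)), "variance")
  expect_error(delta_psi_correlation(x[1:2], x[1:2]), "3 complete")
})

test_that("clustering standardizes rows and recovers planted blocks", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 2, byrow = TRUE)
  cl <- cluster_psi(m)
  expect_equal(cl$row_hclust$height[1], 0)
  expect_true(all(abs(rowMeans(cl$z_matrix)) < 1e-12))

  # two opposite row blocks separate at k = 2
  set.seed(4)
  up <- matrix(rep(c(0.2, 0.2, 0.8, 0.8), 5), 5, 4, byrow = TRUE) +
    matrix(rnorm(20, 0, 0.02), 5, 4)
  dn <- matrix(rep(c(0.8, 0.8, 0.2, 0.2), 5), 5, 4, byrow = TRUE) +
    matrix(rnorm(20, 0, 0.02), 5, 4)
  mat <- rbind(up, dn)
  cl2 <- cluster_psi(mat)
  groups <- stats::cutree(cl2$row_hclust, k = 2)
  expect_equal(length(unique(groups[1:5])), 1L)
  expect_equal(length(unique(groups[6:10])), 1L)
  expect_true(groups[1] != groups[6])
  # column clustering separates the planted conditions
  colgroups <- stats::cutree(cl2$col_hclust, k = 2)
  expect_equal(colgroups[1], colgroups[2])
  expect_equal(colgroups[3], colgroups[4])
  expect_true(colgroups[1] != colgroups[3])

  # constant rows are flagged, left at zero
  m3 <- rbind(c(1, 1, 1), c(0.5, 0.5, 0.5), c(0, 1, 2))
  cl3 <- cluster_psi(m3)
  expect_equal(cl3$constant_rows, c(1L, 2L))
  expect_true(all(cl3$z_matrix[1:2, ] == 0))
  # all-missing row errors
  m4 <- rbind(c(NA, NA, NA), c(0, 1, 2))
  expect_error(cluster_psi(m4), "no observed PSI")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})
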