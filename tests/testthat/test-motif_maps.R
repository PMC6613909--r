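spec <- motif_spec()

test_that("dicluster scanning finds spacer-constrained pairs, smallest spacer first", {
  m <- scan_motif("CACACAC", spec)
  expect_equal(m$start, 1L)
  expect_equal(m$spacer, 1L)
  expect_equal(m$end, 7L)

  expect_equal(nrow(scan_motif("CACCAC", spec)), 0L)  # spacer 0 not allowed
  expect_equal(nrow(scan_motif(paste0("CAC", strrep("T", 13), "CAC"), spec)), 0L)

  m2 <- scan_motif("CACTCACTCAC", spec)
  expect_equal(m2$start, c(1L, 5L))
  expect_equal(m2$spacer, c(1L, 1L))

  expect_equal(nrow(scan_motif("", spec)), 0L)
  expect_equal(nrow(scan_motif("CANACAC", spec)), 0L)  # N never matches
})

test_that("scanning agrees with the double-loop oracle on random sequences", {
  set.seed(101)
  for (i in 1:200) {
    # CA-rich alphabet so diclusters actually occur
    n <- sample(10:300, 1)
    s <- paste(sample(c("C", "A", "G", "T"), n, replace = TRUE,
                      prob = c(.4, .35, .15, .1)), collapse = "")
    got <- scan_motif(s, spec)
    ora <- oracle_scan_motif(s)
    expect_equal(nrow(got), nrow(ora), label = paste("seq", i))
    expect_equal(as.integer(got$start), as.integer(ora$start))
    expect_equal(as.integer(got$end), as.integer(ora$end))
    expect_equal(as.integer(got$spacer), as.integer(ora$spacer))
  }
})

test_that("match counts are invariant under region splits no match spans", {
  left <- "TTTCACTCACTTT"        # one match wholly inside
  right <- "TTTTTTTTTTTCACTCACTT"  # far enough that nothing spans the seam
  whole <- paste0(left, right)
  m_whole <- scan_motif(whole, spec)
  m_split <- rbind(scan_motif(left, spec),
                   within(scan_motif(right, spec), {
                     end <- end + nchar(left); start <- start + nchar(left)
                   }))
  expect_equal(nrow(m_whole), nrow(m_split))
  expect_setequal(m_whole$start, m_split$start)
})

test_that("region densities split each region into thirds, remainder last", {
  # diclusters starting at positions 10 and 240 of a 250 nt flank
  flank <- strsplit(strrep("T", 250), "")[[1]]
  flank[10:16] <- c("C", "A", "C", "G", "C", "A", "C")
  flank[240:246] <- c("C", "A", "C", "G", "C", "A", "C")
  ev <- data.frame(event_id = "e1", group = "up",
                   upstream_flank = paste(flank, collapse = ""),
                   exon = strrep("T", 135),
                   downstream_flank = strrep("T", 250))
  rd <- region_density(ev, spec, motif_map_config())
  expect_equal(unname(rd$count[1, c("upstream_first", "upstream_middle",
                                    "upstream_last")]), c(1, 0, 1))
  expect_equal(unname(rd$lengths[1, c("upstream_first", "upstream_middle",
                                      "upstream_last")]), c(83, 83, 84))
  expect_equal(unname(rd$density[1, "upstream_first"]), 1 / 83)
  expect_true(all(rd$count[1, grep("exon|downstream", colnames(rd$count))] == 0))

  # 3-nt region: thirds of 1 nt each
  tiny <- data.frame(event_id = "e2", group = "up",
                     upstream_flank = "ACG", exon = "CAC",
                     downstream_flank = "TTT")
  rd2 <- region_density(tiny, spec, motif_map_config())
  expect_equal(unname(rd2$lengths[1, c("exon_first", "exon_middle",
                                       "exon_last")]), c(1, 1, 1))
  expect_true(all(rd2$count[1, ] == 0))
})

test_that("long exons are scanned as splice-site-anchored halves", {
  # dicluster in the exon middle must not be counted when the exon is long
  exon <- paste0(strrep("T", 68), "CACACAC", strrep("G", 200))
  ev <- data.frame(event_id = "e1", group = "up",
                   upstream_flank = strrep("T", 250), exon = exon,
                   downstream_flank = strrep("T", 250))
  rd <- region_density(ev, spec, motif_map_config())
  expect_true(all(rd$count[1, grep("exon", colnames(rd$count))] == 0))
  expect_equal(unname(rd$lengths[1, "exon_first"]), 45)  # 135 / 3
})

test_that("enrichment is symmetric when regulated equals background", {
  set.seed(5)
  ev <- data.frame(event_id = sprintf("e%d", 1:12), group = "up",
                   upstream_flank = replicate(12, random_dna(250)),
                   exon = replicate(12, random_dna(100)),
                   downstream_flank = replicate(12, random_dna(250)))
  res <- thirds_enrichment(ev, ev, spec,
                           motif_map_config(n_perm_enrich = 200, seed = 3))
  expect_equal(res$score, rep(1, 9))
  # randomized tie-breaking keeps the test exact, so the degenerate
  # identical-input case gives large (not exactly 1) p-values; identical
  # inputs must never be called significant
  expect_true(all(res$p_value > 0.05))
  expect_gt(stats::median(res$p_value), 0.5)
  expect_error(thirds_enrichment(ev[0, ], ev, spec), "non-empty")
})

test_that("planted downstream diclusters are detected as enrichment", {
  cfg <- sim_config(seed = 21, n_events = c(up = 50, down = 50,
                                            unregulated = 150))
  seqs <- make_event_sequences(cfg)
  ev <- seqs$events
  res <- thirds_enrichment(ev[ev$group == "up", ],
                           ev[ev$group == "unregulated", ], spec,
                           motif_map_config(n_perm_enrich = 1000, seed = 9))
  dn <- res[grepl("downstream", res$region), ]
  expect_true(all(dn$direction == "enriched"))
  expect_true(all(dn$p_value < 0.05))
})

test_that("RNA maps mark planted regions and stay quiet on identical input", {
  set.seed(8)
  ev <- data.frame(event_id = sprintf("e%d", 1:20), group = "up",
                   upstream_flank = replicate(20, random_dna(250)),
                   exon = replicate(20, random_dna(120)),
                   downstream_flank = replicate(20, random_dna(250)))
  m <- rna_map(list(up = ev), ev, spec,
               motif_map_config(n_perm_map = 200, seed = 4))
  expect_false(any(m$up$significant))
  expect_true(all(m$up$p_value == 1))
  expect_true(all(m$up$coverage >= 0 & m$up$coverage <= 1))

  cfg <- sim_config(seed = 31, n_events = c(up = 50, down = 50,
                                            unregulated = 150))
  seqs <- make_event_sequences(cfg)
  evs <- seqs$events
  mp <- rna_map(list(up = evs[evs$group == "up", ]),
                evs[evs$group == "unregulated", ], spec,
                motif_map_config(n_perm_map = 500, seed = 4))
  up <- mp$up
  expect_gt(sum(up$significant[up$region == "downstream"]), 0)
  # false-positive positions outside the planted flank stay near alpha
  other <- up$significant[up$region != "downstream"]
  expect_lt(mean(other), 0.15)
})

test_that("RNA maps are reproducible and tolerate short exons", {
  set.seed(12)
  mk <- function(n, exon_len) {
    data.frame(event_id = sprintf("e%d", seq_len(n)), group = "up",
               upstream_flank = replicate(n, random_dna(250)),
               exon = replicate(n, random_dna(exon_len)),
               downstream_flank = replicate(n, random_dna(250)))
  }
  grp <- mk(10, 40)   # exon much shorter than the 135 nt scan
  bg <- mk(30, 40)
  cfg <- motif_map_config(n_perm_map = 100, bg_downsample = 20, seed = 77)
  m1 <- rna_map(list(up = grp), bg, spec, cfg)
  m2 <- rna_map(list(up = grp), bg, spec, cfg)
  expect_identical(m1, m2)
  exon_cov <- m1$up$coverage[m1$up$region == "exon"]
  expect_true(all(exon_cov >= 0 & exon_cov <= 1))
  expect_warning(rna_map(list(up = mk(3, 40)), bg, spec, cfg), "fewer than 5")
})
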