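#' Default pipeline configuration
#'
#' Nested configuration covering every stage: the association-rule screen,
#' the motif specification, RNA-map settings, event filters and the
#' synthetic-data generator. Values default to the method's canonical
#' parameters.
#'
#' @param seed Global seed; each stage derives its own sub-seed with
#'   [stage_seed()].
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    screen = unclass(screen_config()),
    motif = unclass(motif_spec()),
    map = unclass(motif_map_config()),
    filter = unclass(event_filter_config()),
    sim = lapply(unclass(sim_config()), identity)
  ), class = "pipeline_config")
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys at any level are rejected; omitted keys keep their
#' defaults.
#'
#' @param path Path to a YAML file whose top-level keys are a subset of
#'   `seed`, `screen`, `motif`, `map`, `filter`, `sim`.
#' @param seed Optional seed overriding the file's.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  merge_level <- function(base, override, where) {
    unknown <- setdiff(names(override), names(base))
    if (length(unknown) > 0L) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    }
    for (k in names(override)) {
      if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
          is.list(override[[k]])) {
        base[[k]] <- merge_level(base[[k]], override[[k]],
                                 paste0(where, "$", k))
      } else {
        base[[k]] <- override[[k]]
      }
    }
    base
  }
  cfg <- merge_level(cfg, user, "config")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' Derive a per-stage sub-seed from the global seed
#'
#' Deterministic fan-out so each pipeline stage has an independent,
#' reproducible RNG stream.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (string).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

restore_cfg <- function(lst, cls) {
  structure(lst, class = cls)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, screen, motifmap and events stages with the given
#' configuration, writing all outputs (BED per tissue, gene and RBP
#' tables, event sequences, rMATS-dialect tables, screen report,
#' enrichment and RNA-map tracks, filtered/overlap/correlation/cluster
#' tables) plus a manifest with an MD5 content hash per file.
#'
#' @param config A [pipeline_config()] (or list from
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_all <- function(config = pipeline_config(), out_dir = tempfile("sesplice_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- restore_cfg(config$screen, "screen_config")
  spec <- restore_cfg(config$motif, "motif_spec")
  mcfg <- restore_cfg(config$map, "motif_map_config")
  fcfg <- restore_cfg(config$filter, "event_filter_config")
  sim <- restore_cfg(config$sim, "sim_config")

  # ---- simulate ----------------------------------------------------------
  sim$seed <- stage_seed(config$seed, "simulate")
  genome <- make_genome(sim)
  ses <- make_superenhancers(genome$genes, sim)
  seqs <- make_event_sequences(sim)
  tabs <- make_rmats_tables(sim)
  expr <- make_expression(genome$genes, sim)
  write_gene_table(genome$genes, file.path(out_dir, "genes.tsv"))
  writeLines(make_rbp_catalog(genome$genes, sim),
             file.path(out_dir, "rbp_catalog.txt"))
  for (t in unique(ses$tissue)) {
    sub <- ses[ses$tissue == t, , drop = FALSE]
    write_bed(data.frame(chrom = sub$chrom, start = sub$start,
                         end = sub$end, name = sub$se_id),
              file.path(out_dir, paste0("se_", t, ".bed")))
  }
  fa <- c(stats::setNames(seqs$events$upstream_flank,
                          paste0(seqs$events$event_id, "|upstream")),
          stats::setNames(seqs$events$exon,
                          paste0(seqs$events$event_id, "|exon")),
          stats::setNames(seqs$events$downstream_flank,
                          paste0(seqs$events$event_id, "|downstream")))
  write_fasta(fa, file.path(out_dir, "event_sequences.fa"))
  write_tsv(seqs$events[, c("event_id", "group")],
            file.path(out_dir, "event_groups.tsv"))
  write_tsv(seqs$truth, file.path(out_dir, "truth_motifs.tsv"))
  write_rmats_table(tabs$table_a, file.path(out_dir, "comparisonA.SE.MATS.JC.txt"))
  write_rmats_table(tabs$table_b, file.path(out_dir, "comparisonB.SE.MATS.JC.txt"))
  write_tsv(tabs$truth, file.path(out_dir, "truth_events.tsv"))
  write_tsv(data.frame(symbol = rownames(expr$values), expr$values,
                       check.names = FALSE),
            file.path(out_dir, "expression.tsv"))
  write_tsv(expr$truth, file.path(out_dir, "truth_expression.tsv"))

  # ---- screen ------------------------------------------------------------
  genes <- read_gene_table(file.path(out_dir, "genes.tsv"))
  catalog <- read_rbp_catalog(file.path(out_dir, "rbp_catalog.txt"))
  domains <- extend_domains(genes, scfg, genome$chrom_sizes)
  tissues <- c(sim$tissues, sim$outlier)
  sets_dom <- sets_prox <- list()
  for (t in tissues) {
    bed <- read_bed(file.path(out_dir, paste0("se_", t, ".bed")))
    bed$se_id <- bed$name
    sets_dom[[t]] <- associated_symbols(associate_by_domain(bed, domains), genes)
    sets_prox[[t]] <- associated_symbols(
      associate_by_proximity(bed, genes, scfg), genes)
  }
  rep_dom <- candidate_screen(sets_dom[sim$tissues], sets_dom[[sim$outlier]],
                              catalog)
  rep_prox <- candidate_screen(sets_prox[sim$tissues], sets_prox[[sim$outlier]],
                               catalog)
  consensus <- consensus_candidates(rep_dom$rbp_candidates,
                                    rep_prox$rbp_candidates)
  ranked <- rank_candidates(rep_dom$rbp_candidates, expr$values,
                            expr$conditions, "tissue", "culture")
  screen_report <- data.frame(
    section = c(rep("domain_candidates", length(rep_dom$rbp_candidates)),
                rep("proximity_candidates", length(rep_prox$rbp_candidates)),
                rep("consensus", length(consensus)),
                rep("ranked", nrow(ranked))),
    symbol = c(rep_dom$rbp_candidates, rep_prox$rbp_candidates, consensus,
               ranked$symbol),
    stringsAsFactors = FALSE)
  write_tsv(screen_report, file.path(out_dir, "screen_report.tsv"))
  write_tsv(ranked, file.path(out_dir, "screen_ranked.tsv"))

  # ---- motifmap ----------------------------------------------------------
  mcfg$seed <- stage_seed(config$seed, "motifmap")
  ev <- seqs$events
  regulated <- ev[ev$group %in% c("up", "down"), , drop = FALSE]
  background <- ev[ev$group == "unregulated", , drop = FALSE]
  enrich <- thirds_enrichment(regulated, background, spec, mcfg)
  write_tsv(enrich, file.path(out_dir, "thirds_enrichment.tsv"))
  maps <- rna_map(split(ev[ev$group != "unregulated", ],
                        ev$group[ev$group != "unregulated"]),
                  background, spec, mcfg)
  track <- do.call(rbind, lapply(names(maps), function(g)
    cbind(group = g, maps[[g]])))
  write_tsv(track, file.path(out_dir, "rna_map.tsv"))

  # ---- events ------------------------------------------------------------
  ta <- read_rmats_table(file.path(out_dir, "comparisonA.SE.MATS.JC.txt"), "SE")
  tb <- read_rmats_table(file.path(out_dir, "comparisonB.SE.MATS.JC.txt"), "SE")
  sig_a <- filter_significant(ta, fcfg)
  sig_b <- filter_significant(tb, fcfg)
  ov <- overlap_events(list(A = sig_a, B = sig_b))
  venn <- data.frame(region = names(ov$counts), count = unname(ov$counts))
  write_tsv(venn, file.path(out_dir, "venn_counts.tsv"))
  pair <- ov$pairs[["A&B"]]
  write_tsv(pair, file.path(out_dir, "overlap_pairs.tsv"))
  corr <- if (nrow(pair) >= 3L)
    delta_psi_correlation(pair$dpsi_A, pair$dpsi_B)
  else data.frame(n = nrow(pair), r = NA, r2 = NA, slope = NA,
                  intercept = NA, p = NA)
  write_tsv(corr, file.path(out_dir, "dpsi_correlation.tsv"))
  sig_events <- sig_a
  psi_mat <- t(vapply(seq_len(nrow(sig_events)), function(i)
    c(sig_events$inc_level_1[[i]], sig_events$inc_level_2[[i]]),
    numeric(2L * sim$n_replicates)))
  clust <- NULL
  if (nrow(psi_mat) >= 2L) {
    rownames(psi_mat) <- event_uid(sig_events)
    colnames(psi_mat) <- c(paste0("cond1_", seq_len(sim$n_replicates)),
                           paste0("cond2_", seq_len(sim$n_replicates)))
    clust <- cluster_psi(psi_mat)
    write_tsv(data.frame(uid = rownames(psi_mat)[clust$row_order]),
              file.path(out_dir, "cluster_row_order.tsv"))
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[manifest$file != "manifest.tsv", , drop = FALSE]
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(screen = list(domain = rep_dom, proximity = rep_prox,
                               consensus = consensus, ranked = ranked),
                 enrichment = enrich, maps = maps,
                 events = list(significant_a = sig_a, significant_b = sig_b,
                               venn = venn, correlation = corr,
                               clustering = clust),
                 manifest = manifest, out_dir = out_dir))
}
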