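# sesplice

Tissue-specific master regulators of alternative splicing tend to sit next
to the super-enhancers that define a cell's identity. `sesplice`
implements, as a tested and reusable R pipeline, the computational screen
that exploits this: find the RNA-binding protein (RBP) genes that are
super-enhancer-associated in every target tissue but not in an outlier
tissue, rank the candidates by expression behavior, and then characterize
the candidate's splicing program from motif geometry around regulated
exons and from rMATS-style differential-splicing tables. The motivating
use case is smooth muscle, where this logic singles out RBPMS — a
dimerizing RBP whose optimal binding element is a pair of CAC
trinucleotides separated by a short spacer (CACN<sub>1-12</sub>CAC) — but
every stage is generic and configurable.

The package is aimed at regulatory genomicists and splicing biologists who
have per-tissue super-enhancer BED files, a gene annotation, an RBP
catalog, exon/flank sequences, and rMATS junction-count tables — or who
want to validate the statistics on synthetic data first: a first-class
generator produces every input with planted ground truth.

## What it computes

**Regulatory-domain association (GREAT-style).** Each gene gets a
strand-aware basal domain around its TSS (default 5 kb upstream / 1 kb
downstream) extended on each side to the nearer of the closest other
gene's basal-domain boundary or ±1 Mb; a super-enhancer is associated with
every gene whose extended domain it overlaps. A stricter dbSUPER-style
rule assigns each enhancer to the single closest TSS within 50 kb.

**The candidate screen.** With target tissues *T₁…Tₖ*, outlier *O* and an
RBP catalog *R*, candidates are (∩ᵢ genes(Tᵢ)) \\ genes(O) ∩ *R*, matched
on upper-cased symbol; a consensus is the intersection of the two
association rules' candidate sets, and candidates are ranked by mean
abundance among those down-regulated from tissue to culture.

**Motif statistics.** `scan_motif()` finds spacer-constrained dimeric
motifs (CACN<sub>1-12</sub>CAC by default; one match per start, smallest
spacer). `thirds_enrichment()` splits the upstream flank (250 nt), the
scanned exon (135 nt, splice-site-anchored halves) and the downstream
flank into thirds and reports, per third, the regulated/background
density ratio with a two-sided permutation p-value (label reshuffles,
50,000 by default, with randomized tie-breaking so the discrete statistic
stays calibrated). `rna_map()` builds positional motif-coverage tracks
(sliding window 31 nt) for each event group against a background
downsampled to 2,000 events, with per-position permutation significance
(1,000 reshuffles, p < 0.05).

**rMATS post-processing.** PSI from junction counts,
PSI = (IJC/incLen) / (IJC/incLen + SJC/skipLen); significant events
(total counts > 50 in a condition, FDR < 0.05, |ΔPSI| ≥ 10%) and
unregulated background events (FDR > 0.1, |ΔPSI| < 5%); reproducible
event IDs from type, symbol and exon coordinates; Venn overlaps across
comparisons with sign-concordance; Pearson ΔPSI correlation; and Z-scored
hierarchical clustering of PSI matrices.

## Worked example

Everything below runs offline on synthetic data with planted truth:

```r
library(sesplice)

cfg <- sim_config(seed = 42)          # 3 target tissues + 1 outlier
g   <- make_genome(cfg)
ses <- make_superenhancers(g$genes, cfg)
dom <- extend_domains(g$genes, screen_config(), g$chrom_sizes)
sets <- lapply(split(ses, ses$tissue), function(s)
  associated_symbols(associate_by_domain(s, dom), g$genes))
candidate_screen(sets[cfg$tissues], sets[[cfg$outlier]],
                 make_rbp_catalog(g$genes, cfg))
#> Super-enhancer RBP screen
#>   target tissues:         3
#>   target intersection:    4 genes
#>   after outlier removal:  1 genes
#>   RBP candidates:         RBPMS
```

Four genes are enhancer-associated in all three target tissues; removing
the outlier tissue's genes leaves one, and it is in the RBP catalog — the
planted regulator. Ranking by expression confirms it is the most abundant
down-regulated candidate (abundance 151, 4.8-fold down from tissue to
culture):

```r
expr <- make_expression(g$genes, cfg)
rank_candidates("RBPMS", expr$values, expr$conditions, "tissue", "culture")
#>   symbol abundance fold_change
#> 1  RBPMS  150.9631    4.803106
```

Motif geometry of repressed exons (planted: exon + exon-proximal 80 nt of
upstream intron):

```r
seqs <- make_event_sequences(sim_config(seed = 42,
          n_events = c(up = 60, down = 60, unregulated = 300)))
ev <- seqs$events
thirds_enrichment(ev[ev$group == "down", ], ev[ev$group == "unregulated", ],
                  motif_spec(), motif_map_config(n_perm_enrich = 5000, seed = 1))
#>               region score p_value direction
#>       upstream_first 1.581  0.2042  enriched
#>        upstream_last 3.560  0.0020  enriched
#>           exon_first 4.805  0.0080  enriched
#>            exon_last 4.400  0.0162  enriched
#>     downstream_first 0.542  0.0984  depleted
#>     ...
```

The exon thirds and the exon-adjacent upstream third are significantly
enriched (3.6-4.8x), the downstream flank is not — exactly the planted
geometry. `run_all(pipeline_config(seed), out_dir)` executes the whole
chain (simulate → screen → motifmap → events) and writes every table plus
an MD5-stamped manifest; a thin command-line wrapper lives at
`inst/cli/se_splice_screen.R`.

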