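---
title: "Methods: super-enhancer proximity screens and splicing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer proximity screens and splicing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sesplice)
```

# The screening model

The premise of the screen is that master regulators of a cell type's
splicing program are transcriptionally wired like other cell-identity
genes: driven by super-enhancers in the tissues where the program runs,
and not in closely related tissues where it does not. The screen
therefore needs only interval arithmetic and set algebra — no expression
modeling — which makes it robust but blunt: it cannot distinguish a
splicing regulator from any other super-enhancer-associated RBP, which is
why an expression-based ranking step follows.

## Regulatory domains

A gene's **basal domain** is a strand-aware window around the TSS:
`[tss - basal_up, tss + basal_down)` on the plus strand, mirrored on the
minus strand; defaults 5,000 bp upstream and 1,000 bp downstream. The
**extended domain** grows each side to the nearer of (a) the closest
other gene's basal-domain boundary on that side and (b)
`tss ± max_extension` (default 1 Mb), never shrinking below the gene's
own basal domain and clipped to the chromosome. Extension stops at
neighbor basal *boundaries*, not neighbor TSSs, irrespective of the
neighbor's strand; when a neighbor's basal domain overlaps the gene's
own, extension on that side is zero. A super-enhancer associates with
every gene whose extended domain it overlaps by at least 1 bp, so one
enhancer can serve several genes.

The stricter proximity rule assigns each enhancer to the single gene
whose TSS is closest to the enhancer interval — distance 0 if the TSS
lies inside it, otherwise the gap to the nearest edge — provided the
distance is at most `proximal_window` (default 50 kb). Ties between
equidistant TSSs break toward the lexicographically smaller gene id; this
case is essentially measure-zero on real annotations but the rule keeps
the output deterministic.

All coordinates are 0-based half-open (BED convention) everywhere inside
the package; 1-based dialects must be converted at the reader boundary.
Genes must enter with one TSS per gene: the association rules are
per-gene, so multi-TSS annotations have to be collapsed upstream.

## The candidate screen and ranking

With per-tissue associated-symbol sets, candidates are
`(∩ target sets) \ outlier set ∩ RBP catalog`, all matching on
upper-cased symbols (the practical reason: tissue enhancer gene lists and
RBP catalogs are symbol-keyed; stable ids rarely survive across such
sources). The consensus operation intersects the candidate sets of the
two association rules. Ranking keeps candidates whose mean abundance in
the high condition (tissue) exceeds `min_fold` times the mean in the low
condition (culture; `min_fold` defaults to 1, i.e. any decrease counts,
because the underlying biology states a direction, not an effect size)
and sorts by descending abundance in the high condition.

# Motif statistics

## The dicluster scanner

The scanner looks for two occurrences of a core (default `CAC`)
separated by a spacer of `spacer_min`–`spacer_max` nt (defaults 1–12),
the optimal element for a dimeric RBP such as RBPMS. One match is
recorded per start position, with the smallest qualifying spacer; without
that rule a single pair of CAC-rich stretches would be counted once per
alternative spacer and densities would be ill-defined. Matches at
different starts may overlap. `N` never matches. Match coordinates are
1-based inclusive, the R/Biostrings convention for within-sequence
positions (genomic intervals remain 0-based half-open).

## Region thirds and enrichment

Three regions are scanned per cassette-exon event: 250 nt of upstream
intron (ending at the 3' splice site), the exon, and 250 nt of
downstream intron. Exons longer than `exon_scan_len` (135 nt) are
represented by their splice-site-anchored halves (first 68 + last 67 nt):
regulation acts at splice sites, so anchoring there preserves the
positions that matter, whereas scanning the middle of a long exon would
dilute the signal. The two halves are scanned separately so no match is
fabricated across the junction. Each region splits into thirds by length,
remainder to the last third (any consistent rule would do; this one is
deterministic). The enrichment score per third is

```
score = (mean regulated density + eps) / (mean background density + eps)
```

with `eps = 1 / (flank_len × pooled event count)` guarding empty regions.
Significance is a two-sided permutation test on `|log score|`: group
labels of the pooled events are reshuffled (default 50,000 times) with
group sizes preserved, and `p = (1 + #exceedances) / (n_perm + 1)`.

Because per-event densities are ratios of small integers, the permutation
statistic is heavily tied, and tie-inclusive counting makes the test
conservative (measured type-I error ~0.013 at a nominal 0.05). The
package therefore adds an infinitesimal (≤ 1e-9), seeded, per-event
jitter that is used *only to rank* the statistic — randomized
tie-breaking, which makes a discrete permutation test exact. Reported
scores are computed from the unjittered densities. A region whose pooled
densities are all identical carries no information and is reported at
p = 1 rather than a random tie-broken value. One consequence worth
knowing: feeding the same events as both regulated and background yields
scores of exactly 1 but p-values that are merely large, not exactly 1.

## RNA maps

The positional map lays events on a composite axis: 250 nt upstream
flank (right-aligned at the 3' splice site), the exon's anchored halves,
and 250 nt downstream flank (left-aligned at the 5' splice site). Events
with shorter flanks or exons contribute only the positions they have —
missing positions are excluded from means, never fabricated. Per event,
a binary occupancy vector marks every nucleotide covered by a match;
occupancy is then smoothed with a centered sliding window (31 nt,
truncated at the axis ends), and coverage at a position is the mean of
the smoothed occupancy over the group's events, always in [0, 1]. The
unregulated background is downsampled without replacement to
`bg_downsample` (2,000) events when larger. Per-position significance
against the background uses the same label-reshuffling permutation
scheme (default 1,000 iterations, two-sided, significant at p < 0.05);
here ties are counted conservatively, which suppresses spurious
single-position calls — appropriate for a track whose consumers look for
sustained significant windows, not isolated positions. Groups smaller
than 5 events produce a warning but still a map.

# rMATS post-processing

PSI is the effective-length-normalized inclusion ratio
`(IJC/incLen) / (IJC/incLen + SJC/skipLen)`; both counts zero gives a
missing value. The read-count filter (total inclusion+skipping counts
above 50 across replicates in at least one condition) applies to the
significant *and* the background set alike, since it exists to remove
unreliable events before any downstream analysis. Significant events
additionally need FDR < 0.05 and |ΔPSI| ≥ 0.10; background events need
FDR > 0.1 and |ΔPSI| < 0.05. ΔPSI is condition 1 minus condition 2
throughout, with the condition order fixed per comparison — comparisons
in this field flip orientation between panels, and an explicit convention
prevents silent sign errors. Missing per-replicate PSI values are
excluded from means; events all-missing in a condition drop out of
correlation and clustering.

Event identity across comparisons uses a deterministic string of type,
symbol, chromosome, strand and the coordinates of the regulated and both
flanking exons (plus the second exon pair for mutually exclusive exons).
Venn overlaps are reported both as raw id overlap and with a
sign-concordance flag on each matched pair, since whether "shared"
should require the same ΔPSI direction is analysis-dependent. Clustering
Z-scores each event row (constant rows are flagged and left at zero — a
zero-variance row cannot be standardized), then runs agglomerative
clustering with Euclidean distance and complete linkage; the method
family is conventional for PSI heat maps and both choices are arguments.

# The synthetic-data generators

The generators produce every pipeline input with planted, recorded
ground truth, emulating the statistical structure of the real screen:

* **Genome/enhancers** — 60 genes on a 10 Mb chromosome, TSSs uniform
  with ≥ 10 kb spacing, one planted RBP mid-chromosome, six decoy RBPs
  ≥ 1 Mb away. Each target tissue gets an enhancer at the planted gene;
  the outlier gets none within 1 Mb of it. Decoys fail the screen by
  construction (half missing from one target tissue, half present in the
  outlier as well); noise enhancers land inside random non-RBP genes'
  basal domains, which pins their association to the host gene under
  both rules. Placement is re-verified post hoc by running the
  closest-TSS association and the screen.
* **Sequences** — i.i.d. uniform background; repressed ("down") events
  get CAC diclusters planted at 5/kb in the exon and in the 80 nt of
  upstream intron adjacent to the 3' splice site, activated ("up")
  events at 5/kb in the downstream flank, unregulated events at
  background rate. 5/kb sits well above the uniform-sequence chance rate
  (~2.7 diclusters per kb) without saturating a 250 nt flank.
* **Junction tables** — generative PSI in [0.25, 0.75] with effect sizes
  0.15–0.40; congruent events share ΔPSI sign and magnitude across the
  two comparisons, reciprocal events flip sign, null events are flat.
  Replicate PSI adds truncated Gaussian noise (sd 0.03); inclusion
  counts are Binomial(2 × depth, PSI) and skipping counts
  Binomial(depth, 1 − PSI) with effective lengths 2 and 1 — inclusion
  reads span two junctions, so this parameterization makes the PSI
  formula invert the generative model in expectation, and parameter
  recovery becomes a meaningful check. P-values come from a Welch test
  on replicate PSI with BH adjustment; this emulates a
  differential-splicing test and is *not* the rMATS likelihood model,
  which operates on counts and is deliberately out of scope.
* **Expression** — log-normal abundances; the planted RBP is the most
  abundant down-regulated candidate; housekeepers have fold change 1.

What passing on synthetic data does **not** show: real intron sequence is
far from i.i.d. uniform (repeats, compositional bias, branch points), so
real-data enrichment scores will sit on a different baseline; real
super-enhancer catalogs contain overlapping and multi-gene enhancers at
rates the generator does not mimic; and real rMATS FDRs come from a
count-based likelihood test with different power. The synthetic suite
validates the algorithms and their calibration, not effect sizes in any
particular tissue.

# Numerical and testing choices

Every stochastic routine takes an explicit seed; the pipeline driver
derives one sub-seed per stage from the global seed so stages are
independently reproducible, and `run_all()` writes an MD5 manifest of
every output. The test suite checks the interval machinery against a
per-basepair scanning oracle (200 random layouts of up to 200 genes and
enhancers), the scanner against double-loop enumeration (1,000 random
sequences up to 300 nt), permutation calibration on 500 null splits at
200 permutations each, RNA-map localization on 20 seeded planted
instances at 500 permutations (a detected region is a run of ≥ 31
consecutive significant positions, one window length — isolated
positions at the nominal false-positive rate are expected and ignored),
and concordance/PSI recovery on the generator's defaults (depth 100,
noise 0.03, 100 congruent events). These sizes keep the full suite under
a few minutes while leaving the statistical margins wide; they are choices
of the package, and all scale up through the corresponding configuration
objects.

# Known limitations

* GREAT's "curated regulatory domains" flag is not implemented: no
  public per-gene curation table exists, so only the basal-plus-extension
  rule is reproduced. Candidate lists on real data can differ slightly
  from tools that include the curation.
* The enrichment statistic is a mean per-nt density ratio; the MATT
  suite's "quant mode" statistic is not publicly specified and may
  weight events differently. The density ratio is the stated, tested
  choice.
* RNA maps do not weight events by |ΔPSI|; all regulated events count
  equally.
* Liftover between genome builds, enhancer calling from ChIP signal,
  GTF parsing and the rMATS statistical test itself are out of scope;
  those inputs arrive as files in the documented dialects.
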