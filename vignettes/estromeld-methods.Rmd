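---
title: "Harmonizing ER-modulator transcriptomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing ER-modulator transcriptomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estromeld)
```

## The problem

Hundreds of published experiments measure how estrogen-receptor (ER)
modulators — SERMs such as tamoxifen, SERDs such as fulvestrant, covalent
SERCAs, PROTAC-style degraders — and endocrine-resistance models (tamoxifen
resistance, long-term estradiol deprivation, *ESR1* hotspot mutants)
reshape breast-cancer transcriptomes. The individual studies differ in
platform (RNA-seq vs microarray), cell line, dose, duration, and batch
structure, so their fold-change tables cannot be pooled directly.
`estromeld` harmonizes each treated-vs-control comparison onto a common
scale and then asks cross-comparison questions: which genes respond
consistently, which diverge between drug classes or between cell-model
construction methods, which experimental covariates explain the variation,
and whether consensus signatures classify clinical-style cohorts.

## The regulatory percentile

Each comparison's per-gene log2 fold changes are rank-scaled into
**regulatory percentiles** in [-100, +100]: genes with positive fold change
are ranked within the up pool and mapped to (0, 100] (the most up-regulated
gene is exactly +100), negative genes are ranked by magnitude within the
down pool and mapped to [-100, 0) (the most down-regulated gene is exactly
-100), and unchanged genes stay at 0. Ties take mid-ranks, so the transform
is order-independent; a strictly monotone, sign-preserving distortion of
the fold changes — exactly the kind of difference RNA-seq and array
pipelines introduce — leaves the percentiles untouched. That invariance is
why rank scaling, rather than linear scaling of the fold change itself, is
the primary convention (`percentile_rank(scale = "fc")` provides the linear
alternative). A gene absent from a platform is *missing*, never 0: the two
states carry different information and are kept distinct throughout.
Sections are filtered with an 80% presence rule before pooled statistics
(genes observed in exactly 80% of a section's comparisons are retained; the
filter is idempotent).

## Cross-comparison statistics

* **Heterogeneity** per gene is `log10((sd/|mean|)^2)` over a scope of
  comparisons; two scopes (e.g. tamoxifen vs fulvestrant experiments) are
  contrasted with a two-sided Mann-Whitney test. Genes with zero mean or
  zero variance are excluded and reported rather than silently dropped.
* **Profile correlation** averages percentiles per group (compound, cell
  line), computes Pearson r on pairwise-complete genes, and orders leaves
  by average-linkage clustering on 1 - r.
* **Concordance quadrants** split genes at boundary-inclusive average
  percentiles of +/-25; **discordance calls** use a strict
  |delta percentile| > 70 between two profiles.
* **Bidirectional genes** sit in the top decile of up-regulation
  (percentile >= +90) in at least 15% of comparisons *and* the top decile
  of down-regulation in at least 15%; **consensus targets** sit in the top
  decile of one direction in at least 50% of comparisons. Both fractions
  use comparisons where the gene is non-missing as the denominator —
  otherwise platform gene-universe differences would penalize array-absent
  genes — and both boundaries are inclusive ("at least").
* **Ligand-dependence gating** compares a resistance-model average against
  an estrogen-treatment average: ligand-independent genes exceed +/-50 in
  both; de novo genes exceed +50 in the model while the estrogen average
  sits within +/-15. The 50 cut is the default; 40 is also in circulation
  for this gate and both are exposed.
* **Per-gene mixed models** regress a gene's percentile on cell line,
  sequencing modality, and drug class x treatment duration with a random
  intercept per batch (a batch groups comparisons sharing a control set).
  Duration enters in hours, centered at the mean observed duration so the
  drug main effect is reported at a representative duration instead of an
  extrapolation to 0 h. Terms reduced to a single level are dropped with a
  warning; single-batch designs fall back to an ordinary linear model;
  singular or non-converged fits are flagged, never raised. P-values come
  from Satterthwaite approximation (lmerTest) and are BH-adjusted across
  genes by the caller.

## Enrichment statistics

Over-representation uses the one-sided Fisher exact test on the 2x2 table
against a finite universe with BH adjustment. Preranked GSEA is the
weighted Kolmogorov-Smirnov statistic: genes sorted by the ranking metric,
hits incrementing proportionally to |metric|^weight, misses decrementing
uniformly; the enrichment score is the maximum deviation of the running
sum. Defaults mirror common practice for this analysis: set-size bounds
5-1000, 1000 gene-label permutations, seed 6, weight 1 (weight 0 recovers
the classic unweighted KS statistic). NES divides the observed score by
the mean magnitude of same-sign permutation scores; the FDR follows the
sign-stratified permutation convention of the GSEA method family. Two
numerical details are worth stating: a set covering the whole universe has
score 0 by construction, and when the maximal positive and negative
deviations tie in magnitude exactly (possible because miss decrements are
rational) the positive deviation is reported, making the statistic
deterministic.

The single-sample signature score is deliberately simple: within-sample
ranks are z-scored and averaged over the set genes. It is monotone (raising
every set gene's expression in a sample cannot lower the score), zero for
constant samples, and free of distributional assumptions — all the
downstream classification stage needs from a set-level score. It is not
GSVA; it is a rank-z scorer with a compatible interface. Signature fold
changes (browser "Mode 2") use the geometric mean of signature-gene
expression per sample, a treated/control ratio of group means, and a
two-sided Welch test on log signature values (the test is a documented
choice; a +1 offset is applied when non-positive values occur, as with some
array intensities). The Oncotype DX weighted impact applies the published
recurrence-score coefficients (0.47 HER2, -0.34 ER, +1.04 Proliferation,
+0.1 Invasion, +0.05 CD68, -0.08 GSTM1, -0.07 BAG1) to group-mean
regulatory percentiles; CTSL2 and GUS are excluded from the panel.

## Peak-set algebra and regulatory potential

Coordinates are BED 0-based half-open throughout. A case peak is *gained*
when it shares fewer than `min_overlap_bp` (default 1) bases with every
control peak. Regulatory potential sums, over peaks whose midpoint lies
within 100 kb of a gene's TSS, the decay weight `exp(-(0.5 + 4d))` with
`d` the TSS distance as a fraction of the window — `exp(-0.5)` at the TSS,
`exp(-4.5)` at the window edge, 0 beyond. The exponential form follows the
binding-and-expression-target style of TSS scoring; because published
descriptions of that tool do not pin the kernel down, it is a configurable,
documented choice (`linear` and `flat` alternatives are built in), and peak
position is the interval midpoint since summit columns are not guaranteed
in ingested BED files. The browser-style TSS view reports signed offsets in
a +/-200 kb window, negative meaning upstream in the gene's orientation.

## The synthetic-data generator

Every pipeline stage is exercised on generated data with serialized ground
truth, so the whole analysis runs without downloads. The generator emulates
the *statistical structure* of a curated ER-modulator registry, with effect
sizes specified on the log2 fold-change scale (percentiles are an output of
the pipeline, never an input):

```
log2fc = class_mult x loading + cellline_effect
         + dose_coef x log10(dose/100) x loading + batch_draw + N(0, sd)
```

Defaults: 2000 genes, 40 comparisons, 3% ER-up and 3% ER-down core genes
with loadings of magnitude ~3 (jittered 0.8-1.2x), 2% bidirectional genes
carrying a +3 effect in exactly 30% of comparisons and -3 in exactly 20%,
drug-class multipliers SERM -1 / SERD -1.5 (positive multipliers such as
GE +1 / OE +0.8 emulate activating *ESR1*-mutant sections, in which case
the labels land in the construction metadata field), 4 cell lines in 2
response clusters (per-gene cluster effects sd 0.3), 8 batches (sd 0.2),
residual noise sd 0.5, 25% microarray comparisons observing a random 90% of
the gene universe. One master seed fans out to per-artifact child streams
via a fixed linear rule (`child_seed`), so every dataset is reproducible
from a single integer.

Companion generators cover the other stages: negative-binomial counts whose
treated means scale by the designed 2^log2fc (the no-replicate fallback
path); percentile-scale regression responses with a planted drug effect and
batch intercepts (effect 30, noise sd 10 at 40 comparisons for power
checks; effect 0 for null calibration); a log-normal cohort of 100 samples
at 21% case prevalence — the mutant fraction of the merged clinical cohorts
this emulates — shifted +/-1 sd on 50-gene activation/repression sets; and
a toy 10 Mb genome with 100 TSSs on a jittered grid (guaranteed spacing, so
a planted proximal cluster is attributable to one gene), 200 WT background
peaks, and 10 target genes receiving 3 tightly TSS-proximal gained peaks
(within 10 kb), emulating unambiguous direct-target binding such as gained
ER peaks at strongly mutant-activated loci. For the class-correlation
check, a dedicated generator gives two drug classes continuous Gaussian
loadings shared on a fraction of genes; its closed-form design correlation
`share x v / (v + noise_sd^2/n)` is recovered from the percentile profiles
because the continuous loading distribution keeps the rank transform close
to affine.

What the generator does **not** emulate: real gene symbols or genome
builds, compositional library-size artifacts beyond what the NB sampler
induces, correlated gene-gene noise within pathways, platform-specific
intensity distributions, or the actual 361-experiment registry. Passing
recovery tests therefore demonstrate internal consistency of the statistics
under the designed conditions, not performance on any real dataset.

## Problem sizes and reproducibility

The bundled checks run the generator at its defaults (2000 genes x 40
comparisons, 3 seeds for recovery rates), fit 500 null mixed models for the
calibration check, and use 20 peak-set seeds for the regulatory-potential
ranking — sizes chosen so the whole suite completes in minutes on one core
while keeping the binomial noise of the recovery rates well below the 0.9
acceptance thresholds. `scripts/acceptance.R --seed N --out file.json`
recomputes all headline quantities from scratch; the numbered scripts under
`analysis/` run the same pipeline as a narrative, writing tables under
`results/`.

## Known limitations

* The percentile transform discards effect-size magnitude beyond rank;
  two comparisons with very different dynamic ranges contribute equally.
* The mixed-model design treats duration linearly in hours; log-hours may
  fit saturating kinetics better (an option, not the default, since the
  plain reading of "treatment duration (h)" is linear).
* Permutation FDRs below 1/n_perm are reported as 0; raise `n_perm` when
  small FDRs matter.
* The rank-z single-sample scorer ignores gene-gene correlation, so its
  scores are comparable within a dataset but not across datasets with
  different gene universes.
* `fisher_ora` treats the supplied universe as exchangeable; expression-
  dependent detection bias is the caller's responsibility.
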