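# estromeld

Cross-study meta-analysis of estrogen-receptor (ER) modulator
transcriptomes for breast-cancer researchers who need to pool
heterogeneous differential-expression experiments — different platforms,
cell lines, doses, durations and batches — into one comparable scale and
then ask which responses are consistent, which diverge, and why.

## What it computes

The harmonizing unit is the **regulatory percentile**: within each
treated-vs-control comparison, per-gene log2 fold changes are rank-scaled
so the most down-regulated gene is −100, the most up-regulated is +100 and
unchanged genes are 0 (mid-ranks for ties; up and down pools ranked
separately). On the resulting genes × comparisons matrix (80% presence
filter per section, missing ≠ zero) the package provides:

* heterogeneity `log10(CV²)` per gene with Mann–Whitney contrasts between
  scopes (e.g. tamoxifen vs fulvestrant experiments);
* Pearson correlation / average-linkage clustering of compound and
  cell-line response profiles;
* concordance quadrants (±25 cut), discordant genes (|Δ percentile| > 70),
  **bidirectional genes** (top decile up in ≥15% of comparisons *and* top
  decile down in ≥15%), **consensus targets** (top decile in ≥50%), and a
  ligand-dependence gate (±50 in both conditions vs de novo within ±15 on
  the estrogen axis);
* per-gene mixed-effect regression
  `percentile ~ cell line + modality + drug class × duration + (1 | batch)`
  with Satterthwaite p-values;
* Fisher over-representation, preranked GSEA (weighted KS statistic,
  1000 permutations, seed 6, sign-stratified permutation FDR),
  geometric-mean signature fold changes, a rank-z single-sample signature
  score, and the Oncotype DX weighted impact
  `0.47·HER2 − 0.34·ER + 1.04·Prolif + 0.1·Invasion + 0.05·CD68 −
  0.08·GSTM1 − 0.07·BAG1` on group-mean percentiles;
* cohort classification: integrated activation-minus-repression scores,
  univariate logistic fit, empirical ROC with tie-corrected rank AUC;
* peak-set algebra: gained peaks (BED, 0-based half-open), TSS-window
  regulatory potential with a 100 kb exponential decay kernel
  `exp(−(0.5 + 4d))`, and browser-style ±200 kb TSS views;
* TMM normalization and log2(CPM + 1) fold changes for the no-replicate
  fallback path;
* a synthetic-data generator with serialized ground truth that emulates
  the registry's statistical structure (core ER program, drug-class
  multipliers, dose/batch/cell-line effects, planted bidirectional and
  consensus genes, labeled cohorts, planted TSS-proximal gained peaks), so
  the entire pipeline runs and is tested without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole pipeline on a
simulated registry (fixed seed) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # 80 comparisons, ground truth
Rscript analysis/02_harmonize.R     # percentile matrices per section
Rscript analysis/03_meta_analysis.R # consensus / bidirectional / models
Rscript analysis/04_enrichment.R    # ORA, preranked GSEA, Oncotype
Rscript analysis/05_classify.R      # cohort ROC
Rscript analysis/06_cistrome.R      # gained peaks, regulatory potential
```

Output printed by the run (abridged):

```
no-replicate fallback: r = 0.920 between recovered and designed log2fc (2000 genes)
heterogeneity log10(CV^2): SERM median 1.04 vs SERD median 0.91 (Mann-Whitney p = 0.000908)
bidirectional genes: 40 called, precision 1.00, recall 1.00
consensus up targets (top decile in >= 50%): 60 called, precision 1.00, recall 1.00
GSEA ESR1mut: 'er_down_program' NES = -3.65, FDR = 0.000
Oncotype weighted impact: modulator -68.1, ESR1mut 67.4
cohort: 100 samples (21 mutant), integrated-score AUC = 1.000
regulatory potential: 100% of planted targets in the top decile
```

Reading it: the fallback path recovers designed fold changes from raw
counts up to compositional shift; SERM comparisons are measurably noisier
than SERD ones; every planted bidirectional and consensus gene is
recovered with no false calls; the planted repression program scores
strongly negative NES in the activating section; the Oncotype impact flips
sign between repressive and activating sections; the cohort signature
separates mutant from WT samples completely; and all peak-linked target
genes top the regulatory-potential ranking.

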