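# promcage

Promoterome analysis of CAGE (cap analysis of gene expression) data in R.

CAGE sequences the capped 5' ends of mRNAs, giving single-base
transcription start sites (CTSSs) with quantitative expression.  From
per-sample CTSS count tables, `promcage` reconstructs promoter-level
biology the way sorted-cell CAGE studies do:

- **Power-law normalization** of raw tag counts to normalized tags per
  million (tpm): each library's reverse-cumulative count distribution
  r(x) = 10^b·x^s is fitted in log-log space and mapped onto a common
  reference law r_ref(y) = β·y^(−α) (α = 1.05, implied library size 10^6
  tags), so tpm(x) = (10^b·x^s/β)^(−1/α).
- **Tag clusters (TCs)**: same-strand CTSSs supported by ≥ 0.5 tpm in any
  sample are chained while neighbour gaps are ≤ 20 bp, trimmed to the
  10th–90th percentiles of cumulative expression, and kept when trimmed
  expression exceeds 5 tpm.  TCs within 100 bp across samples are merged
  into **consensus clusters (CCs)**, annotated to the nearest gene TSS.
- **Promoter shape**: the interquantile width (IQW = q90 − q10 + 1) and
  the dominant-TSS fraction classify promoters as *sharp* (IQW < 10 bp),
  *peaked broad* (dominant TSS > 60 % of expression) or *broad*, with a
  3×3 transition matrix between conditions (CCs ≥ 10 tpm in both).
- **Core-promoter motifs**: JASPAR-format PWMs are scanned over the
  −120..+50 bp window around the dominant TSS (log2-odds scores min–max
  scaled to a match %; hit = ≥ 90 %), with Fisher-exact enrichment of DE
  groups versus the unchanged background, TATA match distributions in
  −40..−20, WW-dinucleotide profiles, and poly-W pentamer statistics.
- **Differential expression**: a negative-binomial Wald test on CC raw
  counts across replicates (median-of-ratios size factors, trend-shrunk
  method-of-moments dispersions, BH adjustment at padj < 0.05).
- **Alternative promoters**: twinned canonical/alternative promoter
  pairs expressed > 5 TPM in both conditions are classified as
  canonical/alternative up/down from the signed relative changes when
  relative use shifts ≥ 2-fold.
- **Temporal trends**: CCs > 5 TPM changing monotonically by > 1.5-fold
  at each of two sequential stage steps are *gained* or *lost*.
- **Gene-set statistics**: Tau and Shannon-entropy tissue-specificity
  indices, permutation enrichment against catalogues (n = 10 000 draws),
  and chi-square intersection tests.
- **A seeded synthetic-data generator** emits a genome, annotation,
  planted promoter motifs and multi-sample CTSS tables with full ground
  truth (shape classes, fold changes, motif placement, alt-promoter and
  temporal classes), so every stage is validated end to end.

## Worked example

```r
library(promcage)

sim <- simulate_cage_study(sim_config(seed = 1))   # 5000 genes, 2 cond x 3 reps
res <- run_pipeline(pipeline_config_from_sim(sim), outdir = "promcage_out")

table(res$shape_calls$A$shape_class)
#>        broad peaked_broad        sharp
#>         2017         1230         1753

table(res$diffexp$call)
#> unchanged      up_A      up_B
#>      4677       165       158

subset(res$motif_enrichment, significant & log2_odds_ratio > 0,
       c(motif, group, log2_odds_ratio, p_value))
#>       motif group log2_odds_ratio      p_value
#>    TATA_SYN  up_A        3.284422 6.680270e-40
#>   CCAAT_SYN  up_B        3.361266 5.414638e-40
#>     SP1_SYN  up_A        1.509384 6.489833e-09
```

The 165/158 clusters called up in the slow/fast condition recover the
300 planted fold changes (plus a controlled share of false calls:
empirical FDR 0.07 at BH 0.05), and the planted motif biology comes back
with the right sign: TATA-box enrichment in promoters up-regulated in
the slowly cycling condition, CCAAT-box enrichment in the rapidly
cycling one.

Real data enter through the same doors: `read_ctss()` per sample,
`read_genome()`, `read_jaspar()` (supply your own JASPAR PFM files; the
PWMs shipped in `inst/extdata/` are synthetic, built for simulation and
testing), a gene table, and `run_pipeline()` with a YAML configuration
(`read_pipeline_config()`), or the stage functions called directly.

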