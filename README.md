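# cistromeGO

Functional enrichment analysis of transcription factor (TF) ChIP-seq
peaks, for computational biologists who want to know **which genes a TF
directly regulates and which biological processes those genes drive** —
without ever picking a peak-to-gene distance cutoff.

## What it computes

**Regulatory potential (RP).** Every annotated gene receives a continuous
score summing nearby peak contributions with exponentially decaying
weights:

```
RP(g) = Σ_{i : |c_i − t_g| ≤ 15·d0}  2^(−|c_i − t_g| / d0)
```

where `c_i` is a peak center, `t_g` the gene's TSS, and the decay distance
`d0` is a half-life (a peak at `d0` counts half as much as one on the
TSS). Scores are min–max scaled per dataset and optionally adjusted by
subtracting a per-gene baseline (the median scaled RP over reference
cistromes), correcting for promoters that attract peaks in any
experiment. Genes are ranked by decreasing adjusted RP.

**Promoter/enhancer classification.** The fraction of the most significant
peaks (top 2000 / 5000 / 10000 / all, ranked by −log10 p-value) within
1 kb of the nearest TSS decides the default decay distance: if any
fraction exceeds 20%, the cistrome is promoter-dominant (`d0 = 1 kb`),
otherwise enhancer-dominant (`d0 = 10 kb`).

**Rank-product integration (ensemble mode).** Given a
differential-expression table from a perturbation of the TF, genes are
also ranked by DE p-value (optionally up- or down-regulated only) and the
two ranks are combined as `R_RP × R_DE`; genes bound *and* responsive
rise to the top. ROC/PR curves report how well adjusted RP alone predicts
the DE genes.

**Threshold-free enrichment (mHG).** Each gene set becomes a 0/1 series
down the ranking; the minimum hypergeometric (mHG) statistic takes the
best hypergeometric tail over *all* prefix cutoffs, and an exact p-value
for that minimum is computed by an O(N·B) dynamic program (no
permutations, no cutoff parameter). Terms are size-filtered (10–2000
genes in the universe), de-duplicated at Jaccard > 0.85, and reported
with Benjamini–Hochberg FDR (< 0.2 in the filtered report).

## Worked example

The package ships a seeded generator that writes all five input formats
(peak BED, TSS table, DGE table, GMT gene sets, baseline table), so a full
run needs no downloads:

```r
library(cistromeGO)

spec  <- fixtureSpec(n_genes = 1000, planted_term_size = 30,
                     n_null_terms = 15, n_background_peaks = 2000,
                     seed = 42)
paths <- writeFixture(spec, "demo")
cfg   <- runConfig(peaks = paths[["peaks"]],
                   annotation = paths[["annotation"]],
                   gmt = paths[["gmt"]], dge = paths[["dge"]],
                   outdir = "demo/out")
bundle <- runEnsemble(cfg)

bundle$classification
#> TFClassification: enhancer-dominant
#>   chosen d0: 10000 bp
#>   threshold: 0.2 | radius: 1000 bp
#>   fraction of peaks near TSS per subset:
#>     2000   0.0610
#>     all    0.0586

head(enrichmentTable(bundle$enrichment$sets)[
    , c("set_id", "B", "n_opt", "b_at_cutoff", "pvalue", "fdr")], 3)
#>        set_id         B     n_opt b_at_cutoff      pvalue         fdr
#> 1   planted_1        30        29          28 1.17898e-50 1.65057e-49
#> 2     null_14        20       442          15 4.14497e-02 2.90148e-01
#> 3     null_10        21        12           2 1.79024e-01 5.59567e-01
```

Reading the top row: of the planted 30-gene program, 28 genes sit inside
the top 29 of the 1000-gene rank-product ranking — the mHG-optimal cutoff
found on its own — giving an exact p-value of ~1e-50; every null term is
flat (FDR ≫ 0.2), so only the planted program is reported. The
classification shows ~6% of peaks near TSSs, an enhancer-type binding
profile, hence the 10 kb decay distance. `bundle$curves$auroc` (here
0.890) quantifies how strongly binding alone predicts the perturbed
genes.

A shell entry point with the same functionality is installed at
`inst/scripts/cistromego` (subcommands `run`, `fixtures`, `baseline`).

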