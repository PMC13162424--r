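# testistools

Tools for analysing testis transcriptomes assembled from heterogeneous
expression sources — whole-body tissue atlases, bulk segmented-testis
RNA-seq, and single-cell/single-cyst datasets. The testis expresses a
very large fraction of the genome across an ordered succession of
germline and somatic cell types; `testistools` asks, quantitatively,
whether genes with similar testis expression profiles form recoverable
groups, whether testis specificity can be predicted from testis-internal
data alone, and whether co-expressed gene groups share promoter motifs.

## What it computes

**Tissue specificity.** For expression $e_1,\dots,e_n$ over $n$
tissues/categories,

$$\tau = \frac{\sum_i (1 - e_i/\max(e))^2}{n-1}, \qquad
x_i = \frac{e_i - \bar e}{\mathrm{sd}(e)} \;(\text{sample sd}),$$

where tau captures overall specificity and the signed z-score $x_i$
separates testis-enriched from testis-depleted genes. The testis z-score
is min-max rescaled to $[-1,1]$ per atlas and averaged across atlases
into the testis-specificity index (`tsp`).

**Feature assembly.** Each testis source contributes its per-category
specificity z-scores plus one overall expression dimension (a source with
$k$ categories yields $k+1$ features; the default five sources with
3/8/10/9/39 categories give 74), followed by column standardization.

**Embedding + clustering.** t-SNE (perplexity 100, early exaggeration
19, 1000 iterations) or UMAP (50 neighbours), then deterministic DBSCAN
(eps 0.11/0.12, min samples 40/60/90 on the min-max-normalized
embedding), with per-group specificity profiles.

**Classification.** Gradient-boosted trees (xgboost) predicting
`tsp >= 0.8` (or contrasts against under-represented `tsp < -0.45` /
generally expressed `-0.1 < tsp < 0.4` genes, or TF-target membership)
from the 74 features, with an 80:20 split, SMOTE balancing of the
training set, ROC/AUC, confusion metrics, and gain/weight/cover
importances.

**Promoter motif mapping.** PWM scanning of ±1 kb TSS-centred,
gene-oriented windows on both strands at a relative-score cutoff
(default 0.8), gene-set filters (expression floors, specificity
intervals, explicit lists), and strand-resolved positional hit
distributions.

**Synthetic data.** A generator producing multi-source expression
tables, tissue atlases, TF-target lists, and promoter sequences with
planted motifs, with labelled ground truth, so the full pipeline runs
and is verified without any external download.

## Worked example

```r
library(testistools)

study <- simulate_study(n_genes = 1000, seed = 1)   # 5 sources + 3 atlases
spec  <- testis_specificity(study$atlases)
head(spec[c("gene_id", "tau", "tsp")], 4)
#> # A tibble: 4 × 3
#>   gene_id   tau    tsp
#>   <chr>   <dbl>  <dbl>
#> 1 g00001  0.265  0.127
#> 2 g00002  0.501 -0.119
#> 3 g00003  0.975  0.999
#> 4 g00004  0.439 -0.683
```

`tsp` is the testis-specificity index in $[-1, 1]$: gene `g00003` is
strongly testis-specific (its tau near 1 says its atlas expression is
confined to one tissue), `g00004` is depleted in testis relative to
other tissues.

```r
features <- standardize_features(assemble_features(study$sources))
fit <- classify_testis(features, spec, rule = "specific_vs_rest", seed = 1)
fit
#> <testis_gbt> contrast: specific_vs_rest
#>   train/test: 800/200   AUC: 0.9967
#>   sensitivity 0.956  specificity 0.987  ppv 0.956  npv 0.987
head(tidy(fit), 4)
#> # A tibble: 4 × 4
#>   feature           gain weight cover
#>   <chr>            <dbl>  <int> <dbl>
#> 1 seg_testis:c02:z 2015.     23 3742.
#> 2 fca:c01:z        1749.     65 4110.
#> 3 fca:mean          805.     88 3268.
#> 4 larval_sc:c01:z   446.     35 1706.
```

The held-out AUC of 0.9967 says testis specificity — defined entirely
from independent whole-body atlases — is almost perfectly predictable
from testis-internal expression profiles; the importance table shows
which source dimensions carry that signal (here the mid-stage
segmented-testis specificity and the cell-atlas dimensions).
`glance(fit)` returns the same metrics as a one-row tibble and
`autoplot(fit)` draws the ROC curve. Downstream, `embed_genes()` +
`cluster_embedding()` group genes in 2-D, and `scan_windows()` +
`positional_distribution()` map promoter motifs for any gene set.

A command-line driver mirroring every stage (subcommands `simulate`,
`specificity`, `assemble`, `embed`, `cluster`, `classify`, `scan`,
`distribution`) is installed at
`system.file("cli", "testistools", package = "testistools")`.

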