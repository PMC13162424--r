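---
title: "Methods: testis transcriptome specificity, clustering, classification and promoter motif mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testis transcriptome specificity, clustering, classification and promoter motif mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(testistools)
```

# The analysis in outline

The testis expresses an unusually large fraction of the genome across a
highly structured succession of cell types, which makes it a natural test
bed for the hypothesis that genes with similar expression profiles share
regulation. The package implements that analysis as five connected stages:

1. **Tissue specificity.** From whole-body expression atlases, each gene
   receives a tau score and a z-score-based testis-specificity index.
2. **Feature assembly.** From several testis-only expression sources, a
   gene-by-feature table is built from per-category specificity profiles.
3. **Embedding and clustering.** Genes are embedded in two dimensions
   (t-SNE or UMAP) and grouped by density clustering (DBSCAN).
4. **Classification.** Gradient-boosted trees predict testis-specificity
   classes — derived from the atlas-based index — using only the
   testis-internal features, with SMOTE balancing of the training set.
5. **Promoter motifs.** PWM motifs are scanned across ±1 kb TSS-centred
   windows on both strands at a relative-score cutoff, and hit positions
   are summarised as strand-resolved distributions for filtered gene sets.

A synthetic-data module generates all inputs with the statistical
structure the analysis assumes, so every stage is runnable and testable at
desk scale.

# Specificity indices

For a gene with expression $e_1,\dots,e_n$ over $n$ categories:

$$\tau = \frac{\sum_{i=1}^{n}\left(1 - e_i/\max(e)\right)^2}{n-1},
\qquad
x_i = \frac{e_i - \bar e}{\sqrt{\tfrac{1}{n-1}\sum_j (e_j-\bar e)^2}}.$$

Tau is bounded in $[0,1]$ (1 = single-category expression) and is
scale-invariant; the z-score $x_i$ is signed, so it distinguishes over-
from under-representation in a particular tissue — the property the
pipeline relies on, since testis-*depleted* genes are as informative as
enriched ones. Note the sample standard deviation ($n-1$): for small
category counts the distinction from the population form is material, and
the package uses $n-1$ everywhere.

The testis-specificity index (`tsp`) takes the testis component of the
z-score per atlas, min-max rescales it to $[-1, 1]$ over genes
(1 = most specific), and averages across atlases:

* **Rescale-then-average versus average-then-rescale.** The default
  rescales within each atlas and then averages, which keeps atlases with
  different dynamic ranges commensurate; the alternative order is
  available (`rescale = "after_mean"`) because with genes missing from
  some atlases the two orders genuinely differ.
* **Missing genes** receive the mean over the atlases where they are
  present; genes absent everywhere get `NA`.
* **Constant expression vectors** get all-zero z-scores (flagged via an
  attribute) rather than `NA`, keeping downstream matrices dense.
* **No log-transform** is applied to atlas expression by default;
  `log2_expression = TRUE` is available for heavy-tailed atlases.

# Feature assembly

Each testis source is first collapsed to per-category means
(`aggregate_categories()`); the per-gene z-score across those categories
gives that source's specificity block, and the mean over categories gives
a single expression dimension. A source with $k$ categories therefore
contributes $k + 1$ features, and with the default category counts
(3, 8, 10, 9, 39) the table has 74 columns. Two consequences are
intentional: higher-resolution sources get proportionally more
dimensions, while raw expression magnitude — whose scale differs wildly
between bulk and single-cell data — can influence exactly one column per
source (the z-dimensions are scale-invariant). The whole table is then
column-standardized; standardization is idempotent and flags constant
columns.

The gene universe defaults to the intersection across sources, mirroring
a single joined table; `gene_policy = "union"` keeps all genes and
zero-imputes missing blocks (recorded in the `imputed` attribute), since
a zero z-profile is the natural "no information" value after
standardization. The expression dimension defaults to the mean over
category means; a max-over-categories variant is available for sources
where a single peaked stage carries the signal.

# Embedding and clustering

t-SNE (perplexity 100, early exaggeration 19, 1000 iterations) and UMAP
(50 neighbours) run with seed 106 by default; both are delegated to their
standard implementations (Rtsne, uwot) in single-threaded mode so results
are reproducible from the seed. When the gene count is too small for the
requested perplexity it is reduced with a warning rather than failing.

DBSCAN is implemented in the package (deterministic, Euclidean): core
points have at least `min_samples` neighbours within `eps` (self
included), clusters are grown from core points in row order, border
points go to the first cluster that reaches them, everything else is
noise (−1). Radii like 0.11/0.12 are only meaningful on a fixed scale, so
by default the embedding is min-max normalized to the unit square before
clustering; raw-coordinate clustering is available. Group profiles report
group size, mean testis-specificity, and per-feature means of the
*unstandardized* specificity dimensions, which is what a group heatmap
should display.

# Classification

Labels come from the testis-specificity index: positives are genes with
`tsp >= 0.8`; the three contrasts oppose them to all remaining genes, to
under-represented genes (`tsp < -0.45`), or to generally expressed genes
(`-0.1 < tsp < 0.4`). The boundary gene (`tsp` exactly 0.8) is counted
positive; the choice is recorded in the report. A `target_set` rule
instead labels membership in an explicit list (e.g. TF-target genes).

The split is 80:20 with the *floor* convention on the test set — 11,019
records give 8,816 training and 2,203 test records. SMOTE is applied
strictly after the split and only to the training data, to avoid leaking
synthetic copies of test points into training: each synthetic minority
point lies uniformly on the segment between a minority point and one of
its `k = 5` nearest minority neighbours, so synthetic points never leave
the minority class's convex hull. Gradient boosting is delegated to
xgboost (binary logistic, single thread, fixed seed). Hyperparameter
search defaults to seeded random search over a bounded space scored by
3-fold cross-validated AUC — each candidate is derived from a
per-iteration child seed, so enlarging the budget extends rather than
reshuffles the search; a Bayesian-style optimizer could be slotted in,
but a seeded random search is reproducible bit-for-bit and adequate for
tree boosters at this budget.

Evaluation uses the model's scores: the ROC curve sweeps all thresholds
with tied scores collapsed, and the AUC (trapezoidal) equals the
Mann-Whitney statistic with ties counting one half. Confusion metrics
(sensitivity, specificity, PPV, NPV) use a 0.5 score cutoff; ratios with
empty denominators are reported as missing rather than 0. Feature
importances are per-feature totals over the fitted trees: `gain` (summed
loss improvement), `weight` (integer split count), `cover` (summed
covered observations); unused features score 0.

# Promoter motif mapping

Motifs are position probability matrices (MEME minimal text format is
read and written; absent background blocks default to uniform). Scores
are log2-odds against the background with a pseudocount of 0.01 of the
background probability, and every placement is reported on the
*relative* scale $(raw - min)/(max - min)$, where min/max are the
column-wise worst/best sums — so the consensus scores exactly 1 and the
cutoff 0.8 has the same meaning for every motif. Ambiguous bases
contribute their column's background-expected score.

Windows are symmetric, ±1000 nt around the TSS base (configurable):
regulatory signal in these data appears both upstream and downstream of
the TSS, so a one-sided window would hide half the picture. Minus-strand
windows are reverse-complemented so every window reads 5'→3' in the
gene's frame; hits carry gene-relative strand (`sense`/`antisense`) and
the TSS-relative offset of their leftmost base (0 = TSS, negative =
upstream). Both strands are scanned — the antisense scan runs over the
window's reverse complement and maps positions back — and overlapping
hits are all reported. Windows truncated at contig ends keep their own
TSS index so offsets remain exact.

Gene sets for the positional distributions combine expression floors
(>1, >100, >1000), specificity intervals (>0.9, >0.5, <0, <−0.5) and
explicit lists by conjunction. Distributions are counts (not densities)
in 25-nt bins, overall and per strand; the overall histogram is exactly
the element-wise sum of the strand histograms.

# The synthetic-data generator

The generator emulates the *shape* of the real inputs, not their content:

* **Archetypes.** Genes belong to one of five classes — testis_late,
  testis_early, somatic, general, underrepresented — with default
  proportions 0.15/0.10/0.20/0.45/0.10, chosen to reproduce the class
  imbalance that motivates SMOTE. Source profiles are smooth functions of
  a category's developmental progression (late genes ramp up as $t^2$,
  early genes peak near $t = 0.25$, somatic genes occupy early/somatic
  categories); atlas profiles make testis archetypes testis-restricted
  and the under-represented archetype testis-depleted.
* **Specificity continuum.** Each testis-archetype gene carries a
  specificity quantile $q \sim \mathrm{Beta}(2,1)$ that scales its
  testis signal in both the atlases (testis level $0.5 \cdot 200^q$ for
  late genes) and the testis sources (signal amplitude $\propto q$).
  Real specificity indices are continuous, and a generator without this
  gradient makes every classification contrast trivially perfect; with
  it, a minority of genes sit near the 0.8 labelling boundary with
  correspondingly intermediate features, which is exactly the regime in
  which the full contrast is harder than the contrast against
  under-represented genes.
* **Noise.** Log-normal multiplicative noise (sd 0.5 on the natural-log
  scale) on archetype means, plus Bernoulli dropout (default 0.3) for the
  single-cell-like sources only; the bulk-like segmented-testis source
  never receives dropout. The published datasets are consumed as
  processed tables and state no noise model, so these are the package's
  own choices of a plausible regime.
* **Promoters.** One contig per gene, i.i.d. background at 45% GC, random
  gene strand, and a 12-nt planted motif (0.94 consensus probability per
  position) inserted in testis_late promoters at offsets
  $\mathcal{N}(-150, 20^2)$, sense strand with probability 0.8,
  insertion probability 0.9 per gene. Instances are *sampled from the
  PWM*, not copied from the consensus, so relative scores near the 0.8
  cutoff occur; with these defaults an instance passes the cutoff with
  probability ≈0.97, while background sequence yields on the order of
  0.1 hits/kb. Overlapping placements are re-sampled up to ten times,
  then skipped with a warning.
* **TF targets** are a noisy view of the testis_late class: a coverage
  fraction (default 0.8) of its genes plus a contamination fraction
  (default 0.02) of all others.

What the generator does **not** emulate: read-level sampling, UMI
statistics, batch effects between sources, correlated noise across
tissues, genes with profiles intermediate between *different* archetypes,
and promoter sequence composition beyond i.i.d. background. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that
it recovers signal under a known, favourable generative model — not that
the biological conclusions of any particular real dataset would
reproduce.

# Numerical choices and degenerate inputs

* All-zero expression vectors: tau is undefined and returned as `NA` with
  a warning; constant vectors give zero z-scores and zero min-max values,
  both flagged.
* The test-set size uses `floor(n (1 - f) + 1e-9)`; the epsilon guards
  against binary-representation artefacts (`10 * 0.2` is fractionally
  below 2 in floating point).
* DBSCAN neighbourhood tests use a `1e-12` slack on the squared radius so
  points at exactly `eps` are neighbours regardless of rounding; the
  scanner applies the same slack at the score cutoff.
* Ties in DBSCAN border assignment go to the first cluster in scan
  order; ties in ROC thresholds are collapsed and contribute half.
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; internal stages derive child seeds from the
  user seed through a fixed 32-bit congruential map, so pipelines are
  reproducible end to end from a single integer.

# Problem sizes

The test suite and the acceptance script run the full pipeline at 1,000
genes with the default five sources (74 features), three atlases of 15
tissues, and promoter scans over roughly 500 ±1 kb windows; oracle-based
property checks use up to 1,000 random vectors, 300-point DBSCAN
instances and 2 kb scan sequences. These sizes exercise every code path
(including the published 11,019-record split arithmetic, which is checked
exactly) while keeping a full run in the order of a minute on one CPU.
The CLI mirrors every stage for work on real files; its YAML config
mirrors all flags, with explicit flags taking precedence.

# Known limitations

* The embedding stages inherit the numerical behaviour of Rtsne/uwot;
  coordinates are reproducible for a fixed seed and version but not
  across library versions.
* DBSCAN is exact but quadratic in gene count; at the scale this package
  targets (~10⁴ genes, 2-D embeddings) that is a few seconds, but it is
  not an index-accelerated implementation.
* The classifier's confusion metrics use a fixed 0.5 score cutoff; no
  cutoff calibration is attempted.
* Motif discovery is out of scope: the package prepares discovery inputs
  (`collect_group_sequences()`) and consumes discovered motifs in MEME
  minimal format, but does not search for motifs itself.
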