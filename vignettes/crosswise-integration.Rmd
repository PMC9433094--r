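---
title: "Crosswise integration of RNA-seq and ATAC-seq co-expression networks"
author: "crossomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosswise integration of RNA-seq and ATAC-seq co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossomix)
```

# The problem

Two cancer cell lines respond very differently to the same DNA-damaging
drug. Profiling both lines under control and treated conditions at two time
points, in two omic layers — transcriptome (RNA-seq) and chromatin
accessibility at promoters (ATAC-seq) — gives a perturbation atlas of the
response. `crossomix` turns that atlas into three things:

1. **integrated co-regulation modules** that may mix genes "heard" at the
   RNA level with genes "seen" opening or closing at the chromatin level;
2. a **perturbation-informed signature**: up/down gene sets that separate
   the sensitive from the resistant line at baseline *and* respond
   differentially to the drug;
3. a **sensitivity score** for any basal transcriptome (no perturbation
   required), plus an L1-penalised regression that learns to reproduce the
   score so that even the signature itself is no longer needed at
   prediction time.

# Group fold change: the coordinate system

All co-expression here is measured in *group fold change* (GFC) space, not
per-sample expression space. For feature $i$ and condition group $g$
(a `cell line | treatment | time` combination),

$$\mathrm{GFC}_{ig} = \bar{x}_{ig} - \frac{1}{G}\sum_{g'} \bar{x}_{ig'},$$

where $\bar{x}_{ig}$ is the mean log2 normalized expression of $i$ in $g$.
On the log scale this difference *is* the fold change of the group mean
from the overall mean of group means; uncapped rows sum to zero by
construction. A symmetric cap (default ±2, configurable including none)
clips extreme values so that a single explosive condition cannot dominate
every correlation. The cap is the only operation allowed to break the
row-sum-zero identity, and the validity method of `GFCMatrix` enforces
exactly that dichotomy.

Correlating GFC rows rather than sample profiles means two features are
"co-expressed" when they share a *regulation pattern across conditions*,
which is the semantics the module-selection and signature stages need.
An option to correlate per-sample normalized expression exists but is not
the default.

**One GFC matrix, two uses.** GFCs are computed once over all condition
groups of both cell lines. Per-cell-line networks then correlate only that
cell line's group columns. Restricting columns differs from recomputing
cell-line-local GFCs by a per-feature constant (the centering term), and
Pearson correlation is invariant to such shifts, so the two are equivalent
up to capping. Building per-cell-line networks first — and merging them
horizontally afterwards — prevents the dominant baseline differences
between cell lines from swamping treatment-response patterns.

# Upstream plumbing

The stages before GFC are deliberately standard and replaceable:

* **Filtering**: RNA features are kept when their row total is strictly
  greater than the threshold (default 100); ATAC peaks when the total is at
  least the threshold (default 20). The asymmetry mirrors common practice
  for the two assay types and both rules are exposed.
* **Normalisation**: median-of-ratios size factors (the DESeq estimator)
  followed by `log2(count / factor + 1)`. The log transform is a monotone,
  variance-flattening stand-in for a variance-stabilising transformation;
  the pseudocount is configurable.
* **Differential testing**: per-feature Welch t-tests with
  Benjamini–Hochberg adjustment, one contrast per (cell line, treatment,
  time) against the same line's control at the same time. Workflows that
  prefer a negative-binomial framework can inject an externally computed
  differential table wherever a `DETable`-shaped data frame is accepted —
  the columns (`feature`, `log2fc`, `p`, `padj`, `mean_expr`) are the whole
  contract.
* **Promoter reduction**: ATAC enters the gene-level analysis only through
  promoter peaks of protein-coding genes. When several promoter peaks map
  to one gene, the reference peak is the one with the lowest p-value (for
  differential comparisons) or the highest variance (for expression
  summaries); ties break to the lexicographically smaller peak id so the
  reduction is deterministic.
* **Network input**: per layer, features significant in at least one
  treated-vs-control contrast (adjusted p for RNA, raw p for ATAC, both
  defaulting to 0.05), ranked by variance of normalized values and
  truncated to the top 1000. Variance is computed over all samples of the
  dataset by default; the sample set is configurable because reasonable
  analysts disagree on it.

# Networks, modules, and the two integrations

Edges connect features whose GFC patterns correlate positively at or above
a cutoff (inclusive ≥; negative correlations never make edges by default,
matching the co-expression convention of regulation-pattern clustering).
Isolated nodes are dropped, and node ids carry their layer namespace
(`rna::GENE`, `atac::GENE`) so the same gene can exist in both layers of an
integrated graph.

There is no automatic cutoff selection: the choice is empirical, and
`cutoffScan()` provides the evidence table (nodes, edges, and the $R^2$ of
a log–log linear fit to the degree distribution). `suggestCutoff()` offers
a heuristic default — the smallest scanned cutoff whose degree distribution
fits a power law with $R^2 \ge 0.8$, falling back to the best fit — but the
configuration supplies the final value.

**Horizontal integration** merges the two cell lines' same-layer networks:
node and edge union, with edges present in both parents reweighted to the
arithmetic mean of their two weights. The operation is commutative and
idempotent, which the test suite asserts on random graphs.

**Module detection** is community detection on the weighted graph
(walktrap with 4 steps, infomap, or leiden), with communities below the
minimum size (default 15 nodes) relabelled `unassigned`. Modules are named
by color, largest first. The stochastic algorithms run under a fixed seed
and are bit-reproducible. The choice among the three algorithms is
empirical per dataset — they trade module granularity differently — and
the configuration records which one a given analysis used.

**Vertical integration** correlates the mean GFC pattern of every RNA
module against every ATAC module. For pairs at or above the cross-layer
cutoff, cross-layer edges are added between member features whose own
GFC-vector correlation also clears the same cutoff, weighted by that
correlation; intra-layer edges are never removed. The combined graph is
reclustered and module mean GFCs recomputed, each node contributing its
own layer's GFC vector. How cross-layer edges should enter the integrated
graph is genuinely underdetermined in the workflow this package
re-implements (module-level matching is described, feature-level wiring is
not); the package's rule — edges only inside matched module pairs, the
same threshold at both levels — reproduces the intended behavior with a
single tunable: matched modules merge on reclustering, unmatched modules
stay layer-pure.

The cross-layer cutoff itself is chosen to *maximise layer mixing*:
`crosslayerCutoffScan()` reruns the integration over a grid and reports a
mixing score — the mean over modules of the normalized Shannon entropy of
their (RNA, ATAC) member fractions, 0 when every module is layer-pure and
1 when every module is a 50/50 blend. Entropy is the canonical mixedness
measure; the scorer is pluggable. Ties in the argmax resolve to the higher
cutoff (fewer, stronger cross-links).

On synthetic data with planted cross-layer co-regulation, walktrap tends
to keep the two dense layer cliques separate while infomap merges matched
pairs into mixed modules; the package's synthetic scenarios therefore
recluster vertically with infomap. This mirrors the empirical,
per-dataset nature of the algorithm choice rather than contradicting it.

**Pairwise concordance** is the complementary gene-by-gene view: genes
significant in at least one layer ("and/or" inclusion) are classified
`up-up`, `down-down`, or `discordant` by the signs of their RNA and
promoter-ATAC fold changes, optionally pairing chromatin changes at 6 h
with transcriptional responses at 12 h to allow for the lag between
remodeling and transcription.

# From modules to a signature

For each integrated module and each cell line, the treatment response is

$$\Delta\mathrm{GFC} = \overline{\mathrm{GFC}}(\text{drug, 6 h}) -
\overline{\mathrm{GFC}}(\text{control}),$$

computed on module mean patterns. The early (6 h) time point drives the
selection because chromatin and early transcriptional changes are the most
informative of the response; the time point is a configuration key. The
control group defaults to the same time point as the treated group.

The *threshold score* of a module is
$\mathrm{thr} = \Delta\mathrm{GFC}_{\text{sensitive}} -
\Delta\mathrm{GFC}_{\text{resistant}}$, and modules **strictly above the
median** thr score (interpolated median for even counts) are selected —
"above q50" is read literally, so when all scores tie, nothing is
selected; the boundary behavior is tested. The median is taken over all
modules of the integrated network (no size or quality pre-filter), and
swapping the cell-line labels negates every score and complements the
selection, an antisymmetry the tests assert.

Selected module genes (layer namespaces stripped, a gene present in both
layers counted once) are then intersected with the baseline differential
contrast between the two *untreated* lines: genes with adjusted p below
0.01 and log2 fold change above +1 form the **up** signature, below −1 the
**down** signature. The thresholds are per-drug configurable (a more
aggressive fold-change floor suits drugs with broader baseline
differences). ATAC-side module members contribute their gene names to the
candidate pool, but the final signature lives purely in transcriptome
space — basal RNA profiles are what is abundantly available downstream.

Two control signatures calibrate any downstream claim: a random signature
of the same sizes drawn from the expression universe, and a "top fold
change" signature taking the extreme baseline log2FC genes without any
perturbation information.

# Scoring basal transcriptomes

The per-sample enrichment machinery follows the gene-set variation
analysis recipe:

1. **Kernel statistic.** For gene $i$ in sample $j$,
   $z_{ij} = \frac{1}{n}\sum_k \Phi\!\big((x_{ij} - x_{ik})/h_i\big)$ with
   bandwidth $h_i = s_i/4$ — the gene's smoothed cross-sample quantile.
   A Poisson kernel (`mean_k ppois(x_ij, x_ik + 0.5)`) serves raw counts;
   `"none"` passes values through. Zero-variance genes carry no ranking
   information and are set to 0.5 everywhere (logged).
2. **Weighted random walk.** Per sample, genes are ordered by decreasing
   statistic; in-set genes step the walk up proportionally to
   $|z|^\tau$ (default $\tau = 1$), out-of-set genes step it down
   uniformly. The enrichment score is the largest positive deviation plus
   the largest negative deviation (`maxdiff`, the default) or the single
   largest-magnitude deviation (`maxdev`). Ranking ties keep stable input
   order — documented because the ES of pathological inputs depends on it.
3. **Sensitivity score** $= ES_{\text{up}} - ES_{\text{down}}$, exactly,
   per sample; swapping the sets negates every score.

An **ssGSEA-style** variant walks over within-sample expression ranks
without the kernel step and integrates the walk (mean running deviation).
The raw integral is biased upward for $\tau > 0$ — with position weights
$w$, the expected in-set CDF at position $k$ is $W(k)/W(N)$ while the
out-set CDF stays near $k/N$ — so the package centers the integral at that
analytic null expectation. Two caveats are documented deliberately: this
variant is *not* what the reference workflow ran, and within-sample rank
walks are confounded by per-gene baseline offsets that the cross-sample
kernel statistic removes, so the two methods agree in sign only when gene
scales are comparable (e.g. after row-centering). The test suite
demonstrates both facts.

# The self-supervised predictor

`trainLasso()` learns to reproduce sensitivity scores from basal
expression: hold out 20% of samples, standardise features on the training
split only (the leakage-freedom is asserted by a test that perturbs
held-out rows and checks the fitted model is unchanged), choose the L1
penalty by 10-fold cross-validation (`cv.glmnet`, convergence threshold
1e-7), and report Pearson r and RMSE on the untouched split. The penalty
rule defaults to `lambda.min` (maximising fit, matching the near-perfect
closure the workflow reports); `lambda.1se` is available. Despite the word
"classifier" in common descriptions of this step, the model is a
continuous regression — the labels are continuous scores and the reported
metrics are R/RMSE.

The scientific point of the exercise is the **signature-exclusion check**:
dropping every signature gene from the feature matrix *before* the split
and retraining. If held-out performance survives, the sensitivity axis is
encoded redundantly across the transcriptome rather than memorised from
the signature itself. The synthetic cohort plants exactly this redundancy
(a background block correlated with the latent factor at $\rho = 0.9$).

# The synthetic-data generator

The generator defines the study conditions under which every recovery
claim is tested.

* **Perturbation datasets**: 2 cell lines × {control, drug M, drug B} ×
  {6 h, 12 h} × 3 replicates (36 samples, 12 condition groups), two
  layers. Counts are negative binomial with log2 mean = baseline (default
  7, ≈128 counts) + the feature's planted group pattern + its cell-line
  baseline shift; per-sample library-size factors are log-normal with CV
  0.1. Dispersion defaults to 0.01: clonal cell-line replicates are tight,
  and this is the regime in which 3-replicate Welch contrasts have
  realistic power. Background features have flat means drawn ±2 log2
  around baseline. The ATAC layer is simulated directly at promoter-peak
  level: every gene gets a primary promoter peak, 10% get a weaker
  secondary promoter peak and 5% a non-promoter decoy peak, so the
  reference-peak tie-breaking rules are exercised, not just implemented.
  Planted modules can live in one layer or both (`layer = "both"` plants
  the same genes with the same pattern in both layers — promoter opening
  driving transcription).
* **Basal cohorts**: each sample draws a latent sensitivity
  $s \sim U(0,1)$; signature-up genes increase linearly in $s$, down genes
  decrease, background genes split into a block correlated with $s$ at a
  chosen $\rho$ and independent noise genes; all Gaussian on the log scale
  with per-gene baselines drawn ±1 around the cohort mean. Phenotypes are
  strictly monotone in $s$ (linear or logistic-monotone) before additive
  noise.
* Everything is a pure function of its arguments and seed; same seed,
  bit-identical output.

What the generator does **not** emulate — and therefore what passing tests
do *not* establish about real data: batch effects and surrogate-variable
structure, peak-calling and annotation errors, transcript-level
complexity, non-promoter regulation, heteroscedastic dispersion trends,
and cohort population structure beyond a single latent axis. Recovery
results on this generator demonstrate correctness of the machinery under
its stated assumptions, not field performance.

# Numerical choices and degenerate inputs

* Edge retention and cross-layer matching use inclusive ≥ cutoffs.
* Zero-variance GFC rows cannot be correlated and are dropped with a
  warning; zero-variance genes under the Gaussian kernel score 0.5.
* Degenerate Welch contrasts (zero variance in both groups) give p = 1
  when the means agree and p = 0 otherwise.
* Median selection uses R's interpolated median; "above" is strict.
* All tie-breaks are deterministic: lexicographic peak ids, stable
  ranking order, higher cutoff on mixing-score ties, larger community
  first when naming modules.
* Whether reported node counts include isolated nodes is a convention;
  this package drops isolated nodes at construction.

# Problem sizes used by the tests and acceptance script

Module recovery uses 4 planted RNA modules of 50 features over 12 groups
plus 200 background features; vertical integration plants one 30+30
cross-layer module and one unpaired 30-feature module per layer over 150
background features per layer; the end-to-end signature scenario plants
two cross-layer signature modules (30 genes each, baseline shifts ±1.5)
and three decoy modules among 300 background features per layer; score
validity uses 20 cohorts of 60 samples (effect size 1, noise 0.3); the
predictor closure uses one 500-sample, 2000-gene cohort with
$\rho_{\text{background}} = 0.9$. These sizes keep each stage's planted
structure unambiguous while exercising all code paths.

# A worked example

```{r example, eval = FALSE}
design <- standardDesign()
sensM <- setNames(rep(1.5, 2), c("sensitive|M|6h", "sensitive|M|12h"))
specs <- list(
    plantedModule("U", "both", 30, sensM, baseline_shift = 1.5),
    plantedModule("D", "both", 30, sensM, baseline_shift = -1.5),
    plantedModule("dec1", "rna", 30,
        setNames(rep(1.5, 4), c("sensitive|B|6h", "sensitive|B|12h",
            "resistant|B|6h", "resistant|B|12h"))))
sim <- simulatePerturbationDataset(specs, design, seed = 1)
res <- runCrosswisePipeline(sim$rna, sim$atac, sim$annotation, design,
    sensitive = "sensitive", resistant = "resistant", drug = "M")
res$signature

cohort <- simulateCohort(res$signature, n_samples = 200,
    n_background = 500, rho_background = 0.9, seed = 2)
scores <- sensitivityScore(cohort$expr, res$signature)
fit <- trainLasso(t(cohort$expr), scores$score, seed = 3)
fit$report
```

# Known limitations

* The Welch/BH differential stage trades the power of shared-dispersion
  negative-binomial models for simplicity; at 3 replicates this matters,
  and external differential tables are first-class inputs for that reason.
* GFC capping slightly distorts correlations of strongly shifted features.
* The integrated edge counts of any particular published analysis are not
  reconstructable from module-level descriptions alone; this package's
  cross-layer wiring rule is one defensible instantiation.
* ssGSEA-style scores are not comparable across genes with heterogeneous
  baselines (see above); the GSVA-style route is the default everywhere.
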