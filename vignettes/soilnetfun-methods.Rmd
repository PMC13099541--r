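---
title: "Methods: from stand density to soil multifunctionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stand density to soil multifunctionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilnetfun)
```

soilnetfun implements the analysis chain that links a plantation's stand
density to integrated soil function through the soil microbiome: diversity
estimation, co-occurrence network inference, robustness simulation,
multifunctionality indices, and the statistics that tie the stages together.
This vignette is the package's account of the methods themselves — the
models, their assumptions, the tunable parameters, and the design decisions
taken where the conventions of the field leave room.

## The study design and the synthetic generator

The emulated design is a density gradient (very high, high, moderate, low —
2,450, 1,633, 1,067 and 583 trees ha⁻¹) crossed with two soil layers
(0–20 and 20–40 cm) and six replicate composite samples per cell: 48
samples. `study_design()` encodes it; `replicates` switches to other
intensities (published analyses of this design sometimes report a 36-sample
subset without stating which samples were dropped, so the generator exposes
the replicate count rather than guessing a subset).

**Soil properties.** `generate_soil_table()` draws each of twelve variables
(pH; SOC, EOC, TN, TP, TK in g kg⁻¹; AN, NN in mg kg⁻¹; the enzyme
activities PPO, URE, PHO, NR in their assay units) from a truncated normal
with per-cell means and standard deviations. The defaults in
`default_soil_params()` are field-observed cell statistics from a
*Pinus sylvestris* plantation on sandy soil, e.g. surface soil under very
high density has pH 6.50 ± 0.04 and SOC 6.69 ± 0.26 g kg⁻¹. They encode the
unimodal density response the field data show: nutrient pools and enzyme
activities peak under high-to-moderate density. Truncation at zero reflects
non-negative measurements; pH is truncated to [3, 10]. With all SDs set to
zero the generator returns the cell means exactly, which the tests exploit.

**ASV counts.** `generate_abundance_table()` composes per-sample expected
proportions as `softmax(base + density effect + depth effect + noise)` and
draws one multinomial per sample at a sequencing depth drawn from a normal
(rounded, floored at 1). The noise is logistic-normal — iid normal
perturbations of the log-proportions with standard deviation `dispersion` —
chosen over a Dirichlet because it gives independent per-taxon control of
planted effects while still inducing realistic compositional correlation
after the softmax. Two presets encode the qualitative contrast the field
data show: `bacterial_composition_model()` (300 taxa, no density effect) and
`fungal_composition_model()` (120 taxa, graded log-fold shifts on a quarter
of the taxa along the density gradient). Default depth 30,000 ± 2,000 reads
comfortably exceeds the 20,000-read rarefaction target. The default taxon
counts are large enough to leave a workable network after the 80% prevalence
filter yet small enough for desk-scale eigendecompositions.

**What the generator does not emulate:** taxonomic structure (no phylogeny,
no realistic rank-abundance tail beyond the lognormal-ish base profile),
read-level artifacts (chimeras, denoising), spatial autocorrelation between
plots, and any true ecological interaction between taxa — co-occurrence in
the synthetic tables arises from shared responses to the planted design, not
from interaction. Passing tests therefore demonstrate that the estimators
recover what was planted under the stated noise model, not that the pipeline
recovers interaction networks from real communities.

**Linked structure.** `generate_linked_dataset()` plants ground truth for
the linkage statistics: a regression of multifunctionality on network
stability, and a four-block causal chain density → environment → network →
multifunctionality. Each chain stage applies its raw coefficient to the
*population*-standardized previous stage and adds iid noise; standardizing
by sample statistics instead would couple the samples and shrink the true
sampling variance of downstream estimators below iid level. The truth record
carries both the raw slopes and the implied standardized coefficients
`b/sqrt(b² + σ²)`, because ordinary regression on the raw scales targets the
former while PLS-PM (which standardizes everything) targets the latter.

## Diversity

Alpha estimators are computed from their definitions on integer counts.
Chao1 uses the bias-corrected form `S + F1(F1−1)/(2(F2+1))`, which stays
finite when no doubletons exist. ACE uses the abundance-based coverage form
with the conventional rare cutoff of 10. Shannon is in natural log (the
default of the R ecosystem this sits in). Simpson is reported as the
Gini–Simpson complement `1 − Σ pᵢ²` so that larger means more diverse,
with a `simpson_form = "dominance"` switch. Pielou is undefined for
single-taxon samples and returned as `NA` with a warning. Rarefaction is a
single subsample without replacement (not an average over draws); samples
below the target depth are dropped with a message.

PERMANOVA permutes raw sample labels freely — no strata, since the design
this emulates did not report restricted permutation — and reports
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`, so the smallest attainable p is
`1/(n_perm+1)`. PCoA reports negative eigenvalues rather than silently
dropping them (Bray–Curtis matrices are generally non-Euclidean), with a
Cailliez correction behind a flag. The Mantel test is one-sided for positive
association, the vegan convention, and its Spearman variant ranks the
off-diagonal values once — ranking commutes with simultaneous row/column
permutation, which makes the permutation loop cheap without changing the
statistic.

## Co-occurrence networks

The construction follows the common field recipe: prevalence-filter the
rarefied table (keep taxa present in at least 80% of samples, boundary
inclusive), compute pairwise Spearman correlations, and keep edges with
`|r| > 0.6` and `p < 0.05`. Both thresholds are strict inequalities, so a
correlation of exactly 0.6 is not an edge. No multiple-testing correction is
applied by default because the recipe is stated on raw p-values; a
Benjamini–Hochberg flag exists for users who want it. p-values use the
two-sided t approximation `t = r√((n−2)/(1−r²))`; an exact permutation
p-value over all n! orderings is available for n ≤ 8, where the
approximation is at its weakest. Constant taxa have undefined correlations
and never form edges. Whether correlations are computed within each
density × depth group or pooled is left to the caller — the package operates
on whatever table it is handed — because published descriptions of this step
are typically ambiguous about pooling.

Topology metrics follow the Gephi conventions the field reports: average
path length is the mean shortest path over connected pairs (within
components), diameter the maximum over components, the clustering
coefficient is the average local clustering with degree-<2 nodes
contributing zero (global transitivity behind a switch), and modularity is a
Louvain partition of the unweighted, sign-ignored graph at resolution 1
under a caller-fixed seed. Isolated nodes are dropped by default, matching
what an edge-list import into a graph tool would contain.

## Natural connectivity and stability

Natural connectivity is `ln((1/N) Σᵢ e^{λᵢ})` over the eigenvalues of the
binary adjacency matrix — the log of the average closed-walk generating
function, a spectral measure of route redundancy. It is evaluated through a
log-sum-exp (eigenvalues reach N−1 on dense graphs, so direct
exponentiation overflows), and the empty graph is defined as 0 by
convention. Signs and weights are ignored: the robustness literature and the
field's tooling operate on the binary skeleton.

The removal simulation deletes `floor(f·N)` uniformly chosen nodes for each
fraction `f` on a 1%–99% grid in 1% steps, 1,000 times per fraction, and
records the mean (and sd) of the remaining graph's natural connectivity.
The grid stops at 99% because the all-removed value is conventional, not
structural, and would otherwise leak into the slope. The stability score is
the OLS slope of the mean curve against `f` — fitted on the averaged curve,
not averaged over per-run slopes, matching the "slope of the decline after
1,000 averaged simulations" phrasing of the procedure this reproduces.
Slopes are in natural-connectivity units per unit removal fraction; rankings
(the quantity of scientific interest) are invariant to the unit choice.
The hot loop (≈10⁵ eigendecompositions per curve) is C++ via RcppArmadillo,
driven by R's RNG so `set.seed()` gives bit-identical curves; the pure-R
`natural_connectivity()` serves as its oracle in the tests. The per-fraction
sd uses a two-pass computation — the one-pass form cancels catastrophically
when all removals are isomorphic (every half of K₁₀ is a K₅) and reports
spurious variance. Graphs beyond ~2,000 nodes trigger a warning recommending
subsampling.

## Multifunctionality

Seven functions enter the indices — nutrient pools (SOC, TN), available
pools (AN, NN) and process rates (URE, PHO, NR) — min-max normalized across
*all* samples (both depths, all densities; a per-depth option exists). The
M-index is the arithmetic mean of the normalized values; the T-index is the
share of functions strictly exceeding 70% of that function's maximum
normalized value, so with non-degenerate normalization the cutoff is 0.7.
Strictness means ties at the cutoff do not count, and at `quantile = 1` the
index is identically zero — documented boundary behaviour rather than a
special case. A constant function is normalized to zero with a warning
instead of being dropped, keeping the T-index denominator at seven.

## Linking networks to function

`rf_importance()` delegates forest growth to randomForest but computes
%IncMSE in-package: for every tree, the out-of-bag MSE is evaluated with the
original and with a permuted copy of one predictor column, and the per-tree
percent increases are averaged. Model fit is the out-of-bag R². Defaults:
500 trees, seed-controlled permutation.

`fit_plspm()` is a from-scratch PLS path model: indicators standardized,
outer weights initialized at 1, alternation of inner estimation (centroid
scheme by default — the classical default of the plspm lineage; factorial
and path schemes behind a flag) with mode-A (reflective) outer estimation,
until the largest outer-weight change drops below 1e-6 (error, reporting the
last delta, after 300 iterations). Latent scores are standardized and
sign-anchored to each block's first indicator, which resolves the sign
indeterminacy of PLS weights deterministically; single-indicator blocks
therefore reduce exactly to the standardized indicator and converge in one
iteration. Structural coefficients are OLS fits of each endogenous latent on
its predecessors, with per-block R². The bootstrap (default 1,000
replicates, seeded) resamples rows, refits the full algorithm, and reports
percentile 95% intervals and standard errors.

Effect decomposition enumerates every directed path between each ordered
block pair in the structural DAG: the direct effect is the direct edge's
coefficient, each indirect effect is a product of coefficients along one
longer path, the total is their sum, and the indirect share is
indirect/total. This is exact — no matrix-series approximation — and is
checked in the tests against an independently written recursive enumerator.

Default indicator sets for the four latent blocks (density as trees ha⁻¹;
environment as the soil chemistry panel; network as edge count, modularity
and stability slopes; multifunctionality as M and T) are package choices:
published path diagrams of this design do not enumerate their indicators,
so the blocks are configuration, not inference.

## Numerical choices and problem sizes

Tolerances: natural connectivity is validated to 1e-10 against closed forms
and a spectral oracle; PLS convergence is 1e-6 on outer weights;
permutation p-values have resolution `1/(n_perm+1)`. Tie-breaks: stability
rankings break `|slope|` ties by group label; the stability median split
assigns scores at the median to the high-stability group. Degenerate inputs
(empty samples, constant taxa or variables, single-taxon samples,
single-sample normalization) are either errors or flagged `NA`s, never
silent.

The test suite exercises the estimators at sizes chosen to make their
statistical guarantees measurable on a single desk CPU: type-I error of
PERMANOVA and Mantel over 1,000 null datasets (199 permutations each),
random-forest signal detection over 100 seeded runs at n = 200 with a 5:1
signal-to-noise ratio, PLS recovery at n = 1,000 with noise sd 0.2 and
bootstrap coverage over 200 replicates of 1,000 resamples, and robustness
curves on graphs up to 200 nodes at the full 99-point grid with 1,000
simulations per fraction.

## Known limitations

Correlation networks are not interaction networks; nothing here corrects
for compositionality (no CLR transform, no SparCC-style inference), because
the implemented recipe is the field's thresholded-Spearman construction.
PERMANOVA is one-way only. The PLS bootstrap reports percentile intervals
only (no BCa). PCoA on large sample sets is dense-matrix. The random-forest
importance inherits randomForest's handling of correlated predictors:
duplicated predictors share importance, which the tests assert rather than
hide. And the synthetic generator's defaults describe one real study system;
transferring conclusions to other designs means re-parameterizing it, not
trusting the defaults.
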