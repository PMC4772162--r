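---
title: "Models and methods behind phytoregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phytoregions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phytoregions)
```

`phytoregions` turns presence-only occurrence records and gridded
environmental predictors into a richness map, a set of floristic
regions, and an environmental characterization of the turnover between
them.  This vignette explains each model in the chain, the parameters
that matter, the numerical conventions, and what the synthetic test
worlds do and do not demonstrate.

## The data model

Everything is indexed on a rectangular lattice of grid cells
(`make_grid()`), default resolution 10 arc-minutes.  Cells are half-open
intervals `[lon0 + i·s, lon0 + (i+1)·s)` so that every coordinate maps
to exactly one cell; inside-domain cells carry contiguous ids
`0..n_cells − 1`.  Occurrences are species–cell presences: duplicate
records of a species within a cell collapse to one presence, and
species occupying fewer than `min_cells` (default 5) distinct cells are
removed as too sparse to model.  Environmental layers arrive as ESRI
ASCII grids and are resampled to the analysis grid — mean aggregation
for continuous layers, nearest-neighbour for categorical ones (declared
per layer, so class codes are never averaged).  Cells left without a
value by any layer are masked out of the domain with a logged count.

## Predictor screening and collection-bias diagnosis

Collinear predictors cause unstable presence-only fits, so the
environmental matrix is pruned greedily on Spearman rank correlation
(`prune_predictors()`, cutoff `rho_max = 0.75`): predictors are visited
in a caller-supplied priority order — an explicit, reproducible encoding
of the otherwise subjective "keep the ecologically most meaningful
variable" choice — and a predictor is dropped when it correlates at or
above the cutoff with anything already kept.

`bias_test()` asks whether the collection localities are a random
sample of environmental space: each predictor's domain-wide range is cut
into `n_bins = 10` equal-interval bins, expected counts are the domain
bin proportions scaled to the number of collection cells, and a Pearson
chi-square is computed.  Bins that are empty over the whole domain are
merged into their nearest occupied neighbour, reducing the degrees of
freedom accordingly; equal-interval binning makes the statistic
invariant under affine transforms of a predictor (a property the test
suite checks).  Two caveats are worth knowing.  First, when the
localities are a large fraction of the domain, without-replacement
sampling shrinks the statistic below its nominal multinomial
distribution, making the test conservative; the calibration check in
the test suite therefore uses a ~5% sampling fraction.  Second, the
number of testable predictors is data-driven (constant predictors are
flagged untestable), so reports should quote the per-run count rather
than assume a fixed one.

## Presence-background SDMs

`fit_sdm()` estimates a maximum-entropy distribution over domain cells,
using the standard equivalence with an L1-penalized log-linear model
contrasting presences against heavily weighted background (all domain
cells by default; the presence cells are part of the background, as the
presence-background contract requires).  glmnet solves the penalized
likelihood; everything around it — feature construction, penalties,
output transform — is defined here:

* **Features.** Predictors are standardized over the background.
  Linear features are the predictors themselves; quadratic adds their
  squares; hinge adds, per predictor, forward and reverse ramps at 10
  interior background quantiles each (20 thresholds per predictor).
  The feature class is keyed on sample size — 5–10 records linear,
  11–14 quadratic, ≥15 hinge — so complexity grows with information.
  The class bands are taken as half-open at the top of each range,
  which covers every n ≥ 5 exactly once.
* **Regularization.** The penalty on feature *j* is
  `β(class, m) · sd_j(presences) / √m` times a user multiplier, with
  `β` interpolated from a per-class table (linear: 1.0 at m=10 down to
  0.05 at m≥100; quadratic: 1.3 down to 0.05; hinge: 0.5 throughout,
  floored at `0.5/√m`).  The table is a package default in the spirit
  of the canonical MaxEnt settings; it is part of the configuration,
  not a claim of numerical parity with any particular implementation.
  Increasing the multiplier can only shrink the active feature set
  (L1 path monotonicity, checked in the tests).
* **Output.** The fitted intensity is normalized to a probability
  `raw` over cells and mapped to suitability by the complementary
  log-log transform `1 − exp(−exp(H)·raw)` with `H` the entropy of
  `raw`.  All downstream thresholding rules are rank-based, so this
  monotone choice does not affect presence/absence outcomes.

Accuracy is the Mann–Whitney AUC against background with ties counted
1/2; constant suitability scores 0.5 by construction.  Note that with
few presences and flexible features even randomly placed records
produce training AUCs well above 0.5 — this is precisely why a null
model, not a fixed AUC cutoff, decides significance.

## The bias-corrected null model

`null_auc_distribution()` draws `n_records` cells uniformly without
replacement *from the collection localities only*, fits an SDM under
the same feature rule, and records its AUC; `n_null = 1000` replicates
by default.  Because the null species inherit the collecting bias, the
test asks "does this species beat what bias alone explains?".  A
species is significant when its observed AUC strictly exceeds the
nearest-rank 95th percentile (`ceiling(0.95·n)`-th order statistic) of
the nulls; ties are conservatively non-significant, and the reported
`p_rank` is `(1 + #{null ≥ observed}) / (n_null + 1)`.  Distributions
are cached per record count, since all species with equal `n_records`
share one null.  Under unbiased collecting this construction is
exchangeable, giving an exact 5% type-I rate — the acceptance suite
verifies the rejection count of 100 random species against the
binomial 95% interval.

## Thresholding, stacking, richness drivers

`choose_threshold()` converts suitability to presence/absence: species
with 5–9 records use the sensitivity=specificity threshold (sum
maximization is available), species with ≥10 records the 10-percentile
training threshold.  Percentiles interpolate linearly between order
statistics and presence is scored at suitability ≥ threshold, making
training omission equal to 10% up to a 1/n rounding.  `stack_sdms()`
assembles the binary cells × species matrix; richness is its row sum.

`trend_surface_terms()` builds the nine-term cubic surface in
coordinates centered on their mean and scaled to unit range — an affine
change that leaves every R² unchanged while keeping cubic terms
well-conditioned.  `variation_partition()` reports the adjusted-R²
decomposition (pure environment, pure space, shared, unexplained);
slightly negative fractions are reported as-is since they are a known
artifact of adjusted R², and the four fractions sum to one by
construction.  `stepwise_regression()` is forward-only with entry at
partial-F p < 0.05, choosing at each step the largest gain in
cumulative adjusted R²; predictors are standardized internally so
coefficients are betas, and t-values are reported for the final model
(not the entry step).  Residual spatial autocorrelation is diagnosed by
Moran's I with row-standardized rook weights, expectation −1/(n−1) and
a normal-approximation two-sided p.

## Bioregionalization

Floristic distance is βsim = min(b,c)/(min(b,c)+a), the
richness-independent turnover index: only the shared count and the
poorer cell's unique count enter, so a richness gradient alone cannot
create apparent regions.  Cells with zero modeled species are excluded
(with a census) before the pairwise matrix is built; genus-level
analysis aggregates columns through a species→genus map.  Clustering is
UPGMA (average linkage); determinism follows from the fixed input
order, and exact distance ties — a measure-zero event for continuous
dissimilarities — are resolved by the agglomeration order of `hclust`.

The number of regions is selected by indicator species analysis:
IndVal(species, cluster) = specificity × fidelity × 100, species score
= max over clusters, significance by label permutation.  For each of
`n_repeats = 5` seeded subsamples (default up to 1000 cells), the
subsample's UPGMA tree is cut at every k in 2–30 and the summed species
p-values recorded; the k minimizing the mean curve wins, and final
labels come from cutting the full-matrix dendrogram at that k (merging
subsample partitions was the alternative; cutting the full tree keeps
every cell labeled by the same dendrogram that is reported).  Summing
raw p-values is the default score; counting significant indicators is
available behind a flag.

## Ordination and relative environmental turnover

`nmds_ordination()` minimizes Kruskal stress-1 (monotone regression of
configuration distances on dissimilarities) from `n_starts = 100`
seeded random configurations, keeping the best start; scores are
centered and rotated to principal axes.  Convergence uses a stress
floor of 1e-7, a stress-ratio cap of 0.999999 and up to 500 iterations
per start; an error with per-start diagnostics is raised if no start
converges.  Stress lives in [0, 1]: 0 is a perfect rank-order embedding
(verified on exactly planar configurations), 1 a complete lack of
correlation.

`fit_env_vectors()` regresses each standardized predictor on the score
axes: r² is the variance explained, the normalized coefficient vector
is the direction of fastest increase, and the p-value permutes the
predictor across cells (999 permutations, reporting threshold
P < 0.001).  `ret_table()` characterizes regions environmentally:
predictors are mean-aggregated to a factor-2 coarsened grid (the
default halves the linear resolution), region labels transfer by
majority vote, and Gi* is computed per region × predictor with the
global mean and population standard deviation — regions are judged
against the whole domain, not against their neighbourhoods, so no
distance-decay weights enter.  |Gi*| > 2 flags a significant
environmental difference, and for any predictor the region z-values
cannot all share one sign because the region sums are constrained by
the global mean.

## The synthetic world

`simulate_world()` generates the structure each stage assumes, with
known truth:

* **Environments** are Gaussian-smoothed white noise (correlation
  length 5 cells by default) with a monotone latitudinal
  temperature-like gradient and a longitudinal precipitation-like
  gradient; optional near-duplicate predictors exercise pruning.
* **Species** have Gaussian niches on 1–3 predictors, centered on the
  environment of a random cell; breadth is tuned by bisection until
  realized prevalence (cells with suitability > 0.5) falls in the
  requested range (default 5–30%).
* **Regions**, when requested, are contiguous k-means blocks of the
  lattice.  Each species belongs to one block's pool (with an optional
  globally shared fraction) and its suitability decays as
  `exp(−sharpness·d)` outside its block.  Regions also shift predictor
  baselines (`region_env_contrast`, default 1 SD): real biogeographic
  regions are environmentally distinct, and without that distinctness
  purely environmental SDMs necessarily smear spatial region
  boundaries, capping label recovery well below what sharp floristic
  turnover implies.
* **Collecting** draws visit events cell-by-cell with probability
  proportional to an accessibility layer (random "road" corridors)
  raised to `bias_strength`, then records a presence with probability
  equal to true suitability — detection equals suitability, no false
  presences.  `effort` counts visit events, so retained record numbers
  are smaller by the mean acceptance probability.

What passing tests on these worlds shows: the estimators recover truth
when their assumptions hold (smooth environments, niche-driven
occupancy, environmentally distinct block regions, known bias form).
What they do not show: robustness to taxonomic error, temporal
collecting dynamics, detection varying independently of suitability,
non-corridor bias geometries, or phylogenetic structure — none of which
the generator emulates.

## Problem sizes and determinism

The default desk-scale world is a 40 × 30 grid (1200 cells) with 8
predictors and 150–300 species — large enough to span the 5–10 / 11–14
/ ≥15 record regimes, small enough for minutes-scale test runs.  The
test suite uses 199-replicate nulls for the type-I calibration (100
random species, shared cache), 200 replicates for the bias-test
calibration, and a 4-region recovery world with turnover sharpness 4
and 60,000 collecting events (median ≈ 18 records per species), scored
with 5 × 500-cell subsamples and 199 permutations per indicator
analysis.  The cluster-number curve needs that much replication:
with only 2 × 300-cell subsamples its minimum is visibly noisy.
Region-layout draws vary in difficulty — k-means occasionally produces
two adjacent blocks with similar environmental baselines, which depresses
recovery for that draw — so recovery checks fix the world seed.

Every stochastic function takes an explicit seed and restores the
caller's RNG state; replicate seeds derive from the master seed, and
rerunning any stage (or `run_pipeline()`) with the same configuration
is bit-identical.  Known limitations: no caching/resume of pipeline
intermediates (reruns are cheap at desk scale); raster input is ESRI
ASCII only; no spatial regression (Moran's I diagnoses residual
autocorrelation but the models remain OLS); and the null model corrects
collection bias only — it cannot rescue a species whose records
misrepresent its niche for other reasons.
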