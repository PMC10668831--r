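---
title: "The optimal-MaxEnt niche modelling workflow in nichemax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The optimal-MaxEnt niche modelling workflow in nichemax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemax)
```

# The model

`nichemax` implements presence-background species distribution modelling
with a maximum-entropy (MaxEnt) model written from first principles. Given
presence feature vectors $f(x_i)$, $i = 1 \dots m$, and a background sample
$B$ of landscape cells, the model is the Gibbs density over $B$

$$ q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z_\lambda}, \qquad
   Z_\lambda = \sum_{x \in B} \exp(\lambda \cdot f(x)), $$

fitted by maximizing the L1-penalized presence log-likelihood

$$ \ell(\lambda) = \frac{1}{m}\sum_i \lambda \cdot f(x_i) - \log Z_\lambda
   - \sum_j \beta_j |\lambda_j|. $$

This is the convex dual of entropy maximization subject to relaxed
moment constraints: at any optimum every feature satisfies
$|\mathbb{E}_q[f_j] - \bar f_j^{\text{presence}}| \le \beta_j$, which the
test suite checks numerically (the KKT moment-matching bound), and the
fitted objective is verified against an independent generic convex
optimizer on small instances.

## Features and regularization

Covariates are rescaled to $[0,1]$ using background minima/maxima (values
outside the training range clamp at prediction time). Five feature
classes are available — linear (L), quadratic (Q), product (P), threshold
(T) and hinge (H). Threshold and hinge features use a fixed ladder of
evenly spaced interior knots (30 per variable by default); a fixed ladder
keeps candidate models comparable across the calibration grid, whereas
data-adaptive knot placement would make the AICc parameter counts depend
on the presence sample.

Penalties are $\beta_j = \mathrm{RM} \cdot \beta_{\text{class}}(m) \cdot s_j$
with $s_j$ the feature's standard deviation over the presences, RM the
global regularization multiplier, and $\beta_{\text{class}}$ the
published MaxEnt default tables: linear/quadratic/product interpolated on
the presence count over $(0,10,17,30,100) \to (1,1,0.6,0.5,0.05)$, hinge
$0.5$, threshold $1$.

Optimization is cyclic coordinate descent with soft-thresholding. Each
coordinate takes a proximal Newton step under the exact one-dimensional
curvature of $\log Z$, backtracking by step halving until the penalized
objective does not decrease — the objective is therefore monotone by
construction, a property asserted in the tests. Convergence is declared
when the relative objective change over a full sweep falls below
$10^{-6}$ (500-sweep cap). Coordinates whose gradient lies strictly
inside the penalty at the start of a sweep are skipped, which keeps large
hinge ladders cheap.

## Output transforms

The raw output sums to one over the training support. The logistic and
complementary log-log transforms both use $c = e^H$ where $H$ is the
entropy of the fitted distribution: logistic $cq/(1+cq)$, cloglog
$1 - e^{-cq}$. cloglog is the default, the convention of MaxEnt releases
3.4 and later. All three are monotone in the raw output, so rankings,
AUC and binarizations agree across transforms up to threshold choice.

Presence points are appended to the background support before
normalization, which keeps $\log q$ finite at every presence and hence
makes the AICc likelihood well defined.

# Calibration by AICc

Candidate models form a grid of regularization multipliers by
feature-class combinations. The package default axes are RM
$= 0.1, 0.2, \dots, 4.0$ and all 31 non-empty subsets of {L,Q,P,T,H}.
`fc_grid_paper()` provides the alternative 29-entry axis — the 31 subsets
minus the standalone P and T classes, which are not used alone in MaxEnt
practice — giving the familiar $40 \times 29 = 1{,}160$-candidate grid.

Each candidate is fitted on the full thinned presence set against one
shared background, and scored with
$\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$, where $k$ counts
non-zero coefficients, $n$ is the presence count and $\ln L$ sums log raw
predictions at the presences. Candidates with $k \ge n-1$ are invalid.
The selected model is the $\Delta\mathrm{AICc} = 0$ candidate, ties
broken by smaller $k$, then smaller RM, then grid order.

The final model re-fits the winning setting 10 times on random 75/25
train/test subsample splits of the presences ("random seed" subsample
replication), reports mean ± sd of training AUC, test AUC and TSS, and
averages the per-replicate cloglog maps cellwise.

# Variable screening and importance

Screening is two-stage. Stage 1 drops variables whose percent
contribution in an initial all-variable model falls below 0.1 percentage
points. Percent contributions credit each coordinate-descent update's
objective change to the updated feature's source variable(s) (split
equally for products), then normalize positive credits to 100. Stage 2
walks the survivors in decreasing contribution and keeps a variable only
if its absolute Pearson correlation with every already-kept variable is
below 0.8, so the higher-contribution member of any collinear pair
survives. Correlations are computed across all mutually valid grid cells
rather than at occurrence points: the grid-wide frame is data-independent
and reproducible, at the cost of weighting regions the species never
occupies. Ties in contribution break alphabetically; zero-variance
layers have undefined correlations and are dropped with a warning.

Jackknife importance refits the model with only, and without, each
variable, reporting regularized training gain (objective plus
$\log |B|$), test gain and AUC against the full-model baselines. The
jackknife uses the same feature family as the final models (hinge-rich
LQH): importance should be measured with the response shapes the final
model can actually express, and with-only fits restricted to linear and
quadratic terms systematically under-measure variables whose true
response is a narrow bell.

# Classification, areas and range dynamics

Continuous suitability $P$ is reclassified with lower-inclusive
intervals: non $[0, 0.05)$, poor $[0.05, 0.33)$, moderate
$[0.33, 0.66)$, high $[0.66, 1]$. Class areas use exact spherical cell
areas $R^2\,\Delta\lambda\,(\sin\varphi_N - \sin\varphi_S)$ with
$R = 6371$ km, reported in $10^4$ km²; the spherical (rather than
ellipsoidal) figure errs by under 0.3% at subtropical latitudes and
keeps the arithmetic exactly reproducible. Class areas partition the
valid area to machine precision.

Range change binarizes two epochs at the non-habitat bound 0.05
(suitable = poor or better; configurable) and overlays them into never /
stable / expansion / shrinkage, with the exact conservation identities
stable + shrinkage = current suitable and stable + expansion = future
suitable. The suitable-area centroid is the cell-area-weighted mean of
suitable cell centres in geographic coordinates — transparent and
projection-free. Migration vectors use the haversine distance
($R = 6371$ km), the standard initial-bearing formula, and eight
45°-wide compass sectors centred on N, NE, E, ….

# The synthetic scenario generator

All tests run against fully synthetic study scenarios with known truth.
The generator emulates a subtropical monsoon river-basin window
(100–123°E, 24–35°N, 0.25° cells, 44 × 92 grid) — the scale of a
regional pest-risk study:

* **Smooth fields.** White noise low-pass filtered with a normalized
  Gaussian kernel (default decorrelation length 10 cells for climate
  fields). Gaussian filtering was chosen over spectral synthesis:
  simpler, dependency-free, and the lag-1 autocorrelation it produces is
  directly controllable.
* **Climate structure.** Monthly mean temperature combines a 17 °C base,
  a ±9 °C seasonal cycle, cooling of 0.7 °C per degree latitude and
  0.8 °C per degree longitude, a 5.5 °C/km altitudinal lapse over a
  smooth altitude field, and smooth noise (sd 0.8 °C). Precipitation
  distributes an annual total (1,100 mm base, log-sd 0.35) over a
  summer-peaked monsoon cycle, and declines weakly (0.03 log-units per
  degree) along the same axis the temperature gradient follows.
* **Known niche.** True suitability is a product of Gaussians in two
  informative bioclim variables, by default annual mean temperature
  (optimum 17 °C, breadth 1 °C) and annual precipitation (1,100 mm,
  breadth 120 mm) — a narrow thermal envelope of the kind a
  diapause-limited montane-margin insect occupies. Three noise layers
  (decorrelation 4 cells, shorter than the climate fields so they act as
  unrelated environmental layers) and altitude are available as
  confounders.
* **Futures.** Scenario tags add a warming offset (+1.7 °C and +4.0 °C
  by default) and scale precipitation (×1.05, ×1.10). Because
  precipitation declines along the temperature-gradient axis, moistening
  moves the precipitation-optimal contour the same way warming moves the
  thermal band, so the true niche shifts coherently toward the
  east-northeast (the deterministic design bearing is ≈ 89°, inside the
  north-east quadrant; random fields scatter individual realizations
  around it).
* **Occurrences.** 200 records by default, drawn over cells without
  replacement with probability proportional to true suitability and
  jittered uniformly within the cell, so downstream one-record-per-cell
  thinning stays non-trivial.

What the generator does **not** emulate: real station climatologies and
their interpolation error, orographic rain shadows, sampling bias along
roads or rivers, spatially varying record quality, and real species
biology. Passing recovery benchmarks therefore demonstrates that the
pipeline recovers a known truth under idealized smooth fields — not that
it would produce unbiased maps from biased field records.

# Numerical choices and problem sizes

* bio15 (precipitation seasonality) uses the $100\,\mathrm{sd}/(1 +
  \text{mean})$ variant so arid cells never divide by zero; bio4 and
  bio15 use the population standard deviation, matching reference
  bioclim implementations. Quarters are all 12 wrap-around 3-month
  windows; ties go to the smallest starting month.
* Background = all valid cells up to 10,000, else a seeded uniform
  sample of 10,000.
* Thinning keeps, per occupied cell, the record closest (great-circle)
  to the cell centre, ties broken by input order; cell membership is
  half-open $[w, e) \times [s, n)$.
* TSS maximizes sensitivity + specificity − 1 over thresholds
  $0, 0.01, \dots, 1$, returning the smallest maximizing threshold;
  background cells serve as pseudo-absences in both AUC and TSS.
* Pipeline runs expand one global seed into per-stage child seeds
  (`stage_seed()`), so any stage can be re-run in isolation.
* Calibration in the bundled benchmarks uses a compact grid (RM ∈
  {0.5, 1, 2, 4} × {L, LQ, LQH, LQP}, 15 knots) and the default 44 × 92
  scenario with 200 presences — sizes chosen so a complete study runs in
  well under a minute on a laptop while leaving the full 40 × 31 grid
  available through `tuning_grid()`.

# Known limitations

* No clamping/extrapolation diagnostics (MESS) and no sample-bias
  grids; projections beyond the training range clamp silently.
* The coordinate-descent fit is not bit-compatible with the Java MaxEnt
  binaries, although it optimizes the same penalized likelihood family.
* Raster I/O is plain ESRI ASCII grid; there is no GeoTIFF writer.
* Centroids are arithmetic in geographic coordinates with area weights;
  a projected-CRS centroid would differ slightly for large regions.
* partial-ROC and omission-rate candidate pre-filters are not
  implemented; calibration is by ΔAICc alone, with hooks in the
  candidate table for additional filters.
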