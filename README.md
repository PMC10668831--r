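# nichemax

Presence-background ecological niche modelling ("species distribution
modelling") with a from-scratch, fully tested maximum-entropy (MaxEnt)
core and the surrounding "optimal MaxEnt" calibration workflow:
bioclimatic variable derivation, occurrence thinning, contribution- and
correlation-based variable screening, AICc model selection over a
regularization × feature-class grid, replicated evaluation (AUC/TSS),
jackknife variable importance, four-class suitability mapping, and
future-scenario range-change and centroid-migration analysis.

It is written for ecologists and biosecurity analysts who need an
auditable, scriptable version of the workflow usually assembled from the
Java MaxEnt GUI, kuenm/ENMeval and ArcGIS — and for method developers who
want every stage testable against synthetic data with known truth.

## The model

Given `m` presence cells and a background sample `B`, MaxEnt fits the
Gibbs density

    q(x) = exp(λ·f(x)) / Z,   Z = Σ_{x∈B} exp(λ·f(x))

by maximizing the L1-penalized log-likelihood

    (1/m) Σ_presences λ·f(x_i) − log Z − Σ_j β_j |λ_j|

with per-feature penalties `β_j = RM · β_class(m) · sd_presence(f_j)`
(published MaxEnt default class tables; RM is the regularization
multiplier). Features are linear, quadratic, product, threshold and
hinge transforms of the covariates rescaled to [0,1]. Fitting is cyclic
coordinate descent with soft-thresholding and a monotone (backtracked)
objective; the suite verifies the fit against an independent convex
solver and checks the KKT moment bound `|E_q[f_j] − f̄_j| ≤ β_j`.

Candidate models over an RM × feature-class grid are scored with
`AICc = 2k − 2 ln L + 2k(k+1)/(n−k−1)` (k = non-zero coefficients) and
the ΔAICc = 0 candidate is refitted in 10 random-subsample replicates.
Suitability (cloglog, in [0,1]) is classified at 0.05 / 0.33 / 0.66 into
non / poor / moderate / high habitat; binary overlays between epochs
give stable / expansion / shrinkage areas (spherical cell areas,
R = 6371 km) and the suitable-area centroid's migration distance,
bearing and compass sector.

## Worked example

A complete study on a synthetic scenario with a known niche
(two informative bioclim variables + three noise layers, 200 occurrence
records, two future climate tags):

```r
library(nichemax)

cfg <- default_config(seed = 20)
cfg$tuning <- list(rm = c(0.5, 1, 2), fc = c("L", "LQ", "LQH"), skip = FALSE)
cfg$n_knots <- 15
res <- run_pipeline(cfg, out_dir = "demo_run")
```

which logs:

```
[scenario] generated 44 x 92 grid, epochs: current, ssp126, ssp585
[thin] 200 records -> 200 after grid thinning
[background] 4048 background cells, 200 presences
[screen] kept 5/5 variables: bio1, bio12, noise1, noise3, noise2
[tune] 9 candidates; best fc=LQ rm=0.5 (k=7, AICc=2799.00)
[fit] 10 replicates; mean test AUC 0.935
[classify] current class areas (1e4 km2): non=162.72 poor=46.57 moderate=36.69 high=25.87
[change] ssp126: centroid moved 84.2 km E
[change] ssp585: centroid moved 201.0 km E
```

Reading the results: the AICc grid picked linear+quadratic features at
RM 0.5 with 7 active coefficients; the replicated model separates
presences from background with mean test AUC 0.935 ± 0.007 and TSS
0.818 ± 0.022; 25.87 × 10⁴ km² of the window is highly suitable habitat
under the current climate; and under both warming scenarios the suitable
area's centroid moves east-northeast — the stronger forcing moving it
further (84 km vs 201 km) — matching the direction in which the
generator's true niche was configured to shift:

```r
res$centroid_track
#>           epoch      lat      lon distance_km bearing_deg label
#> current current 29.83186 109.1934     0.00000          NA
#> ssp126   ssp126 29.99069 110.0472    84.17024    77.67562     E
#> ssp585   ssp585 30.21140 111.2341   200.95179    77.36767     E
```

`demo_run/` contains every intermediate artifact: thinned occurrences,
the correlation matrix and screening table, the candidate AICc table,
per-replicate evaluation summary, suitability/class/change rasters
(ESRI ASCII grid) per epoch, the centroid track and a JSON run manifest.

Individual stages are plain functions — `generate_scenario()`,
`compute_bioclim()`, `thin_to_grid()`, `select_variables()`,
`fit_maxent()`, `score_candidates()`, `replicate_fit()`, `classify()`,
`change_map()`, `migration()` — see the vignette for the science behind
each.

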