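---
title: "Methods: Bayesian small-area mapping of deprived urban neighbourhoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian small-area mapping of deprived urban neighbourhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cities in low- and middle-income countries need maps of deprived ("slum")
neighbourhoods to target infrastructure and services, but field mapping is
expensive and slow. deprivmap implements a census-plus-remote-sensing
alternative: train a Bayesian logistic regression on enumeration areas
(EAs) with known deprived/non-deprived labels from a field-mapped urban
core, then predict a posterior probability of deprivation for every urban
EA in the wider metropolitan region. EAs are the smallest census units
(median population 689, about 0.05 km² in dense urban areas), so the map
resolves within-neighbourhood heterogeneity.

## Model

For EA $i$ (in neighbourhood $j$), with label $Y_i \in \{0, 1\}$ and an
18-vector $x_i$ of EA-level predictors:

* **Model 1** (fixed effects): $Y_i \sim \mathrm{Bernoulli}(p_i)$,
  $\operatorname{logit}(p_i) = \alpha + \beta^\top x_i$.
* **Model 2** adds exchangeable neighbourhood random effects:
  $\operatorname{logit}(p_{ij}) = \alpha + \beta^\top x_{ij} + V_j$,
  $V_j \sim N(0, \sigma_V^2)$.

The headline prior is $\alpha, \beta_k \sim N(0, 0.98^2)$, chosen so the
95% prior odds-ratio interval per coefficient is
$\exp(\pm 1.96 \times 0.98) = [0.15, 6.8]$ — weakly informative for a
binary-outcome GLM. Because EA-level category proportions are correlated
(improved water, flush toilets and durable walls travel together),
variance-matched shrinkage alternatives are provided: a Bayesian lasso
(double-exponential prior with scale $0.98/\sqrt{2}$, matching the normal
prior's variance) and a ridge variant ($\beta_k \sim N(0, 1/\lambda)$ with
$\lambda \sim \mathrm{InvGamma}(0.01, 0.01)$, taken literally as a "flat
inverse gamma on the precision"). $\sigma_V$ gets a half-Cauchy prior with
scale 1 — the conventional weakly-informative default; the scale is a
`model_spec()` argument.

### Predictors

Fourteen household-category proportions (per non-reference analysis
category of `default_category_map()`: water source, toilet type, tenure,
wall/roof/floor materials, cooking fuel, rubbish disposal, dwelling type)
plus four continuous terms: mean persons-per-bedroom crowding, population
density (persons/km²), zonal-mean NDVI, and the EA's mean elevation minus
the mean over its 5-km surroundings (a flood-risk proxy; the annulus
*excludes* the EA itself, reading "relative to the surrounding area" as
surroundings proper — `include_self = TRUE` restores the inclusive
reading).

**Standardization.** `build_matrix(standardize = TRUE)` centres and
scales *every* column, proportions included, and records the reversible
transform for reuse at prediction time. Source material for this class of
analysis typically leaves proportions on their natural 0–1 scale; we
deviate deliberately: a common prior SD across coefficients presumes a
common column scale, and EA proportions have SDs of 0.07–0.26, so on the
raw scale their coefficients are weakly identified (posterior SDs of
0.2–0.5 at $n = 2000$) while the standardized scale makes coefficient
recovery assessable. Set `standardize = FALSE` for raw columns.

### Sampler

No MCMC engine ships in the supported environment, so the sampler is
implemented in compiled code: a univariate slice sampler (stepping-out and
shrinkage) swept over $\alpha$, each $\beta_k$, each $V_j$,
$\log \sigma_V$ and, for ridge, $\log \lambda$. Slice sampling is
tuning-free, exact for these log-concave conditionals, and close in spirit
to the automated factor slice samplers used for this model class. Each
chain runs an independent 64-bit Mersenne Twister seeded from
`spec$seed`, so draws are bit-reproducible and independent of R's RNG
state. Convergence is summarized by split R-hat (warning above 1.05) and a
Geyer initial-positive-sequence effective sample size, replacing visual
trace inspection with automatable criteria. Defaults mirror the headline
analysis — 20,000 kept draws per chain after 5,000 burn-in, 4 chains —
but every test and the pipeline run reduced budgets, stated where used.

## Model selection

`holdout_cv()` holds out random EA fractions (the canonical seven: 2.5%,
3.7%, 5.0%, 6.2%, 7.5%, 8.7%, 10%), refits on the remainder, and scores
held-out posterior-mean predictions by MSE. "MSE against their fitted
probability values" is ambiguous in the source description, so both
readings are reported: against observed binary labels (a Brier score; the
default) and against full-data fitted probabilities. One partition per
fraction is the default (as described); `repeats` averages over
partitions since single partitions are noisy at small n. `waic()`
computes $-2(\mathrm{lppd} - p_\mathrm{WAIC})$ from the pointwise
log-likelihood matrix via log-sum-exp; for Model 2 the likelihood
conditions on the sampled $V_j$ (the marginalized variant is not
implemented).

## Prediction, summaries, clusters

`posterior_predict()` averages $\operatorname{logit}^{-1}$ of the linear
predictor over draws, restricted by convention to urban EAs. For Model 2
on neighbourhoods unseen in training the default draws a fresh
$V \sim N(0, \sigma_V)$ per posterior draw (the correct predictive
distribution); `policy = "zero"` pins $V = 0$ for comparison. EAs are
flagged deprived at posterior mean $\ge 0.80$ (inclusive; 0.50 yields a
superset), binned into lower-closed probability quintiles
($[0, .2), \ldots, [.8, 1]$), and summarized with EA and resident counts
and shares. `find_clusters()` returns queen-contiguous components of at
least 3 flagged EAs; queen contiguity (shared edge *or* vertex) is chosen
to match the LISA weights convention, since no adjacency rule is stated in
the source material.

## LISA

`local_morans_i()` computes $I_i = z_i \sum_j w_{ij} z_j / m_2$ with
$m_2 = \sum_k z_k^2 / n$ and row-standardized queen weights; under these
definitions the mean of local values over non-isolates equals global
Moran's I exactly (asserted at 1e-10). Significance uses conditional
permutation (the focal value held fixed, 999 permutations by default), a
two-sided pseudo p-value $(\#\{|I^{perm}| \ge |I^{obs}|\} + 1)/(999 + 1)$,
and $\alpha = 0.05$ typing into high-high / low-low / high-low / low-high
quadrants. Contiguity rule, permutation count, and sidedness are all
unstated upstream; queen / 999 / two-sided are the dominant conventions.

## The synthetic world

The generator exists so the full pipeline is testable offline; it states a
world once and keeps it:

* **Lattice**: square EAs of 0.2236 km edge (0.05 km² — the stated mean
  urban EA size) tiled into a rectangle; neighbourhoods are contiguous
  rectangular blocks, so random-effect and LISA tests see genuine spatial
  grouping. A local transverse-Mercator-style metric CRS stands in for UTM
  30N.
* **Populations**: lognormal with median 689; `sdlog = 0.4889` is solved
  from the printed quartiles (mean of $\log(940/689)$ and $\log(689/486)$
  over the normal quartile 0.6745). The printed IQR is slightly
  asymmetric; the lognormal match is within a few percent at both ends.
* **Rasters**: DEM and red/NIR reflectance fields are sums of 6 random
  plane waves (wavelengths 1.5–8 km) plus white noise, covering the EA
  extent plus a ≥5-km margin so buffer differencing never leaves the
  raster. NDVI is derived from the bands, hence always in $(-1, 1)$.
* **Households**: ~10% of each EA's population at 4.2 persons/household.
  Each EA has a latent deprivation score $u_i$ (neighbourhood effect
  SD 1.4 + EA noise SD 1.0); each variable group blends it with an
  idiosyncratic component ($\rho = 0.45$) and a household samples the
  group's "deprived" category profile with probability
  $\operatorname{logit}^{-1}$ of the blended score, else the
  "non-deprived" profile. The profiles are stipulated, not estimated — no
  joint distribution of real census categories is published. The blending
  keeps cross-column correlations below ~0.4: a generator whose columns
  all proxy one factor makes coefficients unidentifiable, defeating the
  parameter-recovery tests the generator exists to serve.
* **Labels**: drawn from the exact logistic model above, using the
  predictor matrix as fed to the model (standardized scale), so the
  generating $(\alpha, \beta, V)$ are the quantities the fit should
  recover and the generator's log-density equals the model likelihood on
  its own draws (tested).

What a green test does **not** establish: real census categories are
jointly dependent in ways the two-profile mixture cannot produce; real
NDVI/DEM fields have anisotropy, water bodies and sensor artifacts; EA
polygons are irregular, not square; and the real labels come from a field
exercise, not from the model — so green tests certify the machinery, not
real-world accuracy.

## Numerical choices

* Bernoulli log-likelihoods use a branch-stable $\log(1+e^x)$; no
  overflow for $|\eta|$ up to the double range.
* WAIC's lppd uses column-wise log-sum-exp.
* Zonal statistics use the cell-centre-in-polygon rule (deterministic,
  cheap, reproducible bit-for-bit); sub-cell polygons fall back to the
  centroid cell; nodata cells are excluded everywhere.
* Queen adjacency declares polygons neighbours when boundary gap
  ≤ 1e-6 m, computed by exact segment-segment distance with bounding-box
  pruning.
* Quintile bins are lower-closed with the last bin $[0.8, 1]$; the
  deprived threshold is inclusive ($\ge$).
* Ties/degenerate inputs: zero-variance LISA variables and empty MSE
  inputs are errors; $\sigma_V \le 0$ in a prior evaluation is $-\infty$,
  not an exception; EAs with no sampled households are flagged, never
  imputed.

## Formats and environment limits

No geospatial R stack (sf/terra/spdep) or GeoTIFF reader is available in
the supported environment, so polygons travel as GeoJSON (planar
coordinates plus a CRS label) and rasters as ESRI ASCII grids (.asc) —
plain-text, lossless for this purpose. The CLI config is JSON (YAML is
accepted when the yaml package is present).

## Known limitations

* The 18-variable list reconstructs the named variable groups; the exact
  census recode of the original study is not published, so the category
  map is a faithful-by-structure stand-in and fully overridable.
* WAIC for Model 2 conditions on sampled $V_j$.
* The slice sampler is serial per chain; very large worlds (tens of
  thousands of EAs) would want a blocked or gradient-based kernel.
* Printed global Moran's I values for the real predictor surfaces
  (0.63/0.65/0.36) are not reproducible without the real data and are used
  only as qualitative sanity context.
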