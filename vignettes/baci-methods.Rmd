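---
title: "Counterfactual impact evaluation with baciR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual impact evaluation with baciR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baciR)
```

## The problem

Whether a restoration or conservation intervention *worked* cannot be read
off a monitoring time series at the intervention site alone: regional
climate, land-use trends and measurement conditions all change over the
same years. The before-after-control-impact (BACI) design compares the
*change* at intervention (impact) sites against the change at control
sites, and statistical matching chooses those controls to be
environmentally similar to the impact sites — otherwise the comparison
inherits the placement bias that interventions tend to go to marginal,
remote, or otherwise atypical land ("naive" designs that skip this step
tend to overstate effectiveness).

`baciR` implements this workflow end to end on a raster grid: pixel-based
unit definition from intervention polygons, covariate construction and
screening, propensity-score / Mahalanobis / exact matching with balance
diagnostics, yearly vegetation-index summarisation, and the BACI
difference-in-difference contrast with a t-test. A seeded synthetic
landscape generator provides ground-truthed inputs so everything runs and
tests offline.

## Units of analysis

`create_control_candidates()` rasterises intervention polygons into a grid
of impact pixels (1), candidate control pixels (0) and excluded pixels
(NA).

* **Pixel membership** uses the cell-centre rule on a half-open, row-major
  grid (a cell covers $[x, x+res) \times (y-res, y]$): a pixel is impact
  iff its centre falls inside an impact polygon. The centre rule is the
  common raster convention and is checkable against an exhaustive
  point-in-polygon oracle, which the test suite does on grids up to
  50×50.
* **Control region**: pixels whose centre lies within
  `control_from_buffer` metres of an impact polygon and/or inside
  `control_from_polygon`; when both are given their union is used. Buffer
  membership is evaluated as an exact Euclidean point-to-polygon distance
  predicate rather than by rasterising a buffered geometry, which keeps
  the semantics exact at coarse resolutions.
* **Exclusions**: pixels inside impact polygons, inside `control_exclude`
  polygons, or closer than `exclude_impact_buffer` metres to an impact
  polygon are never controls. The spillover buffer restricts *control
  eligibility only*; impact pixels are not eroded unless the optional
  `impact_inner_buffer` is set (off by default), since the two concerns —
  leakage into nearby controls vs. edge effects inside sites — are
  distinct.
* **Subsampling** (`sample_impact`, `sample_control`) happens after all
  exclusions, on the final candidate pool, retaining `round(f * n)` pixels
  (round half to even) drawn uniformly in row-major order from a PRNG
  seeded by `spec$seed`. Sampling the final pool (rather than the
  pre-exclusion pool) means the retained fraction is exactly `f` of the
  usable candidates.
* **Grid origin**: `round_coords = -2` snaps the origin to the nearest
  100 m, rounding half away from zero. This makes grids from different
  runs align.
* **CRS**: when polygons arrive in geographic coordinates the grid CRS
  defaults to the UTM zone of the polygon centroid
  (`utm_crs_from_centroid()`, zone $\lfloor(\text{lon}+180)/6\rfloor+1$);
  an already-projected input keeps its CRS. Latitudes outside [−80, 84]
  are refused (UTM undefined).

Degenerate inputs fail loudly: polygons smaller than a pixel yield zero
impact pixels and an error naming the cause, and each exclusion filter
reports itself if it empties the control pool.

## Matching covariates

`terrain_derivatives()` uses Horn's 3×3 finite-difference kernel (the
default of mainstream terrain tools) with nearest-edge padding; aspect is
the azimuth of steepest descent, clockwise from north. Because aspect is
circular it enters matching as **northness** = cos(aspect) and
**eastness** = sin(aspect); flat cells get slope 0 and northness =
eastness = 0 (aspect undefined). `distance_to_features()` is the exact
Euclidean distance from each cell centre to the nearest road/settlement
geometry, with an ordered road-class hierarchy where a filter like
`"track+"` keeps that class and everything ranked above it.
`encode_landcover()` validates an integer class raster against a
user-supplied scheme; at model time the covariate expands to $K-1$
indicators against the most frequent class as reference.

`collate_matching_layers()` assembles one row per labelled pixel
(id = row-major cell index, coordinates, treatment flag, covariates),
resampling misaligned layers on the fly (nearest neighbour for
categorical, bilinear for continuous) and dropping rows with missing
covariates with a warning — matching assumes complete covariates, and
silent imputation would hide data problems.

`vif()` reports the variance inflation factor $1/(1-R^2_j)$ per covariate
column from an OLS regression of that column on all others (categorical
covariates screened per indicator column; a generalised joint VIF is out
of scope). `test_multicollinearity()` defaults to the conventional
threshold of 5 and, under `auto-drop-worst`, greedily removes the
highest-VIF covariate and recomputes until clean. The greedy drop set is
not guaranteed minimal; for small covariate sets users can inspect the
returned correlation matrix and drop manually.

## Matching

`fit_propensity()` is a maximum-likelihood logistic regression of
treatment on covariates. Nearest-neighbour distances and calipers operate
on the **logit** of the propensity score, with the caliper expressed in
standard deviations of the logit scores — the de-facto convention in the
matching literature, which spreads scores away from the [0, 1]
boundaries. Perfect separation and non-convergence are errors, not silent
successes, because a separated propensity model means the groups share no
covariate overlap and matching cannot be meaningful.

`match_nearest()` is greedy sequential nearest-neighbour matching: impact
units are processed in order (default: hardest-to-match first, i.e.
descending distance of the unit's score from the control mean; "data" and
seeded "random" orders are options, and order only matters without
replacement); each unit takes its full `ratio` of nearest eligible
controls before the next is considered; without replacement assigned
controls leave the pool; distance ties break on the lowest control id so
results are deterministic. The test suite holds this implementation equal
to an independently written brute-force oracle over hundreds of random
instances, across both replacement settings, ratios 1/2/10 and calipers.

`mahalanobis_distances()` uses the pooled covariate covariance with a
small ridge (1e−10 · trace/p) when the condition number exceeds 1e12.
`match_exact()` matches each impact unit to all controls sharing its
exact combination of the chosen covariates, with 1/k weights.

`balance_evaluation()` reports standardised mean differences before and
after matching with a **fixed denominator** (the pooled pre-matching SD),
so before/after values are directly comparable on a Love plot
(`plot()` method); matched controls are weighted by their reuse counts.
It also reports variance ratios, the control selection-rate table (worth
checking whenever `replace = TRUE`), and 30-bin overlap histograms of the
distance score.

## Time-series observables

The pipeline consumes either scene stacks (per-acquisition bands +
boolean quality mask + scene cloud percentage) or yearly value stacks.
`yearly_composite()` takes the per-pixel **median** of the NDVI over
valid (unmasked) observations within the chosen year/months, after
dropping scenes above the `max_cloud` scene-level ceiling; an even count
yields the mean of the two middle values, and a pixel with no valid
observation is missing. Compositing is per-pixel on the *index*, not on
reflectance bands. Bitmask decoding of real QA bands is a provider
concern: inside the package a mask is simply boolean. Remote catalogue
access is deliberately out of scope; scenes come from a local manifest
(CSV of date, cloud percentage and band paths), which keeps the pipeline
reproducible and testable offline.

`calc_ts_metrics()` summarises a yearly stack per pixel into the
arithmetic mean, an OLS **trend** (slope of value on calendar year,
centred regressor, missing years omitted, at least `min_years = 3` years
required — two points would make every pair of years a perfect line) and
optionally the fitted value at the earliest/latest year.

## The BACI contrast

For impact unit $i$ with matched controls $M(i)$ and weights $w_c$:

$$\text{contrast}_i = (\mu_{CA} - \mu_{CB}) - (\mu_{IA} - \mu_{IB}),$$

where $\mu_{IB}, \mu_{IA}$ are the unit's own before/after values and
$\mu_{CB}, \mu_{CA}$ are weighted means over $M(i)$. Under this
control-minus-impact convention a gain at impact sites appears as a
negative contrast (a `flip_sign` switch reports the negated value).

Aggregation is a deliberate design choice: controls are first aggregated
to a weighted mean *per impact unit*, then the overall contrast is the
unweighted mean of the per-impact contrasts, and significance is a
two-sided one-sample t-test of those contrasts against zero
(df = matched impact units − 1). This keeps one contrast per impact
pixel — which is also what the spatial contrast layer
(`spatialise_contrast()`) displays — rather than pooling all units into a
two-sample test. Controls matched to several impact units contribute to
each one's control mean independently. The t-test assumes independent,
homoskedastic, normal per-impact contrasts and none of these is verified
by the package, so p-values deserve caution; a Wilcoxon signed-rank
p-value is reported alongside as a distribution-free companion. Units
with missing observable values are excluded and counted; with fewer than
two complete impact units the contrast is still reported but the p-value
is NA.

## Synthetic landscapes and what the tests show

`make_landscape()` builds a smooth elevation field (sum of seeded 2-d
cosine basis functions), a categorical land cover (thresholded second
smooth field), random road polylines, and intervention polygons placed by
sampling seed cells with probability
$\text{logit}^{-1}(\beta_{elev} z_{elev} + \beta_{road} z_{road})$ —
non-zero $\beta$ reproduces confounded placement. `make_outcome_series()`
generates

$$v(p,t) = \text{base} + \text{trend}\,(t - t_0) + \text{field}(p)
  + \gamma\, z_{elev}(p)\,(t - t_0) + \varepsilon
  + \delta\,\mathbb{1}[p\ \text{impact},\ t\ \text{after}]$$

with i.i.d. noise $\varepsilon \sim N(0, \sigma^2)$. Two structural
choices matter. The static spatial field is time-invariant, so the
difference-in-difference cancels it exactly — this is what makes the
per-impact contrasts approximately independent and the t-test calibrated
in the reference conditions. Confounding that matching must *correct*
enters through the elevation-dependent trend $\gamma$: a level-only
confounder would cancel in any before/after difference and could never
distinguish a matched from a naive estimator.

Reference study conditions used by the acceptance checks and
`scripts/acceptance.R`: 50×50 cells at 60 m, four ≈5-cell sites
(≈100–140 impact pixels), ten-year before/after periods around a 2012
intervention, base NDVI 0.3, $\delta = 0.1$, $\sigma = 0.02$, spatial
field SD 0.05, ratio-10 propensity matching with replacement; confounded
scenarios use $\beta_{elev} = 1.5$ and $\gamma = 0.005$ yr⁻¹ per SD of
elevation. These sizes keep a 50-replicate simulation under a minute
while leaving ≈1000 candidate controls per landscape.

What passing these simulations does **not** show: real landscapes have
spatially autocorrelated *disturbances* (not just static fields), so
real per-impact contrasts are positively correlated and the t-test is
anti-conservative; sensor artefacts, georegistration error and gradual
treatment onset are also not emulated. The package reports but does not
correct for any of this.

## Numerical conventions

* Grid cells are half-open, row-major from the top-left; unit ids are
  row-major cell indices.
* Raster interchange is the plain-text ESRI ASCII grid with full `%.17g`
  precision and an `EPSG:<code>` `.prj` sidecar, so round trips are
  value-exact; vectors travel as GeoJSON with a CRS member.
* Origin rounding is half-away-from-zero; subsample counts are
  round-half-even; matching ties break on lowest control id; all
  randomness flows from explicit seeds, and re-running any stage with the
  same inputs and seed reproduces outputs byte-for-byte.
* The UTM forward projection uses the standard WGS84 transverse-Mercator
  series (k₀ = 0.9996), accurate to well under a metre — negligible
  against ≥60 m pixels.

## Known limitations

Polygon- or point-unit analysis is supported only at the covariate-table
level (no zonal statistics beyond means); optimal and coarsened-exact
matching, probit propensity models, spatial-autocorrelation diagnostics
and unobserved-confounder sensitivity analysis are out of scope; land
cover at other than single-raster inputs, and any remote data access,
are left to the user's preprocessing.
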