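---
title: "Quantifying LAI spatial heterogeneity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LAI spatial heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laihet)
```

Spatial heterogeneity of leaf area index (LAI) has two aspects:
*variability* — how widely values scatter — and *structure* — over which
distances they stay correlated. This vignette describes the models behind
each stage of `laihet`, the parameters that matter, the numerical
conventions, and the choices made where the underlying methodology left
the design open. It states no empirical result beyond what the package's
tests and acceptance script themselves compute.

## 1. LAI retrieval from two-band reflectance

The retrieval chain assumes a monotone NDVI–LAI relation mediated by
fractional vegetation cover (FVC):

$$\mathrm{NDVI} = \frac{NIR - Red}{NIR + Red}, \qquad
  \mathrm{FVC} = \frac{\mathrm{NDVI} - \mathrm{NDVI}_s}
                      {\mathrm{NDVI}_v - \mathrm{NDVI}_s}, \qquad
  \mathrm{LAI} = \frac{-\ln(1-\mathrm{FVC})}{k}.$$

* **Endmembers** $\mathrm{NDVI}_v$ (full vegetation) and $\mathrm{NDVI}_s$
  (bare soil) are estimated per date from the two temporally stable
  reference classes, broadleaf forest and bare ground. "Histogram
  analysis" is operationalised as the modal 0.01-wide NDVI bin of each
  class, reported as the mean NDVI inside that bin — exact when a
  reference class is uniform, robust to outliers otherwise. Ties break
  toward the higher bin for the vegetated endmember and the lower bin for
  soil, so the estimate is deterministic. At least 100 valid reference
  pixels per class are required, and $\mathrm{NDVI}_v \le \mathrm{NDVI}_s$
  is rejected as inconsistent.
* **Extinction coefficient** `k` (unitless, default 0.54): Beer–Lambert
  attenuation for a mid-latitude solar geometry. The solar-zenith
  dependence is deliberately not modelled; `k` is a scalar of
  `retrieval_params()`.
* **Cap** (default LAI 7): the FVC→LAI inversion diverges as NDVI
  approaches $\mathrm{NDVI}_v$, where the NDVI–LAI relation saturates
  physically (reported saturation points lie between LAI 2 and 6). FVC at
  or above the value mapping to the cap is truncated, so retrieved LAI is
  always in $[0, \mathrm{cap}]$. Pixels with NDVI below the soil
  endmember (negative FVC, caused by soil heterogeneity) are set to LAI 0
  rather than propagated as negative values.

The synthetic sensor model (`forward_ndvi()`) is the exact algebraic
inverse of this chain with Red held at a 0.05 baseline, so the noiseless
round trip is an identity to $10^{-6}$ — the package's sharpest
correctness check on the retrieval.

## 2. From land use to fields

* **Majority resampling** coarsens a categorical raster by assigning each
  block its most frequent class, ignoring nodata; ties break to the lowest
  class code for determinism.
* **Mixed-pixel exclusion**: a pixel is kept only if *all* its neighbours
  exist and share its class. The full 8-neighbourhood (Moore) is the
  default — the strictest reading, which guarantees no diagonal mixing —
  with 4-connectivity available. Raster-edge pixels are always removed.
  The result is continuous uniform-class areas separated by nodata strips.
* **Segmentation** labels 4-connected components of kept same-class
  pixels as individual fields (ids in row-major order of first pixel). The
  removed border strips are one pixel wide on each side, so adjacent
  fields of the *same* land use remain connected and cannot be
  distinguished — a structural caveat of the method whose consequences are
  quantified in section 6.
* **Size filter**: fields with area *less than or equal to* the threshold
  are removed; `"median"` computes the median area of the input map, which
  removes about half the entities but typically a small share of the
  area (the filter reports both percentages, summing to 100 exactly).
* **Plausibility filter**: per crop, date windows with a maximum plausible
  LAI (default: at most 0.3 before the crop's emergence day). LAI above
  the window maximum contradicts the assigned land use (weeds, catch
  crops, misclassification) and the pixel is excluded from *per-crop*
  analyses only; overall-arable-area statistics keep every pixel, since a
  contradiction with the crop label does not make the vegetation less
  real.

## 3. Variability statistics

All SDs are population SDs (divide by $n$): the rasters are complete
populations of the analysed area, not samples.

The overall statistics of a multi-crop area are pooled from crop-wise
statistics with abundance weights $w_i$ taken from the *original*
classification (mixed-pixel removal changes crop shares; reweighting
undoes that bias):

$$\mu = \sum_i w_i \mu_i, \qquad
  \sigma^2 = \sum_i w_i\left(\sigma_i^2 + (\mu_i - \mu)^2\right).$$

The between-crop term makes the overall SD exceed every single-crop SD
whenever crop means diverge — without it (within-group pooling only,
available as `mode = "within"`) that ordering would be impossible, which
is why the total-variance form is the default.

Relative frequency distributions (RFDs) use half-open classes
$[cw, (c+1)w)$ anchored at zero, default width $w = 0.1$ LAI (accordance
values stabilise below roughly this width); a value exactly on an edge
belongs to the upper class. The accordance of two aligned RFDs,
$a = \sum_c \min(D_{a,c}, D_{b,c})$, is the fraction of values falling in
the same class; it is symmetric, bounded in $[0,1]$ and equals one minus
the total-variation distance, which the tests exploit as an independent
oracle. Refining classes can only decrease it. The normal comparator
builds the RFD a normal distribution with the empirical mean and SD would
produce on the same grid, folding all mass below the first class edge
(negative LAI) into class zero and renormalising.

The field-mean RFD weights each field by its pixel count, so pixel-level
and field-level RFDs are measures over the same area and their accordance
is meaningful; an unweighted per-field variant can be built directly from
the aggregates table.

## 4. Spatial structure

The empirical semivariogram uses the classical Matheron estimator
$\gamma(h) = \frac{1}{2N(h)}\sum (z_i - z_j)^2$ on half-open distance
classes (default 200 m wide to a 25 km maximum lag). For full rasters the
pair count is quadratic, so a uniform random subsample (default 0.5% of
valid pixels) is drawn first; `subsample_stability()` quantifies the
induced per-lag fluctuation. Before analysing the overall arable area,
`rebalance_abundance()` randomly removes entities of over-represented
classes until the crop shares match the original classification.

The fitted model is a nested sum of exponentials,
$\gamma(h) = c_0 + \sum_i c_i (1 - e^{-h/a_i})$ with one or two
components, estimated by weighted Levenberg–Marquardt under a fallback
ladder: (1) nested model with default starts (ranges at 1/10 and 1/2 of
the maximum lag, sills split from the empirical plateau); (2) a 3×3 grid
of start-range pairs; (3) the alternative pair weighting; (4) nugget fixed
at zero; (5) a simple exponential; (6) truncation at 6 km and repetition.
A fit is accepted when its relative RMSE over the *transition zone* (lags
between 50% and 150% of the shortest effective range) is below 15% — the
transition to the plateau is where the range is decided, so that is where
fit quality is judged. If every step fails the result is an explicit
fit-failure object, mirroring the fact that irregularly shaped empirical
variograms often cannot be fitted at all.

Numerical choices in the fitter:

* **Weighting.** The default weight is $N(h)/h^2$ — the default of the
  geostatistics tooling this procedure follows — which concentrates
  weight on short lags where the nested decomposition is identified;
  plain $N(h)$ is the ladder's alternative. With $N(h)$ first, the
  plateau (where pair counts are largest) dominates the objective and
  near-degenerate decompositions slip through the transition-zone test.
* **Optimiser.** `minpack.lm::nls.lm` with box constraints: sills and
  nugget $\ge 0$, ranges between 1 m and three times the maximum lag. The
  upper bound is an identifiability guard: a range far beyond the observed
  lags is indistinguishable from a linear drift and its fitted value
  meaningless. Within a ladder step all tested starts compete and the
  converged, transition-passing fit with the lowest weighted SSE wins.
* **Degeneracy.** A flat (pure-nugget) variogram converges with
  zero-sill components or with a range pinned at the 1 m bound; both are
  flagged `degenerate` and yield no ranges. Components contributing less
  than $10^{-4}$ of the total variance are treated as absent.

**Ranges.** Each exponential component's *effective* (practical) range is
reported as $3a_i$, the lag where it reaches ~95% of its partial sill (the
exact 95% point is $a\ln 20 \approx 3a$); the raw parameters $a_i$ are
emitted alongside, since conventions differ and any external comparison
must state which value it uses. The short range of an arable landscape
reflects field dimensions; the long range, where a second component is
identifiable, reflects kilometre-scale soil and weather gradients.

## 5. The synthetic scene generator

The generator produces landscapes with exactly the statistical structure
the analysis assumes, so that every downstream claim can be tested against
known ground truth.

* **Mosaic**: recursive binary space partitioning of the arable region
  with split positions jittered uniformly in the central 40–60% of the
  longer side; a rectangle is finalised when its area falls below a
  log-normal draw. Fields are rectangular like real parcels and field
  areas follow the configured log-normal law (default mean 2.06 ha,
  $\sigma_{\log} = 0.8$). Because final areas undershoot the stop
  threshold, the threshold mean carries a fixed, once-measured correction
  (0.515) so the realised mean area equals the configured mean; the
  realised log-area spread comes out somewhat narrower (~0.65) than the
  configured $\sigma$, a known property of the splitting construction.
  The log-normal family itself is an assumption — only summary statistics
  of real field-size distributions were available to anchor it.
* **Crops**: shares 41% winter wheat, 28% sugar beet, 10% maize of the
  arable area, plus a generic "other crops" class for the remainder so no
  field is artificially bare. Each field draws one crop independently.
* **Seasonal curves**: per crop, zero before emergence, a logistic rise
  normalised to hit the crop maximum exactly on the day of maximum, and a
  linear senescent decline to zero. Default timing reproduces the
  characteristic ordering — wheat greens up early in the season, beet from
  mid-April, maize from mid-May — and the maxima (7.3 / 6.6 / 5.3) follow
  crop-growth simulation values for such landscapes. Four parameters per
  crop (all in day of year) are the entire phenology model; no
  photosynthesis, nitrogen or water dynamics are simulated.
* **Variance components**: an iid per-field offset
  $\mathcal N(0, \sigma_{field})$ (default 1.0 LAI) for management and
  cultivar differences, iid pixel noise $\mathcal N(0, \sigma_{pix})$
  (default 0.2) for intra-field texture and sensor noise, and an optional
  zero-mean Gaussian random field with exponential covariance
  (sill, range parameter in metres) for kilometre-scale soil and weather
  gradients — the same covariance family the variogram fit assumes. The
  sum is clamped at zero. Defaults put the landscape in the
  inter-field-dominated regime ($\sigma_{field} \gg \sigma_{pix}$)
  characteristic of intensively managed arable land.
* **Random fields** are simulated by circulant embedding (FFT on the
  doubled grid); occasional negative embedding eigenvalues are clamped to
  zero, the standard approximation, and the realised marginal variance and
  covariance decay are verified in the test suite.
* **Sensor model**: the exact inverse of the retrieval chain plus optional
  Gaussian reflectance noise; forest and bare-ground reference patches
  (horizontal bands, default 10% and 5% of the domain) emit the true
  endmember NDVI so per-date endmember estimation is exercised.
* **Determinism**: one scene seed drives everything; per-stage seeds are
  derived arithmetically from it (and the analysis day), so identical
  configurations are bit-identical and stages can be re-run independently.

### What the generator does and does not emulate

It reproduces: a field mosaic at the documented mean size, the documented
crop shares, crop-specific phenology ordering, inter-field-dominated
variance, multimodal overall RFDs from crop superposition, and short- plus
long-range variogram structure. It does *not* reproduce: spatially
correlated field effects (neighbouring fields share soil and weather, but
field offsets here are iid), irregular parcel shapes, atmospheric and
geometric sensor artefacts, temporal correlation between dates, or crop
rotation. Consequently, passing tests demonstrate the *method's*
correctness and the stated regimes, not agreement with any particular real
landscape.

The iid field effects have one visible consequence: segmentation merges
adjacent same-crop fields (section 2), and merging iid means removes
variance that in a real landscape would largely survive (neighbouring
means are correlated there). The pipeline's pixel-vs-field-mean accordance
on segmented entities is therefore systematically lower than the same
quantity computed on the generator's true mosaic; the regime benchmark
(`benchmark_field_mean_accordance()`) uses the true mosaic, which is the
quantity the inter-field-dominance claim is about.

## 6. Benchmark scenarios and test problem sizes

Three exported scenarios condense the regimes into scalar summaries (each
a median over five seeds in the acceptance script):

* `benchmark_short_range()` — single-crop mosaic, 1500×1500 px at 5 m,
  field effect SD 1.0, pixel noise 0.2; 0.5% subsample, 50 m lags to 3 km.
  A ~2 ha mosaic decorrelates within a few hundred metres, so the short
  effective range lands below the field-scale bound of 325 m.
* `benchmark_field_mean_accordance()` — multi-crop 1000×1000 px scene at
  5 m on a mid-season day, inter-field SD 1.0, pixel SD 0.2; accordance of
  pixel vs area-weighted field-mean RFDs at class width 0.1. With ~1900
  fields the field-mean histogram is atomic and pixel noise smears each
  atom over ±2 classes, which costs a total-variation distance of about
  0.1; the computed median accordance sits just below 0.9 — a
  finite-sample property of this scene size, documented rather than tuned
  away.
* `benchmark_long_range()` — 20×20 km scene at 20 m with field effect SD
  0.7 plus a background field of sill 0.7 and range parameter 1000 m;
  nested fit on 200 m lags to 10 km. The long effective range recovers
  ~3×1000 m, far above the 1560 m lower bound for weather/soil-driven
  structure, though with substantial seed-to-seed spread: a 20 km domain
  holds only ~20 correlation lengths of a 1 km field, so single-realisation
  variograms fluctuate at long lags.

Parameter-recovery testing uses scenes built from two superimposed random
fields with effective ranges 120 m and 900 m on a 1200×1200 px, 5 m grid
— large enough that single-realisation ergodic fluctuation permits ±30%
recovery of both ranges in most seeds; on half-size domains the long
component's realised variogram deviates too much from the ensemble shape
for any fitter to recover it reliably. Unit tests elsewhere run on scenes
of 150–600 px and oracle checks on rasters up to 50×50 and point sets up
to 500, sizes at which brute-force references are exact and fast.

## 7. Known limitations

* Endmember estimation assumes the reference classes are present and
  spectrally stable; scenes without both classes need externally supplied
  endmembers.
* The LAI cap makes the retrieval blind to differences above LAI ≈ 7, and
  saturation inflates retrieval noise already below the cap.
* Nested-exponential decomposition is weakly identified when the two
  scales are closer than roughly a factor of five, when the domain holds
  few long-range correlation lengths, or when the empirical variogram is
  irregular; the explicit fit-failure and degeneracy flags exist because
  these cases are common in practice.
* The multi-crop vs single-crop short-range ordering (different crops on
  adjacent fields decorrelate the landscape at shorter distances) emerges
  here only through the interplay of field-scale and background
  components and is a median-level effect across seeds, because iid field
  effects give multi- and single-crop scenes proportionally shaped
  variograms.
* Raster file exchange uses plain 32-bit TIFF with a JSON sidecar for
  scaling and resolution; fully georeferenced GeoTIFF (projections,
  transforms) is out of scope.
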