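# laihet — spatial heterogeneity of leaf area index on arable land

Leaf area index (LAI, one-sided green leaf area per unit ground area)
controls transpiration, light interception and photosynthesis, so fluxes of
water, carbon and energy respond nonlinearly to how LAI is distributed in
space. On arable land that distribution is shaped by field geometry, crop
choice and management as much as by soil and weather. `laihet` is an R
package for quantifying that heterogeneity — its *variability* (standard
deviations and frequency distributions) and its *structure* (semivariogram
ranges) — from high-resolution optical remote sensing, for researchers in
agro-ecosystem modelling and environmental remote sensing.

The package implements the full analysis chain:

1. **LAI retrieval.** From a two-band reflectance pair,
   `NDVI = (NIR − Red)/(NIR + Red)`; per-date endmembers `NDVI_v` (broadleaf
   forest) and `NDVI_s` (bare ground) are estimated from histogram modes of
   the temporally stable reference classes; fractional vegetation cover
   `FVC = (NDVI − NDVI_s)/(NDVI_v − NDVI_s)`; and a Beer–Lambert inversion
   `LAI = −ln(1 − FVC)/k` with `k = 0.54`. Negative FVC maps to LAI 0 and
   the inversion is capped at LAI 7 where the NDVI relation saturates.
2. **Fields.** Majority resampling of the land-use map, exclusion of
   potentially mixed pixels (a pixel is kept only if its whole
   8-neighbourhood shares its class), 4-connected segmentation of the
   remainder into fields, an inclusive median field-size filter, and a
   crop-calendar plausibility filter (e.g. maize with substantial LAI in
   February contradicts its land use).
3. **Variability.** Per-field means and population SDs; overall means and
   SDs pooled from crop-wise statistics with abundance weights via the law
   of total variance; relative frequency distributions (RFDs) on 0.1-LAI
   classes anchored at zero; the accordance `a = Σ_c min(D_a,c, D_b,c)`
   (histogram overlap, equal to 1 minus total-variation distance); and a
   normal-distribution comparator RFD.
4. **Structure.** Random subsampling of pixels, abundance rebalancing,
   the Matheron semivariogram estimator on distance classes, and a nested
   two-exponential model `γ(h) = c₀ + Σᵢ cᵢ(1 − e^(−h/aᵢ))` fitted by a
   fallback ladder (start-value grids, alternative weightings, fixed
   nugget, simple model, 6 km cut-off). Effective ranges are `3aᵢ`;
   the short range reflects field dimensions, the long range soil and
   weather gradients.
5. **Synthetic scenes.** A generator produces agro-landscapes with the
   statistical structure the analysis assumes — a rectangular field mosaic
   with log-normal areas (mean 2.06 ha), crop shares 41/28/10% (winter
   wheat, sugar beet, maize), crop-specific seasonal LAI curves, iid
   per-field offsets, pixel noise, an optional kilometre-scale Gaussian
   background field, and an exact forward NDVI sensor model with reference
   patches — so every stage is testable end to end without external data.

## Worked example

```r
library(laihet)

cfg <- scene_config(rows = 400, cols = 400, res = 5, seed = 42)
truth <- generate_mosaic(cfg)
truth
#> <scene_truth> 400 x 400 px @ 5 m, 151 fields (mean 2.25 ha)

lai_true <- simulate_lai(truth, day = 170)
refl <- forward_ndvi(lai_true, cfg, landuse = truth$landuse)
ret <- retrieve_lai(refl$nir, refl$red, truth$landuse)
ret$endmembers
#> <endmembers> ndvi_v = 0.9000 (n = 16000), ndvi_s = 0.1500 (n = 8000)

rep <- run_pipeline(run_config(scene = cfg, days = c(95, 170),
                               variograms = TRUE, subsample = 0.02,
                               lag_width = 50, max_lag = 1500, seed = 42))
rep$stats
#> # A tibble: 8 × 6
#>     day crop            code   mean     sd      n
#>   <dbl> <chr>          <int>  <dbl>  <dbl>  <int>
#> 1    95 winter_wheat       1 4.23   0.989   49221
#> 2    95 sugar_beet         2 0.0364 0.0771  20420
#> 3    95 maize              3 0.0416 0.0788  13150
#> 4    95 overall_arable    NA 1.89   2.03   123396
#> 5   170 winter_wheat       1 4.14   1.01    49221
#> 6   170 sugar_beet         2 6.18   0.914   32547
#> 7   170 maize              3 3.05   0.808   20094
#> 8   170 overall_arable    NA 4.43   1.47   123396
```

On the early date (day 95) only winter wheat has greened up, so the
overall arable area mixes a high-LAI crop with near-zero fields and its SD
(2.03) far exceeds every single-crop SD — between-crop contrast, captured
by the pooled (total) variance, dominates. At mid season (day 170) all
crops carry leaf area; the overall SD (1.47) still exceeds the single-crop
SDs (0.8–1.0). The sugar-beet pixel count is smaller on day 95 because the
plausibility filter excludes beet pixels whose LAI contradicts a date
before emergence. The fitted variogram summary,

```r
dplyr::select(rep$variograms, day, converged, ladder_step, short_range, long_range)
#> # A tibble: 2 × 5
#>     day converged ladder_step short_range long_range
#>   <dbl> <lgl>           <int>       <dbl>      <dbl>
#> 1    95 TRUE                1        307.       521.
#> 2   170 TRUE                1        255.       413.
```

shows short effective ranges of ~250–310 m, the decorrelation scale of a
~2 ha field mosaic (no kilometre-scale background was simulated here, so
no genuinely long range emerges).

`autoplot()` works on RFDs, empirical variograms and fitted models;
`tidy()`/`glance()` summarise a `variogram_model` in broom style.

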