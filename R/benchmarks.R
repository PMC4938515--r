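#' Reference scenarios for the spatial-heterogeneity regimes
#'
#' Three self-contained simulation scenarios reproduce, at desk scale, the
#' regimes a real arable landscape exhibits: field-scale decorrelation,
#' inter-field-dominated variability, and a kilometre-scale background
#' structure. Each takes only a seed and returns the scalar summary the
#' scenario is about, so repeated runs over seeds give a distribution of
#' the quantity.
#'
#' `benchmark_short_range()`: a single-crop 1500 x 1500 pixel mosaic at 5 m
#' (log-normal field areas, mean 2.06 ha, sigma 0.8), per-field LAI offsets
#' of SD 1.0 and pixel noise of SD 0.2, no background field; 0.5% of the
#' pixels are subsampled, the empirical semivariogram (50 m lags to 3 km)
#' fitted by the ladder, and the short effective range (3x the exponential
#' range parameter) returned. Fields of ~2 ha decorrelate within a few
#' hundred metres.
#'
#' `benchmark_field_mean_accordance()`: a 1000 x 1000 pixel, 5 m,
#' multi-crop mosaic (shares 41/28/10% plus other crops) on a mid-season
#' date with inter-field SD 1.0 and pixel noise SD 0.2; returns the
#' accordance (class width 0.1) between the pixel-level LAI distribution
#' and the area-weighted field-mean distribution of the true mosaic. When
#' inter-field variance dominates, field means carry nearly the whole
#' distribution.
#'
#' `benchmark_long_range()`: a 1000 x 1000 pixel scene at 20 m (20 x 20 km)
#' with per-field offsets of SD 0.7 plus a zero-mean background random
#' field (exponential covariance, range parameter 1000 m, sill 0.7);
#' returns the long effective range of the nested two-exponential fit
#' (200 m lags to 10 km).
#'
#' @param seed integer seed driving the whole scenario.
#' @param day analysis day of year (mid-season default).
#' @return a scalar: metres for the range scenarios, a unitless accordance
#'   for the field-mean scenario (`NA` if the fit fails).
#' @name benchmarks
NULL

#' @rdname benchmarks
#' @export
benchmark_short_range <- function(seed, day = 125) {
  crops1 <- tibble(code = 1L, crop = "winter_wheat", proportion = 1,
                   emergence = 60, peak = 125, max_lai = 7.3, sen_end = 227)
  cfg <- scene_config(rows = 1500, cols = 1500, res = 5, crops = crops1,
                      prop_forest = 0, prop_bare = 0,
                      sd_field = 1, sd_pixel = 0.2, lr_sill = 0, seed = seed)
  lai <- simulate_lai(generate_mosaic(cfg), day)
  pts <- subsample_points(lai, 0.005, seed = seed, res = 5)
  ev <- empirical_variogram(pts, 50, 3000)
  effective_ranges(fit_variogram_ladder(ev))$short
}

#' @rdname benchmarks
#' @export
benchmark_field_mean_accordance <- function(seed, day = 170) {
  cfg <- scene_config(rows = 1000, cols = 1000, res = 5,
                      prop_forest = 0, prop_bare = 0,
                      sd_field = 1, sd_pixel = 0.2, lr_sill = 0, seed = seed)
  tr <- generate_mosaic(cfg)
  lai <- simulate_lai(tr, day)
  fa <- field_aggregates(lai, as_field_map(tr))
  ok <- !fa$missing
  pix <- build_rfd(lai[tr$field_labels > 0], 0.1)
  fmr <- build_rfd(rep(fa$mean[ok], fa$n_valid[ok]), 0.1)
  accordance(pix, fmr)
}

#' @rdname benchmarks
#' @export
benchmark_long_range <- function(seed, day = 170) {
  cfg <- scene_config(rows = 1000, cols = 1000, res = 20,
                      prop_forest = 0, prop_bare = 0,
                      sd_field = 0.7, sd_pixel = 0.2,
                      lr_sill = 0.7, lr_range = 1000, seed = seed)
  lai <- simulate_lai(generate_mosaic(cfg), day)
  pts <- subsample_points(lai, 0.005, seed = seed, res = 20)
  ev <- empirical_variogram(pts, 200, 10000)
  effective_ranges(fit_variogram_ladder(ev))$long
}
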