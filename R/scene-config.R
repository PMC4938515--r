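#' Default crop table for the synthetic landscape
#'
#' One row per crop class: land-use code, share of the arable area, and the
#' four parameters of the seasonal LAI curve (all days of year): emergence,
#' day of maximum, maximum LAI, end of senescence. The defaults emulate a
#' Central European loess-plain arable landscape: winter wheat (41% of the
#' arable area) greens up early in the season, sugar beet (28%) from
#' mid-April, maize (10%) from mid-May; the remaining arable share is an
#' "other crops" class with a generic mid-season curve (catch crops, weeds
#' and minor crops keep real fields from being bare). Curve maxima follow
#' crop-growth simulations for such landscapes (wheat 7.3, beet 6.6,
#' maize 5.3).
#'
#' @return a tibble with columns `code`, `crop`, `proportion`, `emergence`,
#'   `peak`, `max_lai`, `sen_end`.
#' @export
default_crops <- function() {
  tibble(
    code       = c(1L, 2L, 3L, 4L),
    crop       = c("winter_wheat", "sugar_beet", "maize", "other"),
    proportion = c(0.41, 0.28, 0.10, 0.21),
    emergence  = c(60, 105, 135, 90),
    peak       = c(125, 185, 200, 180),
    max_lai    = c(7.3, 6.6, 5.3, 4.0),
    sen_end    = c(227, 321, 269, 300)
  )
}

#' Land-use codes of the temporally stable reference classes
#'
#' Broadleaf forest and bare ground are carried in every synthetic scene as
#' reference patches for per-date endmember estimation: forest pixels sit at
#' the fully vegetated NDVI, bare-ground pixels at the bare-soil NDVI.
#' @name reference-codes
#' @export
FOREST_CODE <- 20L

#' @rdname reference-codes
#' @export
BARE_CODE <- 21L

#' Configure a synthetic agro-landscape scene
#'
#' Collects every parameter of the synthetic-scene generator: domain and
#' resolution, the log-normal field-size distribution, crop shares and
#' seasonal LAI curves, the three variance components (inter-field,
#' intra-field, long-range), the forward NDVI sensor model, and the areal
#' fractions of the forest and bare-ground reference patches.
#'
#' The variance components mirror how LAI varies on real arable land: a
#' field-level offset (management, cultivar, sowing date) shared by all
#' pixels of a field, pixel-level noise within fields, and an optional
#' kilometre-scale background field (soil and weather gradients) with
#' exponential covariance.
#'
#' @param rows,cols domain size in pixels.
#' @param res pixel size, m.
#' @param field_mean_area mean field area, m^2 (default 2.06 ha).
#' @param field_sigma_log standard deviation of log field area.
#' @param crops crop table as in [default_crops()]; proportions must sum to
#'   at most 1 (any remainder becomes bare fallow, code 9, LAI 0).
#' @param prop_forest,prop_bare domain fractions of the reference patches.
#' @param sd_field inter-field (field-effect) SD, LAI units.
#' @param sd_pixel intra-field pixel-noise SD, LAI units.
#' @param lr_sill,lr_range sill (LAI^2) and range parameter (m) of the
#'   long-range exponential-covariance background field; `lr_sill = 0`
#'   disables it.
#' @param ndvi_v,ndvi_s true endmember NDVI of full vegetation / bare soil.
#' @param k light extinction coefficient of the Beer-Lambert FVC-LAI link.
#' @param refl_noise_sd Gaussian noise SD added to each reflectance band.
#' @param forest_lai constant LAI assigned to forest pixels.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `scene_config` object (validated list).
#' @export
scene_config <- function(rows = 600, cols = 600, res = 5,
                         field_mean_area = 20600, field_sigma_log = 0.8,
                         crops = default_crops(),
                         prop_forest = 0.10, prop_bare = 0.05,
                         sd_field = 1.0, sd_pixel = 0.2,
                         lr_sill = 0, lr_range = 1000,
                         ndvi_v = 0.90, ndvi_s = 0.15, k = 0.54,
                         refl_noise_sd = 0,
                         forest_lai = 5, seed = 1L) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols), res = res,
              field_mean_area = field_mean_area,
              field_sigma_log = field_sigma_log,
              crops = as_tibble(crops),
              prop_forest = prop_forest, prop_bare = prop_bare,
              sd_field = sd_field, sd_pixel = sd_pixel,
              lr_sill = lr_sill, lr_range = lr_range,
              ndvi_v = ndvi_v, ndvi_s = ndvi_s, k = k,
              refl_noise_sd = refl_noise_sd,
              forest_lai = forest_lai, seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$rows >= 1, cfg$cols >= 1)
  if (cfg$res <= 0) abort("resolution must be > 0", class = "laihet_config_error")
  sds <- c(cfg$sd_field, cfg$sd_pixel, cfg$lr_sill, cfg$refl_noise_sd)
  if (any(sds < 0)) abort("variance components must be >= 0", class = "laihet_config_error")
  p <- cfg$crops$proportion
  if (any(p < 0) || any(p > 1) || sum(p) > 1 + 1e-9) {
    abort("crop proportions must lie in [0,1] and sum to at most 1",
          class = "laihet_config_error")
  }
  if (cfg$prop_forest < 0 || cfg$prop_bare < 0 ||
      cfg$prop_forest + cfg$prop_bare >= 1) {
    abort("reference-patch fractions must be >= 0 and leave arable area",
          class = "laihet_config_error")
  }
  with(cfg$crops, {
    if (any(!(emergence < peak & peak < sen_end))) {
      abort("each crop needs emergence < day of maximum < senescence end",
            class = "laihet_config_error")
    }
  })
  if (!(cfg$ndvi_v > cfg$ndvi_s)) {
    abort("ndvi_v must exceed ndvi_s", class = "laihet_config_error")
  }
  if (cfg$k <= 0) abort("extinction coefficient k must be > 0", class = "laihet_config_error")
  cfg
}

#' Read a scene configuration from a YAML or JSON file
#'
#' The file holds any subset of the [scene_config()] arguments; `crops` may
#' be given as a list of per-crop records.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `scene_config`.
#' @export
read_scene_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$crops)) raw$crops <- as_tibble(as.data.frame(raw$crops))
  do.call(scene_config, raw)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d x %d px @ %g m (%.1f x %.1f km), seed %d\n",
              x$rows, x$cols, x$res,
              x$rows * x$res / 1000, x$cols * x$res / 1000, x$seed))
  cat(sprintf("  fields: mean %.2f ha, sigma(log) %.2f | sd_field %.2f, sd_pixel %.2f, long-range sill %.2f @ %g m\n",
              x$field_mean_area / 1e4, x$field_sigma_log,
              x$sd_field, x$sd_pixel, x$lr_sill, x$lr_range))
  cat(sprintf("  crops: %s\n",
              paste(sprintf("%s %.0f%%", x$crops$crop, 100 * x$crops$proportion),
                    collapse = ", ")))
  invisible(x)
}
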