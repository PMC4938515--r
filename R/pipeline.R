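#' Configure an end-to-end heterogeneity analysis run
#'
#' @param mode `"synthetic"` (generate a scene) or `"rasters"` (read NIR,
#'   Red and land-use rasters from files written by [write_raster_tiff()]).
#' @param scene a [scene_config()] (synthetic mode). Its seed is replaced by
#'   the run `seed` so one master seed drives every stage.
#' @param rasters named list for raster mode: for each date a list with
#'   `nir`, `red`, `landuse` file paths.
#' @param days analysis dates (days of year).
#' @param crop_codes land-use codes analysed as separate crops.
#' @param calendar a [crop_calendar()] for the plausibility filter.
#' @param class_width RFD class width (LAI units).
#' @param lag_width,max_lag variogram lag class width and maximum lag, m.
#' @param subsample fraction of pixels entering the variogram.
#' @param size_threshold field-size filter threshold (m^2 or `"median"`).
#' @param variograms compute spatial-structure statistics (slowest stage).
#' @param out_dir if non-`NULL`, the report is written there as JSON + CSV.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "rasters"),
                       scene = scene_config(), rasters = NULL,
                       days = c(80, 170), crop_codes = c(1L, 2L, 3L),
                       calendar = NULL,
                       class_width = 0.1, lag_width = 200, max_lag = 25000,
                       subsample = 0.005, size_threshold = "median",
                       variograms = TRUE, out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (length(days) == 0) abort("at least one analysis day is required",
                               class = "laihet_config_error")
  if (mode == "rasters") {
    if (is.null(rasters)) abort("raster mode needs input paths",
                                class = "laihet_config_error")
    for (d in names(rasters)) {
      for (p in unlist(rasters[[d]])) {
        if (!file.exists(p)) {
          abort(sprintf("input file does not exist: %s", p),
                class = "laihet_config_error")
        }
      }
    }
  } else {
    scene$seed <- as.integer(seed)
  }
  if (is.null(calendar)) {
    calendar <- if (mode == "synthetic") default_crop_calendar(scene$crops)
                else default_crop_calendar()
  }
  structure(list(mode = mode, scene = scene, rasters = rasters, days = days,
                 crop_codes = as.integer(crop_codes), calendar = calendar,
                 class_width = class_width, lag_width = lag_width,
                 max_lag = max_lag, subsample = subsample,
                 size_threshold = size_threshold, variograms = variograms,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

stage_seed <- function(seed, stage, day = 0) {
  as.integer((as.numeric(seed) * 1009 + stage * 97 + day * 131) %% 2147483647)
}

#' Run the full heterogeneity pipeline
#'
#' Executes, in order and per analysis date: scene generation or raster
#' ingestion, LAI retrieval from the reflectance pair (NDVI, per-date
#' endmembers, FVC, Beer-Lambert inversion), mixed-pixel masking, field
#' segmentation and size filtering, the crop plausibility filter,
#' variability statistics (per-crop and pooled overall mean/SD, pixel and
#' field-mean RFDs, accordance against the field-mean and
#' normal-distribution comparators) and, optionally, the geostatistical
#' structure analysis (subsampling, abundance rebalancing, nested
#' exponential variogram fitting, range extraction). All randomness derives
#' from the single run seed, so re-running an identical configuration is
#' bit-identical.
#'
#' @param config a [run_config()].
#' @return a `heterogeneity_report`: tibbles `stats` (per date x crop x
#'   overall: mean, sd, n), `accordances`, `variograms`, plus `rfds`,
#'   `field_maps` metadata and the `config`. Written to `config$out_dir` as
#'   JSON + CSV when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    truth <- generate_mosaic(config$scene)
    scene_cfg <- config$scene
  } else {
    truth <- NULL
    scene_cfg <- NULL
  }

  stats_rows <- list(); acc_rows <- list(); vgm_rows <- list()
  rfds <- list(); fmaps <- list()

  for (day in config$days) {
    inp <- pipeline_inputs(config, truth, day)
    ret <- retrieve_lai(inp$nir, inp$red, inp$landuse)
    keep <- mask_mixed_pixels(inp$landuse)
    arable_lu <- inp$landuse
    arable_lu[arable_lu %in% c(FOREST_CODE, BARE_CODE)] <- NA_integer_
    # analyses run on non-mixed arable pixels only
    lai <- ret$lai
    lai[!keep | is.na(arable_lu)] <- NA_real_
    fm <- segment_fields(arable_lu, keep & !is.na(arable_lu), res = inp$res)
    fm <- filter_fields_by_size(fm, config$size_threshold)
    fa <- field_aggregates(lai, fm)
    fmaps[[as.character(day)]] <- fm$size_filter

    plaus <- plausibility_filter(lai, arable_lu, config$calendar, day,
                                 codes = intersect(config$crop_codes,
                                                   config$calendar$windows$code))

    arable_codes <- sort(unique(arable_lu[!is.na(arable_lu)]))
    orig_n <- vapply(arable_codes,
                     function(cl) sum(inp$landuse_orig == cl, na.rm = TRUE),
                     numeric(1))
    weights_all <- orig_n / sum(orig_n)

    lai_plaus <- lai
    lai_plaus[!plaus] <- NA_real_
    per_crop <- crop_pixel_stats(lai_plaus, arable_lu, config$crop_codes)
    per_crop$crop <- crop_label(per_crop$code, scene_cfg)
    # overall arable: plausibility filter deliberately not applied
    all_stats <- crop_pixel_stats(lai, arable_lu, arable_codes)
    all_stats$weight <- weights_all
    ov <- overall_stats(all_stats[!is.na(all_stats$mean), ] %>%
                          mutate(weight = .data$weight / sum(.data$weight)))

    stats_rows[[length(stats_rows) + 1L]] <- bind_rows(
      per_crop %>% select("crop", "code", "mean", "sd", "n"),
      tibble(crop = "overall_arable", code = NA_integer_,
             mean = ov$mean, sd = ov$sd, n = sum(all_stats$n))
    ) %>% mutate(day = day, .before = 1)

    # RFDs: per-crop pixel RFDs combined with abundance weights; overall
    # pixel RFD; area-weighted field-mean RFD
    crop_rfds <- purrr::map(arable_codes, function(cl) {
      v <- lai[!is.na(arable_lu) & arable_lu == cl]
      v <- v[!is.na(v)]
      if (length(v) == 0) NULL else build_rfd(v, config$class_width)
    })
    have <- !vapply(crop_rfds, is.null, logical(1))
    rfd_overall <- weighted_rfd(crop_rfds[have], weights_all[have])
    fa_ok <- fa[!fa$missing, , drop = FALSE]
    rfd_fieldmean <- build_rfd(rep(fa_ok$mean, fa_ok$n_valid), config$class_width)
    rfd_normal <- normal_reference_rfd(ov$mean, ov$sd, config$class_width)
    rfds[[as.character(day)]] <- list(pixel = rfd_overall,
                                      field_mean = rfd_fieldmean,
                                      normal = rfd_normal)
    acc_rows[[length(acc_rows) + 1L]] <- tibble(
      day = day,
      comparison = c("pixel_vs_field_mean", "pixel_vs_normal"),
      accordance = c(accordance(rfd_overall, rfd_fieldmean),
                     accordance(rfd_overall, rfd_normal))
    )

    if (config$variograms) {
      pts <- subsample_points(lai, config$subsample,
                              seed = stage_seed(config$seed, 5, day),
                              res = inp$res)
      rr <- round(pts$y / inp$res + 0.5); cc <- round(pts$x / inp$res + 0.5)
      pts$code <- arable_lu[cbind(rr, cc)]
      pts <- rebalance_abundance(pts, setNames(weights_all, arable_codes),
                                 seed = stage_seed(config$seed, 6, day))
      ev <- empirical_variogram(pts, config$lag_width, config$max_lag)
      mod <- fit_variogram_ladder(ev)
      er <- effective_ranges(mod)
      vgm_rows[[length(vgm_rows) + 1L]] <- dplyr::bind_cols(
        tibble(day = day, crop = "overall_arable"), glance(mod))
    }
  }

  rep <- structure(list(
    stats = bind_rows(stats_rows),
    accordances = bind_rows(acc_rows),
    variograms = if (length(vgm_rows)) bind_rows(vgm_rows) else tibble(),
    rfds = rfds,
    field_maps = bind_rows(fmaps, .id = "day"),
    config = config
  ), class = "heterogeneity_report")
  if (!is.null(config$out_dir)) write_report(rep, config$out_dir)
  rep
}

crop_label <- function(code, scene_cfg) {
  if (is.null(scene_cfg)) return(paste0("crop_", code))
  lbl <- scene_cfg$crops$crop[match(code, scene_cfg$crops$code)]
  ifelse(is.na(lbl), paste0("crop_", code), lbl)
}

# assemble per-date inputs for both pipeline modes
pipeline_inputs <- function(config, truth, day) {
  if (config$mode == "synthetic") {
    lai_true <- simulate_lai(truth, day)
    refl <- forward_ndvi(lai_true, config$scene, landuse = truth$landuse,
                         seed = stage_seed(config$seed, 2, day))
    list(nir = refl$nir, red = refl$red, landuse = truth$landuse,
         landuse_orig = truth$landuse, res = truth$res, lai_true = lai_true)
  } else {
    paths <- config$rasters[[as.character(day)]] %||% config$rasters[[match(day, config$days)]]
    nir <- read_raster_tiff(paths$nir)
    red <- read_raster_tiff(paths$red)
    lu <- read_raster_tiff(paths$landuse)
    list(nir = unclass_matrix(nir), red = unclass_matrix(red),
         landuse = unclass_matrix(lu), landuse_orig = unclass_matrix(lu),
         res = attr(lu, "res") %||% 1, lai_true = NULL)
  }
}

unclass_matrix <- function(m) { attr(m, "res") <- NULL; m }

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("<heterogeneity_report> %d date(s), %d stat rows\n",
              length(unique(x$stats$day)), nrow(x$stats)))
  print(x$stats)
  if (nrow(x$accordances)) print(x$accordances)
  invisible(x)
}

#' Write a heterogeneity report as a JSON + CSV bundle
#'
#' @param report a `heterogeneity_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$stats, file.path(dir, "stats.csv"), row.names = FALSE)
  utils::write.csv(report$accordances, file.path(dir, "accordances.csv"),
                   row.names = FALSE)
  if (nrow(report$variograms)) {
    utils::write.csv(report$variograms, file.path(dir, "variograms.csv"),
                     row.names = FALSE)
  }
  for (d in names(report$rfds)) {
    utils::write.csv(as.data.frame(report$rfds[[d]]$pixel),
                     file.path(dir, sprintf("rfd_pixel_day%s.csv", d)),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(
    stats = report$stats, accordances = report$accordances,
    variograms = report$variograms, field_maps = report$field_maps,
    seed = report$config$seed
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Compare two LAI datasets on the same grid
#'
#' Per-crop and overall accordance of the relative frequency distributions
#' and differences of mean and SD between two LAI rasters (e.g. retrieved
#' vs true, pixel vs field-mean).
#'
#' @param lai_a,lai_b congruent LAI matrices.
#' @param landuse congruent class matrix.
#' @param codes crop codes to compare separately.
#' @param class_width RFD class width.
#' @return tibble: `crop`, `accordance`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `d_mean`, `d_sd`.
#' @export
compare_datasets <- function(lai_a, lai_b, landuse, codes = NULL,
                             class_width = 0.1) {
  check_congruent(lai_a, lai_b, "lai_a", "lai_b")
  check_congruent(lai_a, landuse, "lai_a", "landuse")
  groups <- c(as.list(codes), list(NULL))
  names(groups) <- c(if (length(codes)) paste0("crop_", codes), "overall")
  purrr::map_dfr(names(groups), function(g) {
    cl <- groups[[g]]
    sel <- if (is.null(cl)) !is.na(landuse) else !is.na(landuse) & landuse == cl
    va <- lai_a[sel]; vb <- lai_b[sel]
    ok <- !is.na(va) & !is.na(vb)
    va <- va[ok]; vb <- vb[ok]
    if (length(va) == 0) {
      return(tibble(crop = g, accordance = NA_real_, mean_a = NA_real_,
                    mean_b = NA_real_, sd_a = NA_real_, sd_b = NA_real_,
                    d_mean = NA_real_, d_sd = NA_real_))
    }
    acc <- accordance(build_rfd(va, class_width), build_rfd(vb, class_width))
    tibble(crop = g, accordance = acc,
           mean_a = mean(va), mean_b = mean(vb),
           sd_a = pop_sd(va), sd_b = pop_sd(vb),
           d_mean = mean(va) - mean(vb), d_sd = pop_sd(va) - pop_sd(vb))
  })
}
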