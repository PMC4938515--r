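#' @rdname reference-codes
#' @export
FALLOW_CODE <- 9L

# Ratio of the mean realised field area to the mean of the stop-threshold
# distribution in the recursive splitting below (a rectangle is split until
# its area drops under a log-normal draw, so final areas undershoot the
# threshold by this factor on average). Measured once on large mosaics and
# fixed, so that `field_mean_area` means what it says.
.bsp_undershoot <- 0.515

#' Generate the land-use mosaic of a synthetic scene
#'
#' Builds a rectangular-partition field mosaic by recursive binary space
#' partitioning with jittered split positions: each rectangle is split along
#' its longer side until its area falls below a log-normal draw, so field
#' areas follow the configured log-normal law and fields are rectangular
#' like real parcels. Each field is assigned one crop by sampling the
#' configured crop shares; any unassigned share becomes bare fallow
#' (code `FALLOW_CODE`). Disjoint forest and bare-ground reference bands
#' occupy their configured domain fractions at the top and bottom edges.
#'
#' @param config a [scene_config()].
#' @return a `scene_truth` object: land-use raster (`landuse`), field label
#'   raster (`field_labels`), per-field table (`fields`: id, code, crop,
#'   n_pixels, area_m2, centroid), plus `res` and the `config`.
#' @export
generate_mosaic <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  rows <- config$rows; cols <- config$cols; res <- config$res
  nf <- round(config$prop_forest * rows)
  nb <- round(config$prop_bare * rows)
  r0 <- nf + 1L; r1 <- rows - nb
  arable_px <- (r1 - r0 + 1) * cols
  mean_px <- config$field_mean_area / res^2
  if (arable_px / mean_px < 20) {
    abort(sprintf("domain too small: %.0f arable pixels hold only %.1f fields of mean area %.2f ha",
                  arable_px, arable_px / mean_px, config$field_mean_area / 1e4),
          class = "laihet_sizing_error")
  }
  set.seed(config$seed)

  sigma <- config$field_sigma_log
  meanlog <- log(mean_px / .bsp_undershoot) - sigma^2 / 2

  # stack of rectangles (r0, r1, c0, c1) with a stop threshold drawn at birth
  stack <- list(list(r = c(r0, r1), c = c(1L, cols),
                     stop_at = stats::rlnorm(1, meanlog, sigma)))
  final <- list()
  while (length(stack) > 0) {
    rect <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    h <- rect$r[2] - rect$r[1] + 1L
    w <- rect$c[2] - rect$c[1] + 1L
    if (h * w <= rect$stop_at || max(h, w) < 4L) {
      final[[length(final) + 1L]] <- rect
      next
    }
    along_rows <- h >= w
    len <- if (along_rows) h else w
    cut <- round(len * runif(1, 0.4, 0.6))
    cut <- min(max(cut, 2L), len - 2L)
    if (along_rows) {
      a <- list(r = c(rect$r[1], rect$r[1] + cut - 1L), c = rect$c)
      b <- list(r = c(rect$r[1] + cut, rect$r[2]), c = rect$c)
    } else {
      a <- list(r = rect$r, c = c(rect$c[1], rect$c[1] + cut - 1L))
      b <- list(r = rect$r, c = c(rect$c[1] + cut, rect$c[2]))
    }
    a$stop_at <- stats::rlnorm(1, meanlog, sigma)
    b$stop_at <- stats::rlnorm(1, meanlog, sigma)
    stack[[length(stack) + 1L]] <- a
    stack[[length(stack) + 1L]] <- b
  }

  n_fields <- length(final)
  p <- config$crops$proportion
  codes_pool <- config$crops$code
  if (sum(p) < 1 - 1e-9) {
    codes_pool <- c(codes_pool, FALLOW_CODE)
    p <- c(p, 1 - sum(p))
  }
  field_code <- sample(codes_pool, n_fields, replace = TRUE, prob = p)

  labels <- matrix(0L, rows, cols)
  landuse <- matrix(NA_integer_, rows, cols)
  if (nf > 0) landuse[seq_len(nf), ] <- FOREST_CODE
  if (nb > 0) landuse[(rows - nb + 1L):rows, ] <- BARE_CODE
  rec <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    rect <- final[[i]]
    ri <- rect$r[1]:rect$r[2]; ci <- rect$c[1]:rect$c[2]
    labels[ri, ci] <- i
    landuse[ri, ci] <- field_code[i]
    rec[[i]] <- c(n = length(ri) * length(ci),
                  crow = mean(ri), ccol = mean(ci))
  }
  recm <- do.call(rbind, rec)
  crop_name <- config$crops$crop[match(field_code, config$crops$code)]
  crop_name[is.na(crop_name)] <- "fallow"
  fields <- tibble(
    id = seq_len(n_fields),
    code = as.integer(field_code),
    crop = crop_name,
    n_pixels = as.integer(recm[, "n"]),
    area_m2 = recm[, "n"] * res^2,
    centroid_row = recm[, "crow"],
    centroid_col = recm[, "ccol"]
  )
  structure(list(landuse = landuse, field_labels = labels, fields = fields,
                 res = res, config = config),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d px @ %g m, %d fields (mean %.2f ha)\n",
              nrow(x$landuse), ncol(x$landuse), x$res,
              nrow(x$fields), mean(x$fields$area_m2) / 1e4))
  invisible(x)
}

#' Seasonal LAI curve of a crop
#'
#' Piecewise curve: 0 before emergence, a logistic rise normalised to reach
#' exactly the crop maximum on the day of maximum, then a linear senescent
#' decline to 0 at the end of senescence.
#'
#' @param day day of year (scalar).
#' @param emergence,peak,max_lai,sen_end curve parameters (vectorised).
#' @return LAI value(s) of the deterministic curve.
#' @export
lai_curve <- function(day, emergence, peak, max_lai, sen_end) {
  mid <- (emergence + peak) / 2
  rate <- 8 / (peak - emergence)
  sig <- function(d) 1 / (1 + exp(-rate * (d - mid)))
  rise <- max_lai * (sig(day) - sig(emergence)) / (sig(peak) - sig(emergence))
  fall <- max_lai * (sen_end - day) / (sen_end - peak)
  out <- ifelse(day < emergence, 0,
                ifelse(day <= peak, rise,
                       ifelse(day <= sen_end, fall, 0)))
  pmax(out, 0)
}

#' Simulate a zero-mean Gaussian random field with exponential covariance
#'
#' Circulant-embedding (FFT) simulation on a regular grid; the covariance is
#' `sill * exp(-d / range_par)`. Negative embedding eigenvalues (possible for
#' the exponential family on a finite torus) are set to zero, the standard
#' approximation; the resulting marginal variance is checked in the test
#' suite.
#'
#' @param nr,nc grid size in pixels.
#' @param res pixel size, m.
#' @param sill marginal variance.
#' @param range_par range parameter of the exponential covariance, m.
#' @return an `nr` x `nc` numeric matrix.
#' @export
sim_grf_exp <- function(nr, nc, res, sill, range_par) {
  if (sill == 0) return(matrix(0, nr, nc))
  m1 <- 2L * nr; m2 <- 2L * nc
  di <- pmin(0:(m1 - 1), m1 - (0:(m1 - 1))) * res
  dj <- pmin(0:(m2 - 1), m2 - (0:(m2 - 1))) * res
  dmat <- sqrt(outer(di^2, dj^2, `+`))
  lam <- Re(fft(sill * exp(-dmat / range_par)))
  lam[lam < 0] <- 0
  e <- matrix(stats::rnorm(m1 * m2), m1, m2) +
    1i * matrix(stats::rnorm(m1 * m2), m1, m2)
  y <- fft(sqrt(lam) * e) / sqrt(m1 * m2)
  Re(y)[seq_len(nr), seq_len(nc)]
}

#' Simulate the true LAI raster of a scene for one date
#'
#' Adds four components on arable pixels: the crop's deterministic seasonal
#' curve at `day`, a per-field offset `N(0, sd_field)`, an optional long-range
#' background field with exponential covariance, and pixel noise
#' `N(0, sd_pixel)`; the sum is clamped at 0. Forest pixels get the constant
#' configured forest LAI, bare ground gets 0.
#'
#' @param truth a `scene_truth` from [generate_mosaic()].
#' @param day day of year in `[1, 366]`.
#' @param components if `TRUE`, also return the additive component rasters.
#' @param seed RNG seed; defaults to a value derived from the scene seed and
#'   `day`, so identical configurations give bit-identical output.
#' @return the LAI matrix, or (with `components = TRUE`) a list with `lai`,
#'   `curve`, `field_effect`, `long_range`, `noise`.
#' @export
simulate_lai <- function(truth, day, components = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "scene_truth"))
  if (!is.numeric(day) || length(day) != 1 || day < 1 || day > 366) {
    abort("day must be a single day-of-year in [1, 366]", class = "laihet_domain_error")
  }
  cfg <- truth$config
  if (is.null(seed)) {
    seed <- as.integer((as.numeric(cfg$seed) * 131 + day * 7919) %% 2147483647)
  }
  set.seed(seed)
  nr <- nrow(truth$landuse); nc <- ncol(truth$landuse)

  cv <- lai_curve(day, cfg$crops$emergence, cfg$crops$peak,
                  cfg$crops$max_lai, cfg$crops$sen_end)
  curve <- matrix(0, nr, nc)
  idx <- match(as.vector(truth$landuse), cfg$crops$code)
  hit <- !is.na(idx)
  curve[hit] <- cv[idx[hit]]

  eff <- stats::rnorm(nrow(truth$fields), 0, cfg$sd_field)
  field_effect <- matrix(c(0, eff)[truth$field_labels + 1L], nr, nc)

  long_range <- if (cfg$lr_sill > 0) {
    sim_grf_exp(nr, nc, cfg$res, cfg$lr_sill, cfg$lr_range)
  } else {
    matrix(0, nr, nc)
  }

  noise <- matrix(stats::rnorm(nr * nc, 0, cfg$sd_pixel), nr, nc)

  arable <- truth$field_labels > 0
  lai <- matrix(0, nr, nc)
  lai[arable] <- pmax(0, curve[arable] + field_effect[arable] +
                        long_range[arable] + noise[arable])
  lai[!is.na(truth$landuse) & truth$landuse == FOREST_CODE] <- cfg$forest_lai
  # bare ground and any other non-arable class stays 0
  if (!components) return(lai)
  list(lai = lai, curve = curve, field_effect = field_effect,
       long_range = long_range, noise = noise)
}

#' Forward NDVI sensor model: LAI to a (NIR, Red) reflectance pair
#'
#' The exact inverse of the retrieval chain: `FVC = 1 - exp(-k * LAI)`,
#' `NDVI = ndvi_s + FVC * (ndvi_v - ndvi_s)`, then a reflectance pair
#' consistent with that NDVI (Red held at a fixed baseline of 0.05, NIR
#' solved from the NDVI definition), plus optional Gaussian reflectance
#' noise. When a land-use raster is supplied, forest pixels emit the fully
#' vegetated endmember NDVI and bare-ground pixels the bare-soil endmember,
#' so per-date endmember estimation can be exercised downstream.
#'
#' @param lai LAI matrix.
#' @param config a [scene_config()] (supplies endmembers, `k`, noise SD).
#' @param landuse optional land-use matrix for the reference classes.
#' @param noise_sd reflectance noise SD; defaults to the configured value.
#' @param seed RNG seed used when `noise_sd > 0` (default derived from the
#'   scene seed).
#' @return list with matrices `nir` and `red`.
#' @export
forward_ndvi <- function(lai, config, landuse = NULL,
                         noise_sd = config$refl_noise_sd, seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  fvc <- 1 - exp(-config$k * lai)
  ndvi <- config$ndvi_s + fvc * (config$ndvi_v - config$ndvi_s)
  if (!is.null(landuse)) {
    check_congruent(lai, landuse, "lai", "landuse")
    ndvi[!is.na(landuse) & landuse == FOREST_CODE] <- config$ndvi_v
    ndvi[!is.na(landuse) & landuse == BARE_CODE] <- config$ndvi_s
  }
  ndvi <- pmin(ndvi, 0.999)
  red <- matrix(0.05, nrow(lai), ncol(lai))
  nir <- red * (1 + ndvi) / (1 - ndvi)
  if (noise_sd > 0) {
    if (is.null(seed)) {
      seed <- as.integer((as.numeric(config$seed) * 131 + 104729) %% 2147483647)
    }
    set.seed(seed)
    nir <- nir + matrix(stats::rnorm(length(nir), 0, noise_sd), nrow(nir))
    red <- red + matrix(stats::rnorm(length(red), 0, noise_sd), nrow(red))
    nir <- pmax(nir, 1e-6)
    red <- pmax(red, 1e-6)
  }
  nir[is.na(lai)] <- NA_real_
  red[is.na(lai)] <- NA_real_
  list(nir = nir, red = red)
}
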