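#' Retrieval parameters for the NDVI-FVC-LAI chain
#'
#' @param k light extinction coefficient of the Beer-Lambert canopy link
#'   (unitless; 0.54 is the standard value for mid-latitude arable scenes).
#' @param cap upper LAI bound; FVC values that would map above it are
#'   truncated so retrieved LAI stays finite (NDVI saturates near the
#'   vegetated endmember, where the inversion diverges).
#' @param clamp_negative if `TRUE` (default), negative FVC (NDVI below the
#'   bare-soil endmember, caused by soil heterogeneity) maps to LAI 0.
#' @return a `retrieval_params` list.
#' @export
retrieval_params <- function(k = 0.54, cap = 7.0, clamp_negative = TRUE) {
  if (k <= 0) abort("k must be > 0", class = "laihet_config_error")
  if (cap <= 0) abort("cap must be > 0", class = "laihet_config_error")
  structure(list(k = k, cap = cap, clamp_negative = clamp_negative),
            class = "retrieval_params")
}

#' Compute NDVI from a NIR/Red reflectance pair
#'
#' `(NIR - Red) / (NIR + Red)` per pixel. Nodata propagates; pixels with
#' `NIR + Red = 0` become nodata.
#'
#' @param nir,red congruent reflectance matrices in `[0, 1]`.
#' @return NDVI matrix.
#' @export
compute_ndvi <- function(nir, red) {
  check_congruent(nir, red, "nir", "red")
  s <- nir + red
  ndvi <- (nir - red) / s
  ndvi[!is.na(s) & s == 0] <- NA_real_
  ndvi
}

#' Estimate per-date NDVI endmembers from reference land-cover classes
#'
#' The fully vegetated endmember is taken from broadleaf-forest pixels and
#' the bare-soil endmember from bare-ground pixels, the two temporally
#' stable cover classes. Each endmember is the modal histogram bin (width
#' `bin_width`) of the class's NDVI values, reported as the mean NDVI within
#' that bin; ties break toward the higher bin for the vegetated endmember
#' and the lower bin for the soil endmember.
#'
#' @param ndvi NDVI matrix.
#' @param landuse congruent class matrix.
#' @param forest_code,bare_code reference class codes.
#' @param bin_width histogram bin width (NDVI units).
#' @param min_n minimum valid pixels required per reference class.
#' @return an `endmembers` list with `ndvi_v`, `ndvi_s`, `n_forest`, `n_bare`.
#' @export
estimate_endmembers <- function(ndvi, landuse,
                                forest_code = FOREST_CODE, bare_code = BARE_CODE,
                                bin_width = 0.01, min_n = 100) {
  check_congruent(ndvi, landuse, "ndvi", "landuse")
  hist_mode <- function(v, tie_high) {
    v <- v[!is.na(v)]
    if (length(v) < min_n) {
      abort(sprintf("only %d valid reference pixels (need >= %d)", length(v), min_n),
            class = "laihet_estimation_error")
    }
    bin <- floor(v / bin_width + 1e-9)
    tab <- table(bin)
    top <- as.integer(names(tab)[tab == max(tab)])
    b <- if (tie_high) max(top) else min(top)
    list(value = mean(v[bin == b]), n = length(v))
  }
  fo <- hist_mode(ndvi[!is.na(landuse) & landuse == forest_code], tie_high = TRUE)
  ba <- hist_mode(ndvi[!is.na(landuse) & landuse == bare_code], tie_high = FALSE)
  if (fo$value <= ba$value) {
    abort(sprintf("inconsistent endmembers: ndvi_v (%.3f) <= ndvi_s (%.3f)",
                  fo$value, ba$value),
          class = "laihet_endmember_error")
  }
  structure(list(ndvi_v = fo$value, ndvi_s = ba$value,
                 n_forest = fo$n, n_bare = ba$n),
            class = "endmembers")
}

#' @export
print.endmembers <- function(x, ...) {
  cat(sprintf("<endmembers> ndvi_v = %.4f (n = %d), ndvi_s = %.4f (n = %d)\n",
              x$ndvi_v, x$n_forest, x$ndvi_s, x$n_bare))
  invisible(x)
}

# FVC value at which retrieved LAI hits the cap
fvc_cap <- function(params) 1 - exp(-params$k * params$cap)

#' Convert NDVI to fractional vegetation cover
#'
#' Linear normalisation between the endmembers:
#' `FVC = (NDVI - ndvi_s) / (ndvi_v - ndvi_s)`. Values may fall outside
#' `[0, 1]`; FVC at or above the value corresponding to the LAI cap is
#' truncated there, so the Beer-Lambert inversion stays finite.
#'
#' @param ndvi NDVI matrix.
#' @param em an `endmembers` object (or list with `ndvi_v`, `ndvi_s`).
#' @param params [retrieval_params()].
#' @return FVC matrix.
#' @export
ndvi_to_fvc <- function(ndvi, em, params = retrieval_params()) {
  if (!(em$ndvi_v > em$ndvi_s)) {
    abort("endmembers must satisfy ndvi_v > ndvi_s", class = "laihet_endmember_error")
  }
  pmin((ndvi - em$ndvi_s) / (em$ndvi_v - em$ndvi_s), fvc_cap(params))
}

#' Invert fractional vegetation cover to LAI (Beer-Lambert)
#'
#' `LAI = -ln(1 - FVC) / k`. Negative FVC (NDVI below the soil endmember)
#' maps to LAI 0; FVC is truncated so LAI never exceeds the cap.
#'
#' @param fvc FVC matrix.
#' @param params [retrieval_params()].
#' @return LAI matrix in `[0, cap]` (nodata propagates).
#' @export
fvc_to_lai <- function(fvc, params = retrieval_params()) {
  f <- pmin(fvc, fvc_cap(params))
  lai <- -log(1 - f) / params$k
  if (params$clamp_negative) lai <- pmax(lai, 0)
  lai
}

#' Full LAI retrieval from a two-band reflectance pair
#'
#' Chains [compute_ndvi()], [estimate_endmembers()] (unless endmembers are
#' supplied), [ndvi_to_fvc()] and [fvc_to_lai()].
#'
#' @param nir,red reflectance matrices.
#' @param landuse class matrix with the reference classes (needed when `em`
#'   is `NULL`).
#' @param em optional pre-estimated `endmembers`; skips estimation.
#' @param params [retrieval_params()].
#' @inheritParams estimate_endmembers
#' @return list with `lai` (matrix), `ndvi`, `endmembers`, `params`.
#' @export
retrieve_lai <- function(nir, red, landuse = NULL, em = NULL,
                         params = retrieval_params(),
                         forest_code = FOREST_CODE, bare_code = BARE_CODE) {
  ndvi <- compute_ndvi(nir, red)
  if (is.null(em)) {
    if (is.null(landuse)) {
      abort("either endmembers or a land-use raster with reference classes is required",
            class = "laihet_config_error")
    }
    em <- estimate_endmembers(ndvi, landuse, forest_code, bare_code)
  }
  lai <- fvc_to_lai(ndvi_to_fvc(ndvi, em, params), params)
  list(lai = lai, ndvi = ndvi, endmembers = em, params = params)
}
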