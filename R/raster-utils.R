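#' Raster conventions used throughout the package
#'
#' Rasters are plain R matrices: `numeric` for continuous products
#' (reflectance, NDVI, FVC, LAI) and `integer` for class rasters (land use,
#' field labels). `NA` marks nodata in both cases. The physical pixel size in
#' metres is carried separately (a `res` argument or a field of the scene
#' objects); rows index northing, columns easting, and pixel centres sit at
#' `(col - 0.5) * res`, `(row - 0.5) * res`.
#'
#' @name raster-conventions
NULL

# shared congruence check: same dimensions, or stop with the caller's context
check_congruent <- function(a, b, what_a = "first raster", what_b = "second raster") {
  if (!is.matrix(a) || !is.matrix(b)) {
    abort(sprintf("%s and %s must be matrices", what_a, what_b),
          class = "laihet_congruence_error")
  }
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    abort(sprintf("%s (%d x %d) and %s (%d x %d) are not on the same grid",
                  what_a, nrow(a), ncol(a), what_b, nrow(b), ncol(b)),
          class = "laihet_congruence_error")
  }
  invisible(TRUE)
}

#' Write a raster matrix to a TIFF file with a JSON sidecar
#'
#' Continuous rasters are stored as 32-bit TIFF after affine rescaling to
#' `[0, 1]`; the scaling, resolution, nodata convention and semantic are
#' recorded in a `<path>.json` sidecar so that [read_raster_tiff()] restores
#' the original values. Class rasters are stored with nodata encoded as 0,
#' continuous rasters with a validity band. This keeps the on-disk format a
#' plain TIFF readable by any imaging tool.
#'
#' @param x numeric or integer matrix; `NA` is nodata.
#' @param path output file path (`.tif`).
#' @param res pixel size in metres.
#' @param semantic free-text product tag (e.g. `"lai"`, `"ndvi"`, `"landuse"`).
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(x, path, res = NA_real_, semantic = "raster") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for raster file I/O")
  }
  valid <- !is.na(x)
  integerish <- is.integer(x)
  v <- as.numeric(x)
  rng <- if (any(valid)) range(v[valid]) else c(0, 1)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  scaled <- matrix(0, nrow(x), ncol(x))
  scaled[valid] <- (v[valid] - rng[1]) / (rng[2] - rng[1])
  img <- array(0, dim = c(nrow(x), ncol(x), 2))
  img[, , 1] <- scaled
  img[, , 2] <- valid * 1.0
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  meta <- list(semantic = semantic, res = res, vmin = rng[1], vmax = rng[2],
               integer = integerish, nodata_band = 2)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster_tiff()]
#'
#' @param path file path written by [write_raster_tiff()].
#' @return the matrix, with the pixel size attached as attribute `"res"`.
#' @export
read_raster_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for raster file I/O")
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  # libtiff flags the value+validity band pair as unusual colour channels
  img <- suppressWarnings(tiff::readTIFF(path))
  v <- img[, , 1] * (meta$vmax - meta$vmin) + meta$vmin
  v[img[, , 2] < 0.5] <- NA
  if (isTRUE(meta$integer)) {
    m <- matrix(as.integer(round(v)), nrow(v), ncol(v))
  } else {
    m <- v
  }
  attr(m, "res") <- meta$res
  m
}
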