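#' Majority resampling of a class raster
#'
#' Coarsens a categorical raster by `factor`: each output cell takes the
#' most frequent class among its `factor` x `factor` block, ignoring nodata.
#' Ties break to the lowest class code, so the result is deterministic.
#' Dimensions not divisible by `factor` are padded with nodata.
#'
#' @param landuse integer class matrix (`NA` = nodata).
#' @param factor integer aggregation factor, >= 1.
#' @return the coarsened class matrix.
#' @export
upscale_majority <- function(landuse, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1) {
    abort("factor must be a single integer >= 1", class = "laihet_parameter_error")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(landuse)
  nr <- nrow(landuse); nc <- ncol(landuse)
  nbr <- ceiling(nr / factor); nbc <- ceiling(nc / factor)
  pad <- matrix(NA_integer_, nbr * factor, nbc * factor)
  pad[seq_len(nr), seq_len(nc)] <- landuse
  br <- (row(pad) - 1L) %/% factor
  bc <- (col(pad) - 1L) %/% factor
  bid <- br * nbc + bc + 1L
  classes <- sort(unique(as.vector(pad[!is.na(pad)])))
  if (length(classes) == 0) return(matrix(NA_integer_, nbr, nbc))
  counts <- vapply(classes, function(cl) {
    rowsum(as.numeric(!is.na(pad) & pad == cl), as.vector(bid))[, 1]
  }, numeric(nbr * nbc))
  counts <- matrix(counts, nrow = nbr * nbc)
  best <- max.col(counts, ties.method = "first")  # classes sorted: tie -> lowest code
  out <- classes[best]
  out[rowSums(counts) == 0] <- NA_integer_
  # bid runs row-major over blocks; fill accordingly
  matrix(out, nbr, nbc, byrow = TRUE)
}

#' Mask pixels of potentially mixed land use
#'
#' A pixel is kept only if all of its neighbours exist and share its class,
#' so borders between land-use units (and the raster edge) are removed and
#' the result consists of continuous uniform-class areas separated by
#' nodata strips. The strict reading uses the full 8-neighbourhood
#' (default); 4-neighbourhood is available.
#'
#' @param landuse integer class matrix.
#' @param connectivity 8 (Moore neighbourhood, default) or 4.
#' @return logical keep-mask matrix.
#' @export
mask_mixed_pixels <- function(landuse, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) {
    abort("connectivity must be 4 or 8", class = "laihet_parameter_error")
  }
  nr <- nrow(landuse); nc <- ncol(landuse)
  pad <- matrix(NA_integer_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- landuse
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  offs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  keep <- !is.na(ctr)
  for (o in offs) {
    nb <- pad[2:(nr + 1L) + o[1], 2:(nc + 1L) + o[2]]
    keep <- keep & !is.na(nb) & nb == ctr
  }
  keep[is.na(keep)] <- FALSE
  keep
}

#' Segment kept pixels into fields
#'
#' Connected components (4-connectivity by default) of kept pixels with
#' identical land-use class are defined as individual fields; component ids
#' are assigned in row-major order of each field's first pixel. Adjacent
#' fields of the same land use that remain connected after masking cannot
#' be distinguished, by construction.
#'
#' @param landuse integer class matrix.
#' @param mask logical keep-mask (e.g. from [mask_mixed_pixels()]); `NULL`
#'   keeps every valid pixel.
#' @param res pixel size, m.
#' @param connectivity 4 (default) or 8.
#' @return a `field_map`: label matrix (`labels`, 0 = no field) and a
#'   `fields` tibble (id, code, n_pixels, area_m2, centroid_row/col).
#' @export
segment_fields <- function(landuse, mask = NULL, res = 1, connectivity = 4) {
  if (is.null(mask)) mask <- !is.na(landuse)
  check_congruent(landuse, mask, "landuse", "mask")
  code <- landuse
  code[!mask] <- NA_integer_
  storage.mode(code) <- "integer"
  labels <- cpp_label_components(code, as.integer(connectivity))
  new_field_map(labels, code, res)
}

new_field_map <- function(labels, code, res) {
  lab_v <- as.vector(labels)
  nlab <- max(lab_v, 0L)
  if (nlab == 0L) {
    fields <- tibble(id = integer(), code = integer(), n_pixels = integer(),
                     area_m2 = numeric(), centroid_row = numeric(),
                     centroid_col = numeric())
  } else {
    inside <- lab_v > 0L
    n_px <- tabulate(lab_v[inside], nbins = nlab)
    first_idx <- match(seq_len(nlab), lab_v)
    rows_v <- as.vector(row(labels))[inside]
    cols_v <- as.vector(col(labels))[inside]
    lv <- lab_v[inside]
    fields <- tibble(
      id = seq_len(nlab),
      code = as.integer(code[first_idx]),
      n_pixels = as.integer(n_px),
      area_m2 = n_px * res^2,
      centroid_row = rowsum(rows_v, lv)[, 1] / n_px,
      centroid_col = rowsum(cols_v, lv)[, 1] / n_px
    )
  }
  structure(list(labels = labels, fields = fields, res = res),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %d x %d px @ %g m, %d fields\n",
              nrow(x$labels), ncol(x$labels), x$res, nrow(x$fields)))
  if (nrow(x$fields) > 0) {
    cat(sprintf("  areas: median %.0f m2, mean %.2f ha, max %.2f ha\n",
                median(x$fields$area_m2), mean(x$fields$area_m2) / 1e4,
                max(x$fields$area_m2) / 1e4))
  }
  invisible(x)
}

#' Use the generator's true field mosaic as a field map
#'
#' @param truth a `scene_truth`.
#' @param arable_only drop forest/bare reference patches (default `TRUE`;
#'   they carry label 0 already).
#' @return a `field_map` on the true field labels.
#' @export
as_field_map <- function(truth, arable_only = TRUE) {
  stopifnot(inherits(truth, "scene_truth"))
  code <- truth$landuse
  code[truth$field_labels == 0L] <- NA_integer_
  fm <- new_field_map(truth$field_labels, code, truth$res)
  fm
}

#' Filter fields by area
#'
#' Removes fields with area less than or equal to the threshold, the rule
#' used to keep only fields with enough pixels for within-field statistics.
#' `threshold = "median"` uses the median field area of the input, so half
#' the entities (but typically only a small share of the area) are dropped.
#'
#' @param fm a `field_map`.
#' @param threshold area in m^2, or `"median"`.
#' @return the filtered `field_map`; `$size_filter` reports the threshold,
#'   counts and the percentage of area removed (kept + removed = 100).
#' @export
filter_fields_by_size <- function(fm, threshold = "median") {
  stopifnot(inherits(fm, "field_map"))
  if (identical(threshold, "median")) {
    thr <- median(fm$fields$area_m2)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
      abort("threshold must be a non-negative area or \"median\"",
            class = "laihet_parameter_error")
    }
    thr <- threshold
  }
  drop <- fm$fields$area_m2 <= thr
  total <- sum(fm$fields$area_m2)
  removed_area <- sum(fm$fields$area_m2[drop])
  out <- fm
  out$fields <- fm$fields[!drop, , drop = FALSE]
  if (any(drop)) {
    out$labels[fm$labels %in% fm$fields$id[drop]] <- 0L
  }
  out$size_filter <- tibble(
    threshold_m2 = thr,
    n_removed = sum(drop),
    n_kept = sum(!drop),
    pct_area_removed = if (total > 0) 100 * removed_area / total else 0,
    pct_area_kept = 100 - (if (total > 0) 100 * removed_area / total else 0)
  )
  out
}

#' Crop calendar of plausibility windows
#'
#' Per crop code, date windows with a maximum plausible LAI; LAI above the
#' window maximum contradicts the assigned land use (weeds, catch crops or
#' misclassification) and is excluded from per-crop analyses. The default
#' built from a crop table allows at most `pre_emergence_max` (0.3) LAI
#' before each crop's emergence day.
#'
#' @param windows tibble with columns `code`, `start_day`, `end_day`,
#'   `max_lai`; windows must not overlap within a crop.
#' @return a `crop_calendar`.
#' @export
crop_calendar <- function(windows) {
  w <- as_tibble(windows)
  stopifnot(all(c("code", "start_day", "end_day", "max_lai") %in% names(w)))
  if (any(w$max_lai < 0)) abort("max_lai must be >= 0", class = "laihet_config_error")
  if (any(w$end_day < w$start_day)) {
    abort("windows need start_day <= end_day", class = "laihet_config_error")
  }
  overlap <- w %>%
    arrange(.data$code, .data$start_day) %>%
    group_by(.data$code) %>%
    summarise(bad = any(head(.data$end_day, -1) >= tail(.data$start_day, -1) &
                          n() > 1), .groups = "drop")
  if (any(overlap$bad)) {
    abort("plausibility windows overlap within a crop", class = "laihet_config_error")
  }
  structure(list(windows = w), class = "crop_calendar")
}

#' @rdname crop_calendar
#' @param crops crop table as in [default_crops()].
#' @param pre_emergence_max maximum plausible LAI before emergence.
#' @export
default_crop_calendar <- function(crops = default_crops(), pre_emergence_max = 0.3) {
  crop_calendar(tibble(
    code = crops$code,
    start_day = 1,
    end_day = pmax(crops$emergence - 1, 1),
    max_lai = pre_emergence_max
  ))
}

#' Flag pixels whose LAI contradicts their assigned land use
#'
#' A pixel is implausible iff its crop has a calendar window covering `day`
#' and the pixel's LAI exceeds that window's maximum; a date with no window
#' imposes no constraint. The resulting mask applies to per-crop analyses
#' only — overall-arable-area statistics deliberately ignore it.
#'
#' @param lai LAI matrix.
#' @param landuse congruent class matrix.
#' @param calendar a [crop_calendar()].
#' @param day day of year.
#' @param codes crop codes the filter applies to (default: the calendar's
#'   codes). A requested code missing from the calendar is a configuration
#'   error.
#' @return logical keep-mask (TRUE = plausible).
#' @export
plausibility_filter <- function(lai, landuse, calendar, day, codes = NULL) {
  stopifnot(inherits(calendar, "crop_calendar"))
  check_congruent(lai, landuse, "lai", "landuse")
  w <- calendar$windows
  if (is.null(codes)) codes <- unique(w$code)
  missing_codes <- setdiff(codes, w$code)
  if (length(missing_codes) > 0) {
    abort(sprintf("crop code(s) %s absent from the calendar",
                  paste(missing_codes, collapse = ", ")),
          class = "laihet_config_error")
  }
  keep <- matrix(TRUE, nrow(lai), ncol(lai))
  act <- w[w$start_day <= day & day <= w$end_day & w$code %in% codes, , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    bad <- !is.na(landuse) & landuse == act$code[i] &
      !is.na(lai) & lai > act$max_lai[i]
    keep[bad] <- FALSE
  }
  keep
}
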