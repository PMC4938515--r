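# population standard deviation (rasters are full populations, not samples)
pop_sd <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0) return(NA_real_)
  sqrt(max(sum((v - mean(v))^2) / n, 0))
}

#' Per-field mean and standard deviation of LAI
#'
#' Arithmetic mean and population SD of the valid pixels of every field.
#' Fields whose pixels are all nodata are flagged `missing` (absence is not
#' zero).
#'
#' @param lai LAI matrix.
#' @param fm a `field_map` on the same grid.
#' @return tibble: `id`, `code`, `n_pixels`, `n_valid`, `mean`, `sd`,
#'   `missing`.
#' @export
field_aggregates <- function(lai, fm) {
  stopifnot(inherits(fm, "field_map"))
  check_congruent(lai, fm$labels, "lai", "field labels")
  lab <- as.vector(fm$labels)
  val <- as.vector(lai)
  use <- lab > 0L & !is.na(val)
  nlab <- nrow(fm$fields)
  if (nlab == 0) {
    return(tibble(id = integer(), code = integer(), n_pixels = integer(),
                  n_valid = integer(), mean = numeric(), sd = numeric(),
                  missing = logical()))
  }
  ids <- fm$fields$id
  n_valid <- s1 <- s2 <- rep(0, max(ids))
  if (any(use)) {
    lv <- lab[use]; vv <- val[use]
    tb <- tabulate(lv, nbins = max(ids))
    n_valid <- tb
    s1[sort(unique(lv))] <- rowsum(vv, lv)[, 1]
    s2[sort(unique(lv))] <- rowsum(vv^2, lv)[, 1]
  }
  nv <- n_valid[ids]
  mu <- ifelse(nv > 0, s1[ids] / nv, NA_real_)
  va <- ifelse(nv > 0, pmax(s2[ids] / nv - mu^2, 0), NA_real_)
  tibble(
    id = ids,
    code = fm$fields$code,
    n_pixels = fm$fields$n_pixels,
    n_valid = as.integer(nv),
    mean = mu,
    sd = sqrt(va),
    missing = nv == 0
  )
}

#' Per-crop pixel statistics
#'
#' Mean, population SD and valid-pixel count of the LAI pixels of each
#' requested land-use code.
#'
#' @param lai LAI matrix.
#' @param landuse congruent class matrix.
#' @param codes land-use codes to summarise.
#' @return tibble: `code`, `mean`, `sd`, `n`.
#' @export
crop_pixel_stats <- function(lai, landuse, codes) {
  check_congruent(lai, landuse, "lai", "landuse")
  purrr::map_dfr(codes, function(cl) {
    v <- lai[!is.na(landuse) & landuse == cl]
    v <- v[!is.na(v)]
    tibble(code = cl, mean = if (length(v)) mean(v) else NA_real_,
           sd = pop_sd(v), n = length(v))
  })
}

#' Overall mean and SD from crop-wise statistics
#'
#' Combines per-crop means and SDs with abundance weights into overall
#' statistics. The default (`mode = "total"`, law of total variance) pools
#' the within-crop variances *and* the squared deviations of the crop means
#' from the overall mean — the between-crop contrast is what makes the
#' overall SD of a multi-crop landscape exceed every single-crop SD.
#' `mode = "within"` pools within-crop variances only.
#'
#' @param stats tibble with columns `mean`, `sd` and `weight` (abundance
#'   weights from the original classification, summing to 1).
#' @param mode `"total"` (default) or `"within"`.
#' @return one-row tibble: `mean`, `sd`.
#' @export
overall_stats <- function(stats, mode = c("total", "within")) {
  mode <- match.arg(mode)
  stopifnot(all(c("mean", "sd", "weight") %in% names(stats)))
  w <- stats$weight
  if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
    abort(sprintf("weights must be >= 0 and sum to 1 (got %.8f)", sum(w)),
          class = "laihet_normalization_error")
  }
  m <- sum(w * stats$mean)
  v <- if (mode == "total") {
    sum(w * (stats$sd^2 + (stats$mean - m)^2))
  } else {
    sum(w * stats$sd^2)
  }
  tibble(mean = m, sd = sqrt(v))
}

#' Build a relative frequency distribution of LAI values
#'
#' Histogram on half-open classes `[c*w, (c+1)*w)` anchored at zero,
#' normalised to sum to 1. A value exactly on a class edge belongs to the
#' upper class.
#'
#' @param values numeric LAI values (>= 0; `NA` dropped).
#' @param w class width in LAI units (default 0.1, below which accordance
#'   values are stable).
#' @return an `lai_rfd`: tibble (`bin`, `lower`, `frequency`) with the class
#'   width as attribute `"width"`.
#' @export
build_rfd <- function(values, w = 0.1) {
  if (!is.numeric(w) || length(w) != 1 || w <= 0) {
    abort("class width must be a single positive number", class = "laihet_parameter_error")
  }
  v <- values[!is.na(values)]
  if (length(v) == 0) abort("no values to bin", class = "laihet_parameter_error")
  if (any(v < 0)) abort("LAI values must be >= 0 (classes are anchored at 0)",
                        class = "laihet_parameter_error")
  bin <- floor(v / w + 1e-9)
  freq <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  new_rfd(tibble(bin = 0:max(bin), lower = (0:max(bin)) * w,
                 frequency = freq / length(v)), w)
}

new_rfd <- function(tbl, w) {
  structure(tbl, width = w, class = c("lai_rfd", class(tibble())))
}

rfd_width <- function(x) attr(x, "width", exact = TRUE)

check_rfd_compatible <- function(a, b) {
  if (!isTRUE(all.equal(rfd_width(a), rfd_width(b), tolerance = 1e-12))) {
    abort(sprintf("incompatible class widths: %g vs %g", rfd_width(a), rfd_width(b)),
          class = "laihet_incompatibility_error")
  }
  invisible(TRUE)
}

#' Abundance-weighted combination of per-crop RFDs
#'
#' Binwise convex combination of relative frequency distributions with
#' abundance weights; used to undo the bias that mixed-pixel removal
#' introduces into the crop shares of the overall arable area. Weights are
#' normalised to sum to 1.
#'
#' @param rfds list of `lai_rfd` objects with identical class width.
#' @param weights non-negative abundance weights, one per RFD.
#' @return the combined `lai_rfd`.
#' @export
weighted_rfd <- function(rfds, weights) {
  stopifnot(length(rfds) == length(weights), length(rfds) >= 1)
  for (r in rfds[-1]) check_rfd_compatible(rfds[[1]], r)
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be >= 0 with positive sum", class = "laihet_parameter_error")
  }
  w <- weights / sum(weights)
  width <- rfd_width(rfds[[1]])
  kmax <- max(vapply(rfds, function(r) max(r$bin), numeric(1)))
  freq <- rep(0, kmax + 1)
  for (i in seq_along(rfds)) {
    freq[rfds[[i]]$bin + 1L] <- freq[rfds[[i]]$bin + 1L] + w[i] * rfds[[i]]$frequency
  }
  new_rfd(tibble(bin = 0:kmax, lower = (0:kmax) * width, frequency = freq), width)
}

#' Accordance of two relative frequency distributions
#'
#' Histogram overlap `sum_c min(Da_c, Db_c)` over the union of occupied
#' classes: the fraction of values that fall in the same class. Equals one
#' minus the total-variation distance, is symmetric, and lies in `[0, 1]`
#' (1 for identical distributions, 0 for disjoint supports).
#'
#' @param a,b `lai_rfd` objects with identical class width and aligned bins.
#' @return accordance, a unitless scalar in `[0, 1]`.
#' @export
accordance <- function(a, b) {
  check_rfd_compatible(a, b)
  kmax <- max(max(a$bin), max(b$bin))
  fa <- fb <- rep(0, kmax + 1)
  fa[a$bin + 1L] <- a$frequency
  fb[b$bin + 1L] <- b$frequency
  sum(pmin(fa, fb))
}

#' Normal-distribution comparator RFD
#'
#' The relative frequency distribution a normal distribution with the given
#' mean and SD would produce on the same class grid: class probabilities
#' from CDF differences, with all mass below the first class edge (including
#' negative values, which empirical LAI cannot take) folded into the first
#' class, renormalised to 1. Used to test whether mean and SD alone
#' describe an empirical LAI distribution.
#'
#' @param mean,sd normal parameters (`sd > 0`).
#' @param w class width.
#' @return an `lai_rfd`.
#' @export
normal_reference_rfd <- function(mean, sd, w = 0.1) {
  if (!is.numeric(sd) || sd <= 0) {
    abort("sd must be > 0", class = "laihet_parameter_error")
  }
  kmax <- max(ceiling((mean + 8 * sd) / w), 1)
  upper <- (1:(kmax + 1)) * w
  p <- pnorm(upper, mean, sd) - pnorm(upper - w, mean, sd)
  p[1] <- pnorm(w, mean, sd)  # fold mass below the first edge into class 0
  p <- p / sum(p)
  new_rfd(tibble(bin = 0:kmax, lower = (0:kmax) * w, frequency = p), w)
}
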