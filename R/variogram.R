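#' Randomly subsample raster pixels as points
#'
#' Uniform selection without replacement of `round(fraction * n_valid)`
#' valid pixels; pixel centres become point coordinates. At 5 m resolution a
#' fraction of 0.5% keeps variogram computation tractable while repeated
#' draws change per-lag semivariances by only a few percent.
#'
#' @param lai LAI matrix.
#' @param fraction fraction of valid pixels in `(0, 1]`.
#' @param seed RNG seed for the draw.
#' @param res pixel size, m.
#' @return tibble: `x`, `y` (m), `value`.
#' @export
subsample_points <- function(lai, fraction, seed, res = 1) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]", class = "laihet_parameter_error")
  }
  valid <- which(!is.na(lai))
  m <- round(fraction * length(valid))
  set.seed(seed)
  take <- if (m >= length(valid)) valid else sort(sample(valid, m))
  nr <- nrow(lai)
  rr <- (take - 1L) %% nr + 1L
  cc <- (take - 1L) %/% nr + 1L
  tibble(x = (cc - 0.5) * res, y = (rr - 0.5) * res, value = lai[take])
}

#' Empirical semivariogram (Matheron estimator)
#'
#' `gamma(h) = (1 / 2N(h)) * sum (z_i - z_j)^2` over point pairs binned by
#' Euclidean distance into half-open classes `[k*w, (k+1)*w)` up to the
#' maximum lag.
#'
#' @param points tibble with `x`, `y`, `value` (e.g. from
#'   [subsample_points()]).
#' @param lag_width lag class width, m (200 m in the reference analysis).
#' @param max_lag maximum lag, m.
#' @return an `empirical_variogram`: tibble (`lag` = bin centre, `gamma`,
#'   `n_pairs`) with `lag_width` and `max_lag` attributes; empty bins are
#'   dropped.
#' @export
empirical_variogram <- function(points, lag_width = 200, max_lag = 25000) {
  stopifnot(all(c("x", "y", "value") %in% names(points)))
  pts <- points[!is.na(points$value), , drop = FALSE]
  if (nrow(pts) < 2) {
    abort("need at least 2 points", class = "laihet_estimation_error")
  }
  acc <- cpp_variogram_bins(pts$x, pts$y, pts$value, lag_width, max_lag)
  nb <- length(acc$ss)
  out <- tibble(
    lag = (seq_len(nb) - 0.5) * lag_width,
    gamma = ifelse(acc$n > 0, acc$ss / (2 * acc$n), NA_real_),
    n_pairs = acc$n
  )
  out <- out[out$n_pairs > 0, , drop = FALSE]
  structure(out, lag_width = lag_width, max_lag = max_lag,
            class = c("empirical_variogram", class(tibble())))
}

#' Stability of the subsampled semivariogram
#'
#' Computes the empirical variogram for `reps` independent subsamples and
#' returns the maximum over lags and repetitions of the relative deviation
#' `|gamma_r(h) - mean_gamma(h)| / mean_gamma(h)`, ignoring lags with zero
#' mean semivariance or fewer than `pair_floor` pairs in any repetition. A
#' constant raster has zero semivariance everywhere; the deviation is then
#' undefined and reported as 0 with a warning.
#'
#' @inheritParams subsample_points
#' @inheritParams empirical_variogram
#' @param reps number of repetitions (>= 2).
#' @param pair_floor minimum pair count per lag for inclusion.
#' @return maximum relative per-lag deviation (unitless).
#' @export
subsample_stability <- function(lai, fraction, reps = 10, seed = 1, res = 1,
                                lag_width = 200, max_lag = 25000,
                                pair_floor = 30) {
  if (!is.numeric(reps) || reps < 2) {
    abort("reps must be >= 2", class = "laihet_parameter_error")
  }
  evs <- purrr::map(seq_len(reps), function(r) {
    pts <- subsample_points(lai, fraction, seed = seed + r - 1, res = res)
    empirical_variogram(pts, lag_width, max_lag)
  })
  lags <- sort(unique(unlist(purrr::map(evs, "lag"))))
  gm <- vapply(evs, function(ev) ev$gamma[match(lags, ev$lag)], numeric(length(lags)))
  np <- vapply(evs, function(ev) ev$n_pairs[match(lags, ev$lag)], numeric(length(lags)))
  gm <- matrix(gm, nrow = length(lags))
  np <- matrix(np, nrow = length(lags))
  ok <- rowSums(is.na(gm)) == 0 & apply(np, 1, min) >= pair_floor
  gbar <- rowMeans(gm)
  ok <- ok & gbar > 0
  if (!any(ok)) {
    warning("all lag classes degenerate (zero semivariance or too few pairs); returning 0")
    return(0)
  }
  max(abs(gm[ok, , drop = FALSE] - gbar[ok]) / gbar[ok])
}

#' Rebalance crop abundances by random removal
#'
#' Mixed-pixel removal changes the relative crop abundances; before
#' variogram analysis of the overall arable area they are restored to the
#' shares of the original classification by randomly removing entities
#' (pixels or fields) of over-represented classes only. The largest subset
#' achieving the target proportions (to within one entity per class) is
#' kept.
#'
#' @param entities tibble with a `code` column (plus any other columns,
#'   e.g. coordinates and values).
#' @param targets named numeric vector of target proportions (names =
#'   codes); entities of codes absent from `targets` are dropped.
#' @param seed RNG seed for the random removals.
#' @return the rebalanced subset of `entities`.
#' @export
rebalance_abundance <- function(entities, targets, seed = 1) {
  stopifnot("code" %in% names(entities))
  targets <- targets / sum(targets)
  codes <- names(targets)
  n_c <- vapply(codes, function(cl) sum(entities$code == cl, na.rm = TRUE),
                numeric(1))
  if (any(n_c == 0)) {
    abort(sprintf("target class(es) absent from input: %s",
                  paste(codes[n_c == 0], collapse = ", ")),
          class = "laihet_feasibility_error")
  }
  total <- floor(min(n_c / targets))
  keep_n <- pmin(round(targets * total), n_c)
  set.seed(seed)
  keep_idx <- unlist(purrr::map(seq_along(codes), function(i) {
    idx <- which(entities$code == codes[i])
    if (length(idx) > keep_n[i]) sort(sample(idx, keep_n[i])) else idx
  }))
  entities[sort(keep_idx), , drop = FALSE]
}
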