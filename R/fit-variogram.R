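# model value of a (possibly nested) exponential variogram
vgm_value <- function(h, nugget, sills, ranges) {
  g <- rep(nugget, length(h))
  for (i in seq_along(sills)) {
    g <- g + sills[i] * (1 - exp(-h / ranges[i]))
  }
  g
}

new_variogram_model <- function(nugget = NA_real_, sills = numeric(),
                                ranges = numeric(), ladder_step = NA_integer_,
                                cutoff = FALSE, weighting = NA_character_,
                                converged = FALSE, rel_rmse = NA_real_,
                                degenerate = FALSE, ev = NULL) {
  ord <- order(ranges)
  structure(list(
    nugget = nugget,
    components = tibble(sill = sills[ord], range_par = ranges[ord]),
    ladder_step = ladder_step, cutoff = cutoff, weighting = weighting,
    converged = converged, rel_rmse = rel_rmse, degenerate = degenerate,
    ev = ev
  ), class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  if (!x$converged) {
    cat("<variogram_model> fit failure (no ladder step converged)\n")
    return(invisible(x))
  }
  cat(sprintf("<variogram_model> nugget %.4g + %d exponential component(s) [ladder step %d, %s weights%s]\n",
              x$nugget, nrow(x$components), x$ladder_step, x$weighting,
              if (x$cutoff) ", 6 km cut-off" else ""))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  sill %.4g, range parameter %.1f m (effective %.0f m)\n",
                x$components$sill[i], x$components$range_par[i],
                3 * x$components$range_par[i]))
  }
  cat(sprintf("  transition-zone relative RMSE: %.3f%s\n", x$rel_rmse,
              if (x$degenerate) " (degenerate: no resolvable sill)" else ""))
  invisible(x)
}

#' @export
predict.variogram_model <- function(object, h, ...) {
  if (!object$converged) return(rep(NA_real_, length(h)))
  vgm_value(h, object$nugget, object$components$sill, object$components$range_par)
}

# one Levenberg-Marquardt attempt; returns a variogram_model or NULL
try_vgm_fit <- function(ev, start, weighting, nested, fix_nugget) {
  w <- if (weighting == "npairs") ev$n_pairs else ev$n_pairs / ev$lag^2
  if (fix_nugget) start$c0 <- NULL
  if (!nested) { start$c2 <- NULL; start$a2 <- NULL }
  p0 <- unlist(start)
  lower <- ifelse(grepl("^a", names(p0)), 1, 0)
  # ranges far beyond the observed lags are not identifiable from the data
  upper <- ifelse(grepl("^a", names(p0)), 3 * max(ev$lag), 100 * max(ev$gamma))
  sw <- sqrt(w)
  resid_fun <- function(p) {
    g <- if ("c0" %in% names(p0)) p[["c0"]] else 0
    g <- g + p[["c1"]] * (1 - exp(-ev$lag / p[["a1"]]))
    if (nested) g <- g + p[["c2"]] * (1 - exp(-ev$lag / p[["a2"]]))
    sw * (g - ev$gamma)
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
  cf <- fit$par
  if (any(!is.finite(cf))) return(NULL)
  nugget <- if (fix_nugget) 0 else unname(cf["c0"])
  sills <- unname(cf[grepl("^c[12]$", names(cf))])
  ranges <- unname(cf[grepl("^a[12]$", names(cf))])
  m <- new_variogram_model(nugget, sills, ranges, converged = TRUE,
                           weighting = weighting, ev = ev)
  m$wsse <- sum(w * (predict(m, ev$lag) - ev$gamma)^2)
  m
}

# components whose sill is a numerically negligible share of the total
# variance (nugget + sills)
live_components <- function(model, sill_tol = 1e-4) {
  nug <- if (is.finite(model$nugget)) model$nugget else 0
  tot <- nug + sum(model$components$sill)
  model$components$sill > max(sill_tol * tot, 1e-12)
}

# relative RMSE over the transition zone (50%-150% of the shortest effective
# range); falls back to the 5 lags nearest the zone centre when empty
transition_rmse <- function(model) {
  ev <- model$ev
  live <- live_components(model)
  if (!any(live)) {
    pred <- predict(model, ev$lag)
    mg <- mean(ev$gamma)
    return(list(rmse = if (mg > 0) sqrt(mean((pred - ev$gamma)^2)) / mg else 0,
                degenerate = TRUE))
  }
  eff <- 3 * min(model$components$range_par[live])
  zone <- ev$lag >= 0.5 * eff & ev$lag <= 1.5 * eff
  if (!any(zone)) {
    zone <- rank(abs(ev$lag - eff), ties.method = "first") <= 5
  }
  pred <- predict(model, ev$lag[zone])
  mg <- mean(ev$gamma[zone])
  list(rmse = if (mg > 0) sqrt(mean((pred - ev$gamma[zone])^2)) / mg else 0,
       degenerate = FALSE)
}

#' Fit a (nested) exponential variogram model with a fallback ladder
#'
#' Attempts, in order: (1) a nested two-exponential model plus nugget with
#' default start values (ranges at 1/10 and 1/2 of the maximum lag, sills
#' split from the empirical plateau); (2) a 3x3 grid of start-value range
#' pairs; (3) the alternative pair weighting: plain `N(h)` instead of the
#' default `N(h)/h^2` (the default of the geostatistics tooling this
#' procedure follows; it emphasises the short-lag rise where the nested
#' decomposition is identified); (4) the nugget fixed at 0; (5) a simple
#' one-exponential model; (6) the empirical variogram cut at 6 km,
#' repeating (1)-(5). Within a step all tested starts compete and the best
#' converged fit (lowest weighted SSE) whose relative RMSE in the
#' transition zone (lags between 50% and 150% of the shortest effective
#' range) is below `rmse_tol` is accepted; semivariograms whose shape
#' defeats every step yield an explicit fit-failure result
#' (`converged = FALSE`), not an error. A flat (pure-nugget) variogram
#' converges with zero-sill components and is flagged `degenerate`.
#'
#' @param ev an [empirical_variogram()].
#' @param rmse_tol transition-zone relative RMSE acceptance threshold.
#' @param cutoff_lag maximum lag of the truncated retry, m.
#' @return a `variogram_model` with fit-ladder metadata (`ladder_step`,
#'   `weighting`, `cutoff`, `rel_rmse`, `converged`, `degenerate`).
#' @export
fit_variogram_ladder <- function(ev, rmse_tol = 0.15, cutoff_lag = 6000) {
  run_ladder <- function(ev, cutoff) {
    max_lag <- max(ev$lag)
    plateau <- mean(ev$gamma[ev$lag >= 0.8 * max_lag])
    if (!is.finite(plateau) || plateau <= 0) plateau <- mean(ev$gamma)
    c0_start <- max(min(ev$gamma) / 2, 0)
    default_start <- list(c0 = c0_start, c1 = plateau / 2, a1 = max_lag / 10,
                          c2 = plateau / 2, a2 = max_lag / 2)
    grid <- expand.grid(a1 = max_lag * c(1 / 50, 1 / 10, 1 / 4),
                        a2 = max_lag * c(1 / 4, 1 / 2, 1))
    grid_starts <- purrr::map(seq_len(nrow(grid)), function(i) {
      list(c0 = c0_start, c1 = plateau / 2, a1 = grid$a1[i],
           c2 = plateau / 2, a2 = grid$a2[i])
    })
    simple_starts <- purrr::map(max_lag * c(1 / 10, 1 / 50, 1 / 4, 1 / 2),
                                function(a) list(c0 = c0_start, c1 = plateau, a1 = a))
    attempts <- c(
      purrr::map(list(default_start), ~ list(step = 1L, start = .x,
                                             weighting = "npairs_h2",
                                             nested = TRUE, fix = FALSE)),
      purrr::map(grid_starts, ~ list(step = 2L, start = .x, weighting = "npairs_h2",
                                     nested = TRUE, fix = FALSE)),
      purrr::map(c(list(default_start), grid_starts),
                 ~ list(step = 3L, start = .x, weighting = "npairs",
                        nested = TRUE, fix = FALSE)),
      purrr::map(c(list(default_start), grid_starts),
                 ~ list(step = 4L, start = .x, weighting = "npairs_h2",
                        nested = TRUE, fix = TRUE)),
      purrr::map(simple_starts, ~ list(step = 5L, start = .x,
                                       weighting = "npairs_h2",
                                       nested = FALSE, fix = FALSE))
    )
    # within a ladder step every tested start is a candidate; the best
    # passing fit (lowest weighted SSE) wins, and only if a whole step
    # yields none does the ladder fall through to the next step
    for (step in sort(unique(vapply(attempts, `[[`, integer(1), "step")))) {
      best <- NULL
      for (at in attempts[vapply(attempts, `[[`, integer(1), "step") == step]) {
        m <- try_vgm_fit(ev, at$start, at$weighting, at$nested, at$fix)
        if (is.null(m)) next
        tz <- transition_rmse(m)
        if (tz$rmse >= rmse_tol) next
        m$ladder_step <- step
        m$cutoff <- cutoff
        m$rel_rmse <- tz$rmse
        # ranges pinned at the 1 m optimisation bound stand in for a
        # nugget: the range is unidentifiable, not a real spatial scale
        live <- live_components(m)
        pinned <- !any(live) || all(m$components$range_par[live] <= 1.5)
        m$degenerate <- tz$degenerate || pinned
        if (is.null(best) || m$wsse < best$wsse) best <- m
      }
      if (!is.null(best)) return(best)
    }
    NULL
  }
  m <- run_ladder(ev, cutoff = FALSE)
  if (is.null(m) && max(ev$lag) > cutoff_lag) {
    ev_cut <- ev[ev$lag <= cutoff_lag, , drop = FALSE]
    attributes(ev_cut)$max_lag <- cutoff_lag
    if (nrow(ev_cut) >= 4) {
      m <- run_ladder(ev_cut, cutoff = TRUE)
      if (!is.null(m)) m$ladder_step <- 6L
    }
  }
  if (is.null(m)) {
    return(new_variogram_model(ev = ev))
  }
  m
}

#' Effective ranges of a fitted variogram model
#'
#' Per exponential component the effective (practical) range is taken as 3
#' times the range parameter, the lag where the component reaches about 95%
#' of its partial sill (the exact 95% point is `a * ln(20) ~ 3a`).
#' Components whose sill is a negligible share of the total sill are
#' dropped; the long range is absent for single-component fits, and both
#' are absent for fit failures. The raw range parameters are reported
#' alongside.
#'
#' @param model a `variogram_model`.
#' @param sill_tol relative sill share below which a component is absent.
#' @return one-row tibble: `short`, `long` (m; `NA` when absent),
#'   `a_short`, `a_long` (raw range parameters), `n_components`.
#' @export
effective_ranges <- function(model, sill_tol = 1e-4) {
  stopifnot(inherits(model, "variogram_model"))
  none <- tibble(short = NA_real_, long = NA_real_,
                 a_short = NA_real_, a_long = NA_real_, n_components = 0L)
  if (!model$converged) return(none)
  live <- model$components[live_components(model, sill_tol), , drop = FALSE]
  if (nrow(live) == 0) return(none)
  a <- sort(live$range_par)
  tibble(
    short = 3 * a[1],
    long = if (length(a) >= 2) 3 * a[length(a)] else NA_real_,
    a_short = a[1],
    a_long = if (length(a) >= 2) a[length(a)] else NA_real_,
    n_components = nrow(live)
  )
}

#' @export
tidy.variogram_model <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = character(), estimate = numeric()))
  }
  bind_rows(
    tibble(term = "nugget", estimate = x$nugget),
    purrr::map_dfr(seq_len(nrow(x$components)), function(i) {
      tibble(term = c(sprintf("sill_%d", i), sprintf("range_par_%d", i)),
             estimate = c(x$components$sill[i], x$components$range_par[i]))
    })
  )
}

#' @export
glance.variogram_model <- function(x, ...) {
  er <- effective_ranges(x)
  tibble(
    converged = x$converged, ladder_step = x$ladder_step,
    weighting = x$weighting, cutoff = x$cutoff, degenerate = x$degenerate,
    rel_rmse = x$rel_rmse,
    nugget = x$nugget,
    short_range = er$short, long_range = er$long,
    n_lags = if (is.null(x$ev)) NA_integer_ else nrow(x$ev)
  )
}
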