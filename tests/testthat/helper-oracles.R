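# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

# neighbourhood-uniformity mask by explicit per-pixel loops
bf_mask_mixed <- function(lu, connectivity = 8) {
  nr <- nrow(lu); nc <- ncol(lu)
  offs <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  keep <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(lu[i, j])) next
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      r <- i + offs[k, 1]; c <- j + offs[k, 2]
      if (r < 1 || r > nr || c < 1 || c > nc ||
          is.na(lu[r, c]) || lu[r, c] != lu[i, j]) { ok <- FALSE; break }
    }
    keep[i, j] <- ok
  }
  keep
}

# recursive-free flood-fill labelling, row-major first-pixel ids
bf_flood_fill <- function(code, connectivity = 4) {
  nr <- nrow(code); nc <- ncol(code)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  nxt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (lab[i, j] != 0L || is.na(code[i, j])) next
    nxt <- nxt + 1L
    frontier <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(frontier) > 0) {
      p <- frontier[[length(frontier)]]
      frontier[[length(frontier)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (lab[r, c] != 0L || is.na(code[r, c])) next
        if (code[r, c] != code[p[1], p[2]]) next
        lab[r, c] <- nxt
        frontier[[length(frontier) + 1L]] <- c(r, c)
      }
    }
  }
  lab
}

# all-pairs Matheron estimator over half-open distance bins
bf_variogram <- function(pts, lag_width, max_lag) {
  n <- nrow(pts)
  nb <- ceiling(max_lag / lag_width)
  ss <- np <- numeric(nb)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
    if (d >= max_lag) next
    b <- floor(d / lag_width) + 1
    if (b > nb) next
    ss[b] <- ss[b] + (pts$value[i] - pts$value[j])^2
    np[b] <- np[b] + 1
  }
  tibble::tibble(lag = (seq_len(nb) - 0.5) * lag_width,
                 gamma = ifelse(np > 0, ss / (2 * np), NA_real_),
                 n_pairs = np)[np > 0, ]
}

# random relative frequency vector on a fixed number of bins
random_rfd <- function(nbins, w = 0.1) {
  f <- stats::runif(nbins)
  f[sample(nbins, sample(nbins - 1, 1))] <- 0  # some empty bins
  if (sum(f) == 0) f[1] <- 1
  laihet:::new_rfd(tibble::tibble(bin = 0:(nbins - 1),
                                  lower = (0:(nbins - 1)) * w,
                                  frequency = f / sum(f)), w)
}

# small scene used by several tests
tiny_scene <- function(seed = 1, rows = 300, cols = 300, res = 5, ...) {
  scene_config(rows = rows, cols = cols, res = res, seed = seed, ...)
}
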