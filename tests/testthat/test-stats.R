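test_that("field aggregates use the population SD and flag missing fields", {
  lab <- matrix(c(1L, 1L, 2L, 2L, 3L, 3L), 2, 3)
  code <- matrix(1L, 2, 3)
  fm <- laihet:::new_field_map(lab, code, res = 5)
  lai <- matrix(c(3, 3, 2, 4, NA, NA), 2, 3)
  fa <- field_aggregates(lai, fm)
  expect_equal(fa$mean[1], 3); expect_equal(fa$sd[1], 0)
  expect_equal(fa$mean[2], 3); expect_equal(fa$sd[2], 1)  # population SD
  expect_true(fa$missing[3]); expect_true(is.na(fa$mean[3]))
  expect_error(field_aggregates(matrix(1, 3, 3), fm),
               class = "laihet_congruence_error")
})

test_that("overall statistics follow the law of total variance", {
  one <- tibble::tibble(mean = 2.5, sd = 0.7, weight = 1)
  expect_equal(overall_stats(one), tibble::tibble(mean = 2.5, sd = 0.7))
  two <- tibble::tibble(mean = c(0, 2), sd = c(0, 0), weight = c(0.5, 0.5))
  expect_equal(overall_stats(two)$sd, 1)  # purely between-group spread
  expect_equal(overall_stats(two, mode = "within")$sd, 0)
  bad <- tibble::tibble(mean = 1, sd = 1, weight = 0.7)
  expect_error(overall_stats(bad), class = "laihet_normalization_error")
})

test_that("pooled statistics equal brute-force concatenated statistics", {
  set.seed(33)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(g) rnorm(sample(20:200, 1), rnorm(1, 3), runif(1, 0.1, 2)))
    all_v <- unlist(groups)
    st <- tibble::tibble(
      mean = vapply(groups, mean, numeric(1)),
      sd = vapply(groups, laihet:::pop_sd, numeric(1)),
      weight = vapply(groups, length, numeric(1)) / length(all_v)
    )
    ov <- overall_stats(st)
    expect_equal(ov$mean, mean(all_v), tolerance = 1e-9)
    expect_equal(ov$sd, laihet:::pop_sd(all_v), tolerance = 1e-9)
  }
})

test_that("RFD binning uses half-open classes anchored at zero", {
  r1 <- build_rfd(rep(0.55, 10), w = 0.1)
  expect_equal(sum(r1$frequency), 1)
  expect_equal(r1$frequency[r1$bin == 5], 1)
  r2 <- build_rfd(c(0.05, 0.15, 0.15, 0.25), w = 0.1)
  expect_equal(r2$frequency, c(0.25, 0.5, 0.25))
  # a value exactly on a class edge belongs to the upper class
  r3 <- build_rfd(c(0.1), w = 0.1)
  expect_equal(r3$frequency[r3$bin == 1], 1)
  expect_error(build_rfd(numeric(0)), class = "laihet_parameter_error")
  expect_error(build_rfd(1, w = 0), class = "laihet_parameter_error")
  expect_error(build_rfd(c(1, -0.2)), class = "laihet_parameter_error")
})

test_that("weighted RFD combination is a convex binwise mixture", {
  a <- build_rfd(c(0.05, 0.15), w = 0.1)
  same <- weighted_rfd(list(a, a), c(0.3, 0.7))
  expect_equal(same$frequency, a$frequency)
  # two disjoint single-class RFDs combine into their weights
  d1 <- build_rfd(rep(0.05, 5), 0.1); d2 <- build_rfd(rep(0.35, 5), 0.1)
  mix <- weighted_rfd(list(d1, d2), c(0.41, 0.59))
  expect_equal(mix$frequency[mix$bin == 0], 0.41)
  expect_equal(mix$frequency[mix$bin == 3], 0.59)
  expect_equal(sum(mix$frequency), 1)
  first <- weighted_rfd(list(d1, d2), c(1, 0))  # bins extend over the union
  expect_equal(first$frequency[first$bin == 0], 1)
  expect_equal(sum(first$frequency), 1)
  wrong_w <- build_rfd(c(0.05), w = 0.2)
  expect_error(weighted_rfd(list(d1, wrong_w), c(0.5, 0.5)),
               class = "laihet_incompatibility_error")
})

test_that("accordance is the histogram overlap", {
  a <- build_rfd(c(0.05, 0.15), 0.1)
  expect_equal(accordance(a, a), 1)
  d1 <- build_rfd(rep(0.05, 3), 0.1); d2 <- build_rfd(rep(0.95, 3), 0.1)
  expect_equal(accordance(d1, d2), 0)
  ha <- laihet:::new_rfd(tibble::tibble(bin = 0:2, lower = (0:2) * 0.1,
                                        frequency = c(0.5, 0.5, 0)), 0.1)
  hb <- laihet:::new_rfd(tibble::tibble(bin = 0:2, lower = (0:2) * 0.1,
                                        frequency = c(0.25, 0.25, 0.5)), 0.1)
  expect_equal(accordance(ha, hb), 0.5)
  expect_error(accordance(a, build_rfd(0.3, w = 0.2)),
               class = "laihet_incompatibility_error")
})

test_that("accordance is symmetric, bounded, and 1 minus total variation", {
  set.seed(55)
  for (i in 1:200) {
    a <- random_rfd(sample(3:30, 1))
    b <- random_rfd(sample(3:30, 1))
    acc <- accordance(a, b)
    expect_equal(acc, accordance(b, a))
    expect_gte(acc, 0); expect_lte(acc, 1)
    k <- max(max(a$bin), max(b$bin))
    fa <- fb <- rep(0, k + 1)
    fa[a$bin + 1] <- a$frequency; fb[b$bin + 1] <- b$frequency
    expect_equal(acc, 1 - sum(abs(fa - fb)) / 2, tolerance = 1e-12)
  }
})

test_that("refining classes never increases accordance", {
  split_rfd <- function(r, parts) {
    w <- attr(r, "width") / parts
    f <- rep(r$frequency / parts, each = parts)
    laihet:::new_rfd(tibble::tibble(bin = seq_along(f) - 1,
                                    lower = (seq_along(f) - 1) * w,
                                    frequency = f), w)
  }
  set.seed(66)
  for (i in 1:50) {
    a <- random_rfd(sample(3:15, 1)); b <- random_rfd(sample(3:15, 1))
    coarse <- accordance(a, b)
    fine <- accordance(split_rfd(a, 2), split_rfd(b, 2))
    expect_lte(fine, coarse + 1e-12)
  }
})

test_that("the normal comparator folds sub-zero mass and is symmetric about the mean", {
  r <- normal_reference_rfd(2, 0.5, 0.1)
  expect_equal(sum(r$frequency), 1, tolerance = 1e-12)
  f <- function(x) r$frequency[r$bin == floor(round(x / 0.1, 9))]
  for (d in c(0.3, 0.7, 1.1)) {
    expect_equal(f(2 + d), f(2 - d - 0.1), tolerance = 1e-6)
  }
  expect_equal(accordance(r, r), 1)
  # near-degenerate SD concentrates all mass in the mean's class
  r0 <- normal_reference_rfd(2.05, 1e-6, 0.1)
  expect_equal(r0$frequency[r0$bin == 20], 1, tolerance = 1e-9)
  # sub-zero mass lands in the first class
  rneg <- normal_reference_rfd(0.05, 1, 0.1)
  expect_gt(rneg$frequency[1], pnorm(0, 0.05, 1) - 0.01)
  expect_error(normal_reference_rfd(2, 0), class = "laihet_parameter_error")
})

test_that("crop pixel statistics summarise only the requested codes", {
  lu <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  lai <- matrix(c(1, 3, 5, NA), 2, 2)
  st <- crop_pixel_stats(lai, lu, c(1L, 2L))
  expect_equal(st$mean, c(2, 5))
  expect_equal(st$sd, c(1, 0))
  expect_equal(st$n, c(2L, 1L))
})

test_that("inter-field-dominated scenes: field means carry nearly all variability", {
  # inter-field SD 1.0 vs pixel noise SD 0.2: the field-mean distribution
  # (true mosaic) overlaps the pixel distribution closely and retains
  # almost the whole overall SD
  cfg <- scene_config(rows = 500, cols = 500, res = 5, prop_forest = 0,
                      prop_bare = 0, sd_field = 1, sd_pixel = 0.2,
                      lr_sill = 0, seed = 19)
  tr <- generate_mosaic(cfg)
  lai <- simulate_lai(tr, 170)
  fa <- field_aggregates(lai, as_field_map(tr))
  ok <- !fa$missing
  pix_v <- lai[tr$field_labels > 0]
  acc <- accordance(build_rfd(pix_v, 0.1),
                    build_rfd(rep(fa$mean[ok], fa$n_valid[ok]), 0.1))
  expect_gt(acc, 0.8)
  sd_fm <- laihet:::pop_sd(rep(fa$mean[ok], fa$n_valid[ok]))
  expect_gt(sd_fm / laihet:::pop_sd(pix_v), 0.95)
})
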