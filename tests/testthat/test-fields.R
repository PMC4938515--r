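test_that("majority upscaling takes the block mode with lowest-code ties", {
  u <- matrix(5L, 4, 4)
  expect_equal(upscale_majority(u, 2), matrix(5L, 2, 2))
  m <- matrix(c(5L, 5L, 5L, 2L), 2, 2)
  expect_equal(upscale_majority(m, 2)[1, 1], 5L)
  tie <- matrix(c(2L, 2L, 5L, 5L), 2, 2)
  expect_equal(upscale_majority(tie, 2)[1, 1], 2L)  # tie -> lowest code
  expect_identical(upscale_majority(m, 1), m)
  expect_error(upscale_majority(m, 0), class = "laihet_parameter_error")
})

test_that("majority upscaling pads odd dimensions with nodata and ignores it", {
  m <- matrix(7L, 3, 3)
  out <- upscale_majority(m, 2)
  expect_equal(dim(out), c(2L, 2L))
  expect_true(all(out == 7L))  # nodata padding never wins
  allna <- matrix(NA_integer_, 2, 2)
  expect_true(all(is.na(upscale_majority(allna, 2))))
})

test_that("mixed-pixel masking keeps only interior pixels of uniform neighbourhoods", {
  u <- matrix(3L, 5, 5)
  keep <- mask_mixed_pixels(u)
  expect_equal(sum(keep), 9)
  expect_true(all(keep[2:4, 2:4]))
  # a single-pixel field inside another class is removed
  m <- matrix(1L, 5, 5); m[3, 3] <- 2L
  expect_false(mask_mixed_pixels(m)[3, 3])
  # two uniform 10x10 blocks sharing an edge lose a 1-pixel strip each side
  b <- cbind(matrix(1L, 10, 10), matrix(2L, 10, 10))
  kb <- mask_mixed_pixels(b)
  expect_false(any(kb[, 10:11]))
  expect_true(all(kb[2:9, 2:9]))
  expect_true(all(kb[2:9, 12:19]))
})

test_that("mixed-pixel mask matches the brute-force neighbourhood check", {
  set.seed(101)
  for (i in 1:25) {
    nr <- sample(5:40, 1); nc <- sample(5:40, 1)
    lu <- matrix(sample(c(1:3, NA), nr * nc, replace = TRUE,
                        prob = c(0.4, 0.3, 0.2, 0.1)), nr, nc)
    for (conn in c(4, 8)) {
      expect_identical(mask_mixed_pixels(lu, conn), bf_mask_mixed(lu, conn))
    }
  }
})

test_that("every kept pixel has a uniform neighbourhood in the original raster", {
  set.seed(7)
  lu <- matrix(sample(1:3, 900, replace = TRUE, prob = c(0.6, 0.3, 0.1)), 30, 30)
  keep <- mask_mixed_pixels(lu)
  for (idx in which(keep)) {
    i <- (idx - 1) %% 30 + 1; j <- (idx - 1) %/% 30 + 1
    nb <- lu[max(1, i - 1):min(30, i + 1), max(1, j - 1):min(30, j + 1)]
    expect_true(i > 1 && i < 30 && j > 1 && j < 30)
    expect_true(all(nb == lu[i, j]))
  }
})

test_that("segmentation separates blocks and keeps L-shapes whole", {
  b <- cbind(matrix(1L, 10, 10), matrix(2L, 10, 10))
  fm <- segment_fields(b, mask_mixed_pixels(b), res = 5)
  expect_equal(nrow(fm$fields), 2)
  expect_equal(sort(fm$fields$code), c(1L, 2L))
  expect_equal(fm$fields$area_m2, fm$fields$n_pixels * 25)

  l <- matrix(NA_integer_, 10, 10)
  l[1:8, 1:3] <- 4L; l[6:8, 1:8] <- 4L
  fm2 <- segment_fields(l, NULL, res = 1)
  expect_equal(nrow(fm2$fields), 1)
  expect_equal(fm2$fields$n_pixels, sum(!is.na(l)))
})

test_that("segmentation labels agree with an independent flood-fill oracle", {
  set.seed(202)
  for (i in 1:20) {
    nr <- sample(8:30, 1); nc <- sample(8:30, 1)
    lu <- matrix(sample(c(1:3, NA), nr * nc, replace = TRUE), nr, nc)
    keep <- mask_mixed_pixels(lu)
    code <- lu; code[!keep] <- NA_integer_
    for (conn in c(4, 8)) {
      fm <- segment_fields(lu, keep, connectivity = conn)
      expect_identical(fm$labels, bf_flood_fill(code, conn))
    }
  }
})

test_that("empty masks give empty field maps", {
  fm <- segment_fields(matrix(1L, 5, 5), matrix(FALSE, 5, 5))
  expect_equal(nrow(fm$fields), 0)
  expect_true(all(fm$labels == 0L))
})

test_that("the size filter applies the inclusive median rule", {
  lab <- matrix(0L, 10, 20)
  lab[1:5, 1:2] <- 1L          # 10 px  = 1000 m2 at 10 m
  lab[1:5, 5:8] <- 2L          # ~22 px -> use explicit sizes below
  code <- lab; code[lab == 0] <- NA_integer_; code[lab > 0] <- 1L
  fm <- laihet:::new_field_map(lab, code, res = 10)
  # construct areas 1000 / 2250 / 9000 m2 via a synthetic field table
  fm$fields$area_m2 <- c(1000, 2250)
  fm$fields <- dplyr::bind_rows(fm$fields,
                                dplyr::mutate(fm$fields[1, ], id = 3L, area_m2 = 9000))
  out <- filter_fields_by_size(fm, "median")
  expect_equal(out$fields$area_m2, 9000)
  expect_equal(out$size_filter$n_removed, 2)
  # threshold 0 keeps every field with positive area
  out0 <- filter_fields_by_size(fm, 0)
  expect_equal(nrow(out0$fields), 3)
  # all-equal areas: the inclusive comparison removes everything
  fm$fields$area_m2 <- rep(2250, 3)
  expect_equal(nrow(filter_fields_by_size(fm, "median")$fields), 0)
  expect_error(filter_fields_by_size(fm, -5), class = "laihet_parameter_error")
})

test_that("size-filter area percentages are conserved exactly", {
  tr <- generate_mosaic(tiny_scene(seed = 13))
  fm <- as_field_map(tr)
  out <- filter_fields_by_size(fm, "median")
  expect_identical(out$size_filter$pct_area_removed + out$size_filter$pct_area_kept,
                   100)
  expect_true(all(out$fields$area_m2 > out$size_filter$threshold_m2))
})

test_that("the plausibility filter excludes impossible LAI for the date", {
  cal <- crop_calendar(tibble::tibble(code = 3L, start_day = 1, end_day = 120,
                                      max_lai = 0.3))
  lu <- matrix(3L, 2, 2)
  lai <- matrix(c(2.0, 0.0, 0.25, NA), 2, 2)
  keep <- plausibility_filter(lai, lu, cal, day = 53)  # late February
  expect_false(keep[1, 1])   # maize with LAI 2 before sowing dates
  expect_true(keep[2, 1])    # LAI 0 is always plausible
  expect_true(keep[1, 2])
  # outside any window there is no constraint
  expect_true(all(plausibility_filter(lai, lu, cal, day = 200)))
  expect_error(plausibility_filter(lai, lu, cal, day = 53, codes = 5L),
               class = "laihet_config_error")
})

test_that("calendar invariants reject overlap and negative maxima", {
  expect_error(crop_calendar(tibble::tibble(code = 1L, start_day = c(1, 50),
                                            end_day = c(60, 90),
                                            max_lai = c(0.3, 0.3))),
               class = "laihet_config_error")
  expect_error(crop_calendar(tibble::tibble(code = 1L, start_day = 1,
                                            end_day = 60, max_lai = -1)),
               class = "laihet_config_error")
  cal <- default_crop_calendar()
  expect_s3_class(cal, "crop_calendar")
  expect_true(all(cal$windows$end_day < default_crops()$emergence))
})
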