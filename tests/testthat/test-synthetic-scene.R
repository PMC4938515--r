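test_that("mosaic generation is deterministic under a fixed seed", {
  cfg <- tiny_scene(seed = 11)
  a <- generate_mosaic(cfg)
  b <- generate_mosaic(cfg)
  expect_identical(a$field_labels, b$field_labels)
  expect_identical(a$landuse, b$landuse)
  expect_identical(a$fields, b$fields)
})

test_that("mean field area tracks the configured log-normal over seeds", {
  means <- vapply(1:10, function(s) {
    tr <- generate_mosaic(scene_config(rows = 600, cols = 600, res = 5,
                                       prop_forest = 0, prop_bare = 0, seed = s))
    mean(tr$fields$area_m2)
  }, numeric(1))
  expect_lt(abs(mean(means) - 20600) / 20600, 0.25)
})

test_that("area-weighted crop shares land near the configured proportions", {
  tr <- generate_mosaic(scene_config(rows = 600, cols = 600, res = 5, seed = 3))
  shares <- tr$fields %>%
    dplyr::group_by(code) %>%
    dplyr::summarise(area = sum(area_m2)) %>%
    dplyr::mutate(share = area / sum(area))
  target <- default_crops()$proportion
  got <- shares$share[match(default_crops()$code, shares$code)]
  expect_true(all(abs(got - target) <= 0.05))
})

test_that("reference patches occupy their configured fractions and stay disjoint", {
  cfg <- tiny_scene(seed = 5, prop_forest = 0.1, prop_bare = 0.05)
  tr <- generate_mosaic(cfg)
  n <- length(tr$landuse)
  expect_equal(sum(tr$landuse == FOREST_CODE, na.rm = TRUE) / n, 0.1, tolerance = 0.01)
  expect_equal(sum(tr$landuse == BARE_CODE, na.rm = TRUE) / n, 0.05, tolerance = 0.01)
  expect_equal(sum(tr$field_labels[tr$landuse %in% c(FOREST_CODE, BARE_CODE)]), 0)
})

test_that("a domain too small for the mean field size is rejected", {
  expect_error(generate_mosaic(scene_config(rows = 30, cols = 30, res = 5, seed = 1)),
               class = "laihet_sizing_error")
})

test_that("every labelled field has exactly one crop code", {
  tr <- generate_mosaic(tiny_scene(seed = 7))
  lab <- as.vector(tr$field_labels); lu <- as.vector(tr$landuse)
  per_field <- tapply(lu[lab > 0], lab[lab > 0], function(v) length(unique(v)))
  expect_true(all(per_field == 1))
})

test_that("deterministic LAI curve hits its anchors", {
  cfg <- tiny_scene(seed = 2, sd_field = 0, sd_pixel = 0, lr_sill = 0)
  tr <- generate_mosaic(cfg)
  # before every emergence: arable LAI identically zero
  lai <- simulate_lai(tr, day = 30)
  expect_true(all(lai[tr$field_labels > 0] == 0))
  # at the wheat day of maximum every wheat pixel equals the wheat maximum
  wheat <- cfg$crops[cfg$crops$crop == "winter_wheat", ]
  lai <- simulate_lai(tr, day = wheat$peak)
  expect_true(all(abs(lai[!is.na(tr$landuse) & tr$landuse == wheat$code] -
                        wheat$max_lai) < 1e-12))
  expect_error(simulate_lai(tr, day = 400), class = "laihet_domain_error")
  expect_error(simulate_lai(tr, day = 0), class = "laihet_domain_error")
})

test_that("simulated LAI is non-negative and deterministic under the scene seed", {
  cfg <- tiny_scene(seed = 9, sd_field = 2)
  tr <- generate_mosaic(cfg)
  a <- simulate_lai(tr, 170)
  b <- simulate_lai(tr, 170)
  expect_identical(a, b)
  expect_true(all(a >= 0))
})

test_that("variance decomposes into inter-field and intra-field parts", {
  cfg <- scene_config(rows = 600, cols = 600, res = 5, prop_forest = 0,
                      prop_bare = 0, sd_field = 1, sd_pixel = 0.2,
                      lr_sill = 0, seed = 21,
                      crops = dplyr::mutate(default_crops(), max_lai = max_lai + 4))
  tr <- generate_mosaic(cfg)
  # mid-season day, curves high enough that the zero-clamp never bites
  cmp <- simulate_lai(tr, 180, components = TRUE)
  lab <- tr$field_labels[tr$field_labels > 0]
  lai <- cmp$lai[tr$field_labels > 0]
  # within one crop the curve is constant, so the field means spread with
  # the inter-field SD alone
  wheat <- tr$landuse[tr$field_labels > 0] == 1L
  fm_means <- tapply(lai[wheat], lab[wheat], mean)
  expect_equal(var(fm_means), 1.0, tolerance = 0.2)
  wi_var <- tapply(lai, lab, function(v) mean((v - mean(v))^2))
  npix <- tabulate(lab)
  expect_equal(mean(wi_var[npix[as.integer(names(wi_var))] > 50]), 0.04,
               tolerance = 0.2)
  # single-crop variance total: curve constant per crop; compare per crop
  one <- tr$landuse[tr$field_labels > 0] == 1L
  expect_equal(var(lai[one]), 1 + 0.04, tolerance = 0.15)
})

test_that("the exponential-covariance random field has the configured variance and decay", {
  set.seed(1)
  ms <- replicate(30, mean(sim_grf_exp(150, 150, 5, sill = 0.7, range_par = 50)^2))
  expect_equal(mean(ms), 0.7, tolerance = 0.05)
  set.seed(3)
  g <- sim_grf_exp(500, 500, 5, 1.0, 50)
  for (l in c(10, 20)) {
    emp <- cor(as.vector(g[, 1:(500 - l)]), as.vector(g[, (l + 1):500]))
    expect_lt(abs(emp - exp(-l * 5 / 50)), 0.03)
  }
})

test_that("forward sensor model matches the closed form and round-trips", {
  cfg <- tiny_scene(seed = 4)
  # LAI = 0 -> NDVI = ndvi_s
  r0 <- forward_ndvi(matrix(0, 2, 2), cfg)
  ndvi0 <- compute_ndvi(r0$nir, r0$red)
  expect_equal(ndvi0, matrix(cfg$ndvi_s, 2, 2), tolerance = 1e-12)
  # LAI = 2, k = 0.54 -> NDVI = 0.15 + (1 - e^-1.08) * 0.75
  r2 <- forward_ndvi(matrix(2, 1, 1), cfg)
  expect_equal(compute_ndvi(r2$nir, r2$red)[1, 1],
               0.15 + (1 - exp(-1.08)) * 0.75, tolerance = 1e-12)
  # noiseless forward then retrieval with true endmembers is the identity
  lai <- matrix(seq(0, 7, length.out = 64), 8, 8)
  refl <- forward_ndvi(lai, cfg)
  em <- list(ndvi_v = cfg$ndvi_v, ndvi_s = cfg$ndvi_s)
  back <- fvc_to_lai(ndvi_to_fvc(compute_ndvi(refl$nir, refl$red), em))
  expect_lt(max(abs(back - lai)), 1e-6)
})

test_that("scene config invariants are enforced", {
  expect_error(scene_config(res = 0), class = "laihet_config_error")
  expect_error(scene_config(sd_field = -1), class = "laihet_config_error")
  expect_error(scene_config(ndvi_v = 0.1, ndvi_s = 0.5), class = "laihet_config_error")
  bad <- default_crops(); bad$emergence[1] <- 300
  expect_error(scene_config(crops = bad), class = "laihet_config_error")
  bad2 <- default_crops(); bad2$proportion <- rep(0.5, 4)
  expect_error(scene_config(crops = bad2), class = "laihet_config_error")
})

test_that("scene configs round-trip through YAML", {
  cfg <- scene_config(rows = 100, cols = 120, sd_field = 0.5, seed = 42)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(rows = 100, cols = 120, sd_field = 0.5, seed = 42), f)
  cfg2 <- read_scene_config(f)
  expect_equal(cfg2$rows, cfg$rows)
  expect_equal(cfg2$sd_field, cfg$sd_field)
  expect_equal(cfg2$seed, cfg$seed)
})
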