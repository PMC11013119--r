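test_that("profile extraction matches closed-form bilinear interpolation", {
  # f(x, y) = column index: any profile is a linear ramp of slope 1/px
  v <- matrix(rep(1:32, each = 32), 32, byrow = FALSE)
  img <- scan_image(v + 0, pixel_size = 5)
  pr <- extract_profile(img, c(4, 3), c(28, 27), n_samples = 49)
  fit <- stats::lm(pr$values ~ pr$positions)
  # along the diagonal the column coordinate grows by 1/sqrt(2) per unit
  # path length (in px), i.e. 1/(5 sqrt(2)) per nm
  expect_equal(unname(stats::coef(fit)[2]), 1 / (5 * sqrt(2)),
               tolerance = 1e-10)
  expect_true(all(diff(pr$positions) > 0))
  # constant image gives a constant profile on any diagonal
  cimg <- scan_image(matrix(7, 32, 32), 1)
  pc <- extract_profile(cimg, c(2, 2), c(30, 19))
  expect_true(all(abs(pc$values - 7) < 1e-12))
  # axis-aligned crossing of a noiseless step takes exactly two values
  sv <- matrix(0, 32, 32); sv[, 17:32] <- 0.33
  ps <- extract_profile(scan_image(sv, 1), c(16, 2), c(16, 31),
                        n_samples = 30)
  expect_setequal(unique(ps$values), c(0, 0.33))
})

test_that("profile endpoints are validated", {
  img <- scan_image(matrix(0, 16, 16), 1)
  expect_error(extract_profile(img, c(0, 5), c(10, 5)),
               class = "validation_error")
  expect_error(extract_profile(img, c(2, 5), c(10, 55)),
               class = "validation_error")
  expect_error(extract_profile(img, c(3, 3), c(3, 3)),
               class = "validation_error")
})

test_that("step_delta recovers noiseless and blurred steps", {
  sv <- matrix(0, 64, 64); sv[, 33:64] <- 0.33
  img <- scan_image(sv, 1)
  pr <- extract_profile(img, c(32, 4), c(32, 61), n_samples = 64)
  expect_equal(step_delta(pr), 0.33)
  # potential step under tip blur: recovered within 1 mV
  pv <- matrix(0, 128, 128); pv[, 65:128] <- 336
  pot <- scan_image(monodomain:::gaussian_blur(pv, 2), 10,
                    channel = "potential")
  prb <- extract_profile(pot, c(64, 25), c(64, 104), n_samples = 80)
  expect_equal(step_delta(prb, exclusion = 0.2), 336, tolerance = 1 / 336)
  # exact affine equivariance: delta(a * v + b) = a * delta(v)
  pr2 <- prb
  pr2$values <- 3.7 * prb$values + 11
  expect_equal(step_delta(pr2), 3.7 * step_delta(prb), tolerance = 1e-12)
})

test_that("profiles without a step are rejected", {
  img <- scan_image(matrix(2, 32, 32), 1)
  pr <- extract_profile(img, c(5, 5), c(25, 25))
  expect_error(step_delta(pr), class = "no_step")
})

test_that("boundary profiles cross the boundary and honour count and seed", {
  gt <- generate_mask(tiny_spec(seed = 13, coverage = 0.25))
  img <- render_pair(gt)$topography
  profs <- sample_boundary_profiles(img, gt$mask, n_profiles = 40,
                                    length = 300, seed = 99, clearance_px = 4)
  expect_length(profs, 40)
  for (p in profs) {
    ends <- round(p$endpoints)
    m0 <- gt$mask[ends[1, 1], ends[1, 2]]
    m1 <- gt$mask[ends[2, 1], ends[2, 2]]
    expect_true(m0 != m1)  # endpoints lie in different phases
  }
  profs2 <- sample_boundary_profiles(img, gt$mask, n_profiles = 40,
                                     length = 300, seed = 99, clearance_px = 4)
  expect_identical(lapply(profs, `[[`, "endpoints"),
                   lapply(profs2, `[[`, "endpoints"))
  expect_error(sample_boundary_profiles(img, gt$mask * 0L),
               class = "validation_error")
})

test_that("contrast aggregation gives t-based confidence margins", {
  exact <- aggregate_contrast(rep(0.33, 100))
  expect_equal(exact$mean_delta, 0.33)
  expect_equal(exact$margin, 0)
  expect_equal(exact$n, 100)
  set.seed(7)
  x <- rnorm(100, 336, 15)
  ag <- aggregate_contrast(x)
  expect_equal(ag$margin, qt(0.975, 99) * sd(x) / 10, tolerance = 1e-12)
  expect_equal(ag$mean_delta, 336, tolerance = 4 / 336)
  expect_equal(aggregate_contrast(x, confidence = 0)$margin, 0)
  expect_error(aggregate_contrast(0.5), class = "validation_error")
  g <- glance(ag)
  expect_equal(g$n, 100)
  expect_equal(nrow(tidy(ag)), 100)
})

test_that("topography and potential contrasts share sign with the truth", {
  spec <- tiny_spec(seed = 17, coverage = 0.25)
  gt <- generate_mask(spec)
  pair <- render_pair(gt)
  topo <- level_image(pair$topography, per_line = TRUE)
  profs <- sample_boundary_profiles(topo, gt$mask, 30, 300, seed = 5, clearance_px = 4)
  dh <- vapply(profs, function(p)
    tryCatch(step_delta(p), error = function(e) NA_real_), 0)
  dv <- vapply(profs, function(p) {
    q <- extract_profile(pair$potential, p$endpoints[1, ], p$endpoints[2, ],
                         length(p$values))
    tryCatch(step_delta(q), error = function(e) NA_real_)
  }, 0)
  expect_gt(mean(dh, na.rm = TRUE) * sign(spec$delta_h), 0)
  expect_gt(mean(dv, na.rm = TRUE) * sign(spec$delta_v), 0)
})
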