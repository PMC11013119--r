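test_that("plane levelling removes an exact plane and preserves steps", {
  r <- row(matrix(0, 64, 64)); cc <- col(matrix(0, 64, 64))
  plane <- 3 + 0.01 * r - 0.02 * cc
  img <- scan_image(plane, 1)
  out <- level_image(img, order = 1)
  expect_lt(max(abs(out$values)), 1e-10)
  # two-level structure of scattered domains survives levelling with its
  # contrast essentially unchanged (domains uncorrelated with coordinates,
  # so the fitted plane is not fooled by the phase pattern)
  gt <- generate_mask(clean_spec(seed = 12, coverage = 0.25))
  topo <- render_pair(gt)$topography
  rr2 <- row(topo$values); cc2 <- col(topo$values)
  tilted <- topo
  tilted$values <- topo$values + 0.01 * rr2 - 0.02 * cc2
  lev <- level_image(tilted, order = 1)
  delta_rec <- mean(lev$values[gt$mask == 1L]) - mean(lev$values[gt$mask == 0L])
  expect_equal(delta_rec, clean_spec()$delta_h, tolerance = 0.02)
  # order-0 subtracts the mean
  out0 <- level_image(img, order = 0)
  expect_equal(mean(out0$values), 0, tolerance = 1e-12)
})

test_that("constant images level to zero with a warning", {
  img <- scan_image(matrix(5, 16, 16), 1)
  expect_warning(out <- level_image(img), "constant")
  expect_true(all(out$values == 0))
})

test_that("per-line levelling removes streaks without shearing the phases", {
  spec <- tiny_spec(seed = 21, streak_amplitude = 0.05, tilt = c(0, 0),
                    noise_sigma_h = 0.01)
  gt <- generate_mask(spec)
  topo <- render_pair(gt)$topography
  plain <- level_image(topo, order = 1, per_line = FALSE)
  lined <- level_image(topo, order = 1, per_line = TRUE)
  # streak offsets live in the per-row level of the matrix phase; the
  # levelled image must keep the phase step itself (majority-high rows
  # stay high), so measure row offsets on ground-truth matrix pixels
  rm_var <- function(img) {
    offs <- vapply(seq_len(nrow(img$values)), function(i) {
      li <- gt$mask[i, ] == 0L
      if (sum(li) >= 8L) median(img$values[i, li]) else NA_real_
    }, 0)
    stats::var(offs, na.rm = TRUE)
  }
  expect_gte(rm_var(plain) / rm_var(lined), 10)
  # masked per-line offsets keep the recovered coverage on target even when
  # many scan lines are majority high-phase
  spec2 <- tiny_spec(seed = 22, coverage = 0.45, morphology = "coagulated")
  gt2 <- generate_mask(spec2)
  topo2 <- level_image(render_pair(gt2)$topography, per_line = TRUE)
  cov <- coverage_histogram(topo2)$coverage
  expect_equal(cov, gt2$realized_coverage, tolerance = 0.02)
})

test_that("histogram threshold separates a noiseless two-level image exactly", {
  v <- matrix(0, 64, 64); v[1:20, ] <- 0.33
  img <- scan_image(v, 1)
  thr <- histogram_threshold(img)
  expect_gt(thr, 0); expect_lt(thr, 0.33)
  res <- coverage_histogram(img)
  expect_equal(res$coverage, 20 / 64)
  expect_equal(res$coverage, mean(res$mask))
})

test_that("histogram threshold resolves a Gaussian mixture at the stated accuracy", {
  set.seed(42)
  n <- 256
  truth <- matrix(rbinom(n * n, 1, 0.5), n)
  v <- 0.33 * truth + matrix(rnorm(n * n, sd = 0.05), n)
  img <- scan_image(v, 1)
  res <- coverage_histogram(img)
  # misclassification ~ Phi(-delta / (2 sigma)) ~ 5e-4, plus sampling noise
  expect_equal(res$coverage, mean(truth), tolerance = 0.02 / mean(truth))
  expect_gt(res$threshold, 0.33 * 0.25)
  expect_lt(res$threshold, 0.33 * 0.75)
})

test_that("single-phase images raise a not-bimodal condition", {
  expect_error(histogram_threshold(scan_image(matrix(1, 16, 16), 1)),
               class = "not_bimodal")
  set.seed(1)
  uni <- scan_image(matrix(rnorm(64 * 64), 64), 1)
  expect_error(histogram_threshold(uni), class = "not_bimodal")
})

test_that("particle detection counts, filters and measures components", {
  img <- squares_image()
  res <- coverage_particle(img, threshold = 0.5, min_area = 0)
  expect_equal(nrow(res$particles), 3)
  expect_equal(res$coverage, 0.03)
  expect_equal(sort(res$particles$area_nm2), rep(100, 3))
  # five isolated pixels are removed by the default 4-pixel minimum area
  img2 <- squares_image(extra_px = c(5, 3007, 6011, 8015, 9515))
  res2 <- coverage_particle(img2, threshold = 0.5)
  expect_equal(nrow(res2$particles), 3)
  expect_equal(res2$coverage, 0.03)
  # with filtering disabled they are counted
  res3 <- coverage_particle(img2, threshold = 0.5, min_area = 0)
  expect_equal(nrow(res3$particles), 8)
})

test_that("connectivity 8 joins diagonal pixels that connectivity 4 separates", {
  v <- matrix(0, 16, 16)
  v[cbind(5:8, 5:8)] <- 1  # a diagonal line of four pixels
  img <- scan_image(v, 1)
  r8 <- coverage_particle(img, threshold = 0.5, min_area = 0,
                          connectivity = 8)
  r4 <- coverage_particle(img, threshold = 0.5, min_area = 0,
                          connectivity = 4)
  expect_equal(nrow(r8$particles), 1)
  expect_equal(nrow(r4$particles), 4)
  expect_equal(r8$coverage, r4$coverage)
})

test_that("particle and histogram coverage agree exactly on clean synthetics", {
  gt <- generate_mask(clean_spec(seed = 6, coverage = 0.25))
  topo <- render_pair(gt)$topography
  h <- coverage_histogram(topo)
  p <- coverage_particle(topo, threshold = h$threshold, min_area = 0)
  expect_equal(p$coverage, h$coverage)
  expect_equal(h$coverage, gt$realized_coverage)
  expect_identical(p$mask, h$mask)
})

test_that("recovered coverage tracks ground truth within 0.02 across seeds", {
  errs <- vapply(1:20, function(s) {
    gt <- generate_mask(tiny_spec(seed = s, coverage = 0.27))
    topo <- level_image(render_pair(gt)$topography, per_line = TRUE)
    coverage_histogram(topo)$coverage - gt$realized_coverage
  }, 0)
  expect_lt(max(abs(errs)), 0.02)
})

test_that("recovered coverage is monotone in the generator coverage", {
  rec <- vapply(c(0.12, 0.22, 0.32, 0.42), function(f) {
    gt <- generate_mask(tiny_spec(seed = 31, coverage = f))
    topo <- level_image(render_pair(gt)$topography, per_line = TRUE)
    coverage_histogram(topo)$coverage
  }, 0)
  expect_true(all(diff(rec) > 0))
})

test_that("model averaging reproduces the reported combined coverages", {
  r1 <- model_average(c(29, 3), c(25, 3))
  expect_equal(r1$estimate, 27)
  expect_equal(r1$margin, 4)
  r2 <- model_average(c(55.6, 0.6), c(53, 4))
  expect_equal(r2$estimate, 54)
  expect_equal(r2$margin, 4)
  r3 <- model_average(c(40, 0), c(40, 0))
  expect_equal(r3$estimate, 40)
  expect_equal(r3$margin, 0)
  full <- model_average(c(29, 3), c(25, 3), digits = NULL)
  expect_equal(full$estimate, 27)
  expect_equal(full$margin, sqrt(18))
  expect_error(model_average(c(10, -1), c(10, 1)),
               class = "validation_error")
})

test_that("segmentation results carry tidy particle tables and glances", {
  img <- squares_image()
  res <- coverage_particle(img, threshold = 0.5)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$coverage_pct, 3)
  expect_equal(g$n_particles, 3)
  expect_s3_class(autoplot(res), "ggplot")
})
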