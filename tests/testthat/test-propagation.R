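test_that("noiseless samples recover the generating law exactly", {
  sch <- make_band_scheme(1000, 1300, 300)
  s <- gen_pl_samples(sch, depth_grid = 5,
                      A_of = function(b, z) 60, n_of = function(b, z) 17,
                      ranges = c(10, 100, 1000, 10000), residual_sd = 0)
  fit <- fit_pl_loglaw(s, sch, depth_bins = c(0, 10))
  expect_equal(fit$A, 60, tolerance = 1e-9)
  expect_equal(fit$n, 17, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  expect_true(fit$usable)
})

test_that("noisy fits recover coefficients within OLS sampling bounds", {
  sch <- make_band_scheme(1000, 1300, 300)
  ranges <- 10^seq(1, 4, length.out = 200)
  for (seed in 1:5) {
    s <- gen_pl_samples(sch, depth_grid = 5,
                        A_of = function(b, z) 60, n_of = function(b, z) 15,
                        ranges = ranges, residual_sd = 1, seed = seed)
    fit <- fit_pl_loglaw(s, sch, depth_bins = c(0, 10))
    expect_lt(abs(fit$A - 60), 0.5)
    expect_lt(abs(fit$n - 15), 0.3)
    expect_gt(fit$rmse, 0)
  }
})

test_that("rank-deficient cells are flagged, not fitted", {
  sch <- make_band_scheme(1000, 1300, 300)
  s <- gen_pl_samples(sch, depth_grid = 5,
                      A_of = function(b, z) 60, n_of = function(b, z) 15,
                      ranges = c(500, 500, 500), residual_sd = 0)
  expect_warning(fit <- fit_pl_loglaw(s, sch, depth_bins = c(0, 10)),
                 "unusable")
  expect_false(fit$usable)
  expect_true(is.na(fit$A))
  expect_error(pl_coeffs_at(fit, 1, 5), "no usable")
})

test_that("empty sample tables error", {
  sch <- make_band_scheme(1000, 1300, 300)
  expect_error(pl_samples(data.frame(range_m = numeric(),
                                     source_depth_m = numeric(),
                                     band_index = integer(),
                                     pl_db = numeric()), sch),
               "empty")
})

test_that("coefficients interpolate linearly in depth and clamp outside", {
  sch <- make_band_scheme(1000, 1300, 300)
  s <- gen_pl_samples(sch, depth_grid = c(5, 15),
                      A_of = function(b, z) ifelse(z < 10, 50, 60),
                      n_of = function(b, z) ifelse(z < 10, 14, 16),
                      ranges = c(10, 100, 1000), residual_sd = 0)
  fit <- fit_pl_loglaw(s, sch, depth_bins = c(0, 10, 20))
  # at a bin center: that cell's values
  at5 <- pl_coeffs_at(fit, 1, 5)
  expect_equal(at5$A, 50, tolerance = 1e-9)
  expect_equal(at5$n, 14, tolerance = 1e-9)
  # midway: linear interpolation
  at10 <- pl_coeffs_at(fit, 1, 10)
  expect_equal(at10$A, 55, tolerance = 1e-9)
  expect_equal(at10$n, 15, tolerance = 1e-9)
  # outside the fitted span: clamped
  deep <- pl_coeffs_at(fit, 1, 150)
  expect_equal(deep$A, 60, tolerance = 1e-9)
  shallow <- pl_coeffs_at(fit, 1, 0.1)
  expect_equal(shallow$A, 50, tolerance = 1e-9)
})

test_that("the evaluated law obeys its closed form and the decade property", {
  sch <- make_band_scheme(1000, 1300, 300)
  fit <- exact_pl_table(sch, A_vals = 60, n_vals = 15)
  expect_equal(pl_at(fit, 1, 5, 1), 60, tolerance = 1e-9)
  expect_equal(pl_at(fit, 1, 5, 100), 30, tolerance = 1e-9)
  for (r0 in c(3, 47, 900))
    expect_equal(pl_at(fit, 1, 5, r0) - pl_at(fit, 1, 5, 10 * r0), 15,
                 tolerance = 1e-9)
  expect_error(pl_at(fit, 1, 5, 0), "positive")
  expect_error(pl_at(fit, 1, 5, -10), "positive")
})

test_that("refitting on samples regenerated from a fit reproduces it", {
  sch <- make_band_scheme(1000, 1900, 300)
  set.seed(8)
  fit <- exact_pl_table(sch, A_vals = runif(3, 40, 70),
                        n_vals = runif(3, 12, 18))
  regen <- gen_pl_samples(sch, depth_grid = c(5, 15),
                          A_of = function(b, z) pl_coeffs_at(fit, b, z)$A,
                          n_of = function(b, z) pl_coeffs_at(fit, b, z)$n,
                          ranges = c(10, 100, 1000, 10000), residual_sd = 0)
  refit <- fit_pl_loglaw(regen, sch, depth_bins = c(0, 10, 20))
  expect_equal(refit$A, fit$A, tolerance = 1e-9)
  expect_equal(refit$n, fit$n, tolerance = 1e-9)
})

test_that("with a single transect, pooled and per-transect fits agree", {
  sch <- make_band_scheme(1000, 1300, 300)
  s <- gen_pl_samples(sch, depth_grid = 5,
                      A_of = function(b, z) 55, n_of = function(b, z) 16,
                      ranges = 10^seq(1, 4, length.out = 30),
                      residual_sd = 1, seed = 3)
  pooled <- fit_pl_loglaw(s, sch, depth_bins = c(0, 10), pooling = "pooled")
  per_t <- fit_pl_loglaw(s, sch, depth_bins = c(0, 10),
                         pooling = "per_transect")
  expect_equal(pooled$A, per_t$A)
  expect_equal(pooled$n, per_t$n)
})

test_that("propagation CSVs round trip through the documented formats", {
  sch <- make_band_scheme(1000, 1900, 300)
  s <- gen_pl_samples(sch, depth_grid = c(5, 15),
                      A_of = function(b, z) 50 + b, n_of = function(b, z) 15,
                      ranges = c(10, 100, 1000), residual_sd = 0.3, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pl_csv(s, path)
  back <- read_pl_csv(path, sch)
  expect_equal(back$pl_db, s$pl_db, tolerance = 1e-4)
  expect_identical(back$band_index, s$band_index)

  fit <- fit_pl_loglaw(back, sch, depth_bins = c(0, 10, 20))
  fpath <- withr::local_tempfile(fileext = ".csv")
  write_pl_fit_csv(fit, fpath)
  df <- read.csv(fpath)
  expect_identical(nrow(df), nrow(fit))
  expect_equal(df$A_db, fit$A, tolerance = 1e-9)
})
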