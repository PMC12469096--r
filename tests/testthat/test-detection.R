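test_that("per-band detection range obeys its closed form", {
  # A + SL - NL - DT = 0 -> 1 m
  expect_equal(detection_range_band(0, 20, 105, 100, 5), 1)
  expect_equal(detection_range_band(0, 20, 155, 100, 5), 316.228,
               tolerance = 1e-4)
  # raising the noise by n dB divides the range by exactly 10
  set.seed(21)
  for (i in 1:25) {
    A <- runif(1, -10, 10); n <- runif(1, 5, 25)
    sl <- runif(1, 130, 170); nl <- runif(1, 70, 110)
    r0 <- detection_range_band(A, n, sl, nl)
    expect_equal(detection_range_band(A, n, sl, nl + n) * 10, r0,
                 tolerance = 1e-9 * r0)
    # strict monotonicities
    expect_gt(detection_range_band(A + 1, n, sl, nl), r0)
    expect_gt(detection_range_band(A, n, sl + 1, nl), r0)
    expect_lt(detection_range_band(A, n, sl, nl + 1), r0)
    expect_lt(detection_range_band(A, n, sl, nl, dt = 6), r0)
  }
  expect_error(detection_range_band(0, 0, 155, 100), "positive")
  expect_error(detection_range_band(0, -5, 155, 100), "positive")
})

test_that("the argmax band wins with ties to the lowest index", {
  expect_equal(max_detection_range(c(100, 500, 300)),
               list(r_max = 500, band_index = 2L))
  expect_equal(max_detection_range(c(500, 500))$band_index, 1L)
  expect_equal(max_detection_range(c(100, 500, 300),
                                   usable = c(TRUE, FALSE, TRUE)),
               list(r_max = 300, band_index = 3L))
  expect_error(max_detection_range(c(1, 2), usable = c(FALSE, FALSE)),
               "no usable band")
  set.seed(3)
  for (i in 1:20) {
    r <- runif(46, 10, 1e5)
    expect_equal(max_detection_range(r)$r_max, max(r))
    expect_equal(max_detection_range(r)$band_index, which.max(r))
  }
})

test_that("detection curves are empirical survival functions", {
  expect_equal(detection_curve(c(100, 200, 300), 150), 2 / 3)
  expect_equal(detection_curve(c(100, 200, 300), 200), 2 / 3)  # ties detect
  expect_equal(detection_curve(c(100, 200, 300), c(50, 1000)), c(1, 0))
  expect_equal(detection_curve(500, c(100, 500, 501)), c(1, 1, 0))
  expect_error(detection_curve(numeric(0), 1:3), "at least one")
  set.seed(9)
  grid <- 10^seq(1, 5, length.out = 100)
  for (i in 1:10) {
    cv <- detection_curve(10^runif(30, 1, 5), grid)
    expect_true(all(diff(cv) <= 0))
    expect_true(all(cv >= 0 & cv <= 1))
  }
})

test_that("curve inversion finds the range at a target probability", {
  grid <- 10^seq(1, 5, by = 0.01)
  cell <- 10^0.01
  # single step at 500 m
  cv <- detection_curve(500, grid)
  r <- invert_detection_curve(cv, grid, 0.5)
  expect_false(r$unbounded)
  expect_lt(abs(log10(r$range_m / 500)), 0.011)
  # survival curve of [100, 200, 300] crosses 0.5 at 200 m
  cv3 <- detection_curve(c(100, 200, 300), grid)
  r3 <- invert_detection_curve(cv3, grid, 0.5)
  expect_lt(abs(log10(r3$range_m / 200)), 0.011)
  # inversion is monotone in p
  expect_gte(invert_detection_curve(cv3, grid, 0.1)$range_m,
             invert_detection_curve(cv3, grid, 0.5)$range_m)
  expect_gte(invert_detection_curve(cv3, grid, 0.5)$range_m,
             invert_detection_curve(cv3, grid, 0.9)$range_m)
  # boundary contracts
  expect_equal(invert_detection_curve(rep(0.05, length(grid)), grid, 0.5),
               list(range_m = 0, unbounded = FALSE))
  unb <- invert_detection_curve(rep(0.9, length(grid)), grid, 0.5)
  expect_true(unb$unbounded)
  expect_equal(unb$range_m, max(grid))
})

test_that("a degenerate ensemble collapses to one step curve", {
  sch <- make_band_scheme(1000, 1300, 300)
  noise <- flat_noise(sch, 5, 90)
  pl <- exact_pl_table(sch, A_vals = 0, n_vals = 15)
  spec <- source_level_spec(150, 0, 0)
  cfg <- detection_config(n_sl = 1, n_depth = 1, seed = 2)
  ens <- run_monte_carlo(noise, pl, spec, depth_model(), cfg)
  expect_identical(ens$n_realizations, 1L)
  expect_true(all(ens$curves %in% c(0, 1)))
  expect_equal(ens$percentile_curves["p25", ], ens$percentile_curves["p75", ],
               ignore_attr = TRUE)
  # the single step sits at the closed-form range
  r_true <- detection_range_band(0, 15, 150, 90, 5)
  r_hat <- as.numeric(median_range_at_probability(ens, 0.5))
  expect_lt(abs(log10(r_hat / r_true)), 0.025)
})

test_that("single-band constant-noise medians match the closed form", {
  sch <- make_band_scheme(1000, 1300, 300)
  noise <- flat_noise(sch, 4, 92)
  pl <- exact_pl_table(sch, A_vals = 2, n_vals = 16)  # depth-independent
  spec <- source_level_spec(152, 5, 0)
  cfg <- detection_config(n_sl = 9, n_depth = 1, seed = 31,
                          range_grid = 10^seq(0, 6, by = 0.01))
  ens <- run_monte_carlo(noise, pl, spec, depth_model(), cfg)
  r_closed <- detection_range_band(2, 16, median(ens$pools$sl), 92, 5)
  r_hat <- as.numeric(median_range_at_probability(ens, 0.5))
  expect_lt(abs(log10(r_hat / r_closed)), 0.03)
  # brute-force enumeration of the realization pool agrees
  rmax_all <- detection_range_band(2, 16, ens$pools$sl, 92, 5)
  expect_lt(abs(log10(r_hat / median(rmax_all))), 0.03)
})

test_that("the vectorized engine matches the brute-force oracle", {
  for (seed in c(11, 22, 33, 44, 55)) {
    inst <- random_small_instance(seed)
    ens <- suppressWarnings(run_monte_carlo(
      inst$noise, inst$pl, inst$sl_spec, inst$depth_params, inst$config))
    ref <- oracle_curves(inst$noise, inst$pl, inst$sl_spec,
                         inst$depth_params, inst$config, ens$pools)
    expect_lt(max(abs(ens$curves - ref)), 1e-9)
  }
})

test_that("identical seeds give bit-identical ensembles", {
  sc <- gen_site_scenario("toy3band", seed = 6)
  cfg <- detection_config(n_sl = 12, n_depth = 8, seed = 17)
  e1 <- run_monte_carlo(sc$noise, sc$pl_fit, sc$sl_spec, sc$depth_params, cfg)
  e2 <- run_monte_carlo(sc$noise, sc$pl_fit, sc$sl_spec, sc$depth_params, cfg)
  expect_identical(e1$percentile_curves, e2$percentile_curves)
  expect_identical(e1$curves, e2$curves)
  expect_identical(e1$median_ranges, e2$median_ranges)
  expect_identical(e1$argmax_band_share, e2$argmax_band_share)
})

test_that("ensemble invariants hold on a full scenario run", {
  sc <- gen_site_scenario("toy3band", seed = 10)
  cfg <- detection_config(n_sl = 15, n_depth = 10, seed = 3)
  ens <- run_monte_carlo(sc$noise, sc$pl_fit, sc$sl_spec, sc$depth_params, cfg)
  expect_true(all(ens$curves >= 0 & ens$curves <= 1))
  expect_true(all(apply(ens$curves, 1, function(cv) all(diff(cv) <= 0))))
  expect_true(all(diff(t(ens$percentile_curves)) <= 0))  # p25 <= p50 <= p75
  expect_equal(sum(ens$argmax_band_share), 1, tolerance = 1e-12)
  mr <- ens$median_ranges
  expect_true(all(diff(mr$range_m[order(mr$p)]) <= 0))
})

test_that("with a strongly negative slope, flat noise and flat PL, band 1 wins", {
  sch <- make_band_scheme(1000, 2500, 300)
  noise <- flat_noise(sch, 6, 85)
  pl <- exact_pl_table(sch, A_vals = rep(0, 5), n_vals = rep(15, 5))
  spec <- source_level_spec(150, 3, -5)
  cfg <- detection_config(n_sl = 5, n_depth = 4, seed = 12)
  ens <- run_monte_carlo(noise, pl, spec, depth_model(), cfg)
  expect_equal(ens$argmax_band_share[1], 1)
})

test_that("noise strata shifted by exactly n dB scale ranges by factors of 10", {
  sch <- make_band_scheme(1000, 1300, 300)
  n_coef <- 15
  lv <- c(rep(80, 5), rep(80 + n_coef, 5), rep(80 + 2 * n_coef, 5))
  noise <- ambient_series(matrix(lv, ncol = 1), sch)
  strata <- stratify_by_broadband(noise)
  expect_equal(lengths(strata$members),
               c(low = 5L, medium = 5L, high = 5L))
  pl <- exact_pl_table(sch, A_vals = 0, n_vals = n_coef)
  spec <- sl_preset("SRKW")
  cfg <- detection_config(n_sl = 8, n_depth = 4, seed = 9,
                          range_grid = 10^seq(-1, 7, by = 0.02))
  res <- run_stratified(noise, strata, pl, spec, depth_model(), cfg)
  # shared pools across strata
  expect_identical(res$low$pools, res$high$pools)
  r_low <- as.numeric(median_range_at_probability(res$low, 0.5))
  r_med <- as.numeric(median_range_at_probability(res$medium, 0.5))
  r_high <- as.numeric(median_range_at_probability(res$high, 0.5))
  expect_equal(r_low / r_med, 10, tolerance = 1e-6)
  expect_equal(r_med / r_high, 10, tolerance = 1e-6)
})

test_that("stratified runs reject empty strata", {
  sch <- make_band_scheme(1000, 1300, 300)
  noise <- flat_noise(sch, 9, 90)
  strata <- stratify_by_broadband(noise)  # all ties -> all medium
  pl <- exact_pl_table(sch, A_vals = 0, n_vals = 15)
  expect_error(
    run_stratified(noise, strata, pl, sl_preset("SRKW"), depth_model(),
                   detection_config(n_sl = 2, n_depth = 2)),
    "empty stratum")
})

test_that("sensitivity swaps isolate one factor under a shared seed", {
  sch <- make_band_scheme(1000, 1900, 300)
  # low-frequency-heavy noise: band 1 is 15 dB louder
  noise <- ambient_series(
    matrix(rep(c(100, 85, 85), each = 8), nrow = 8), sch)
  pl <- exact_pl_table(sch, A_vals = rep(0, 3), n_vals = rep(15, 3))
  base <- list(noise = noise, pl = pl,
               sl_spec = source_level_spec(150, 4, -5, "sloped"),
               depth_params = depth_model(),
               config = detection_config(n_sl = 6, n_depth = 4, seed = 7,
                                         range_grid = 10^seq(0, 6, by = 0.005)))

  # a null swap (factor replaced by itself) must give exactly zero
  null_res <- run_sensitivity(base, list(list(sl_spec = base$sl_spec)))
  expect_identical(null_res$difference, 0)

  # flattening the source spectrum moves energy into the quiet high bands
  flat <- source_level_spec(150, 4, 0, "flat")
  res <- run_sensitivity(base, list(list(sl_spec = flat)))
  expect_gt(res$difference, 0)

  # a deeper caller sees larger A when A increases with depth
  pl_deep <- exact_pl_table(sch, A_vals = rep(0, 3), n_vals = rep(15, 3),
                            depth_grid = c(5, 150),
                            depth_bins = c(0, 10, 200))
  pl_deep$A <- ifelse(pl_deep$depth_bin_center > 50, 10, 0)
  base2 <- base
  base2$pl <- pl_deep
  res2 <- run_sensitivity(base2, list(list(
    depth_params = uniform_depth_model(200))))
  expect_gt(res2$difference, 0)

  expect_error(
    run_sensitivity(base, list(list(sl_spec = flat, noise = noise))),
    "exactly one")
  expect_error(run_sensitivity(base, list(list(bogus = 1))), "exactly one")
})

test_that("scheme mismatches between noise and propagation error", {
  noise <- flat_noise(make_band_scheme(1000, 1300, 300), 3, 90)
  pl <- exact_pl_table(make_band_scheme(1000, 1900, 300),
                       A_vals = rep(0, 3), n_vals = rep(15, 3))
  expect_error(
    run_monte_carlo(noise, pl, sl_preset("SRKW"), depth_model(),
                    detection_config(n_sl = 1, n_depth = 1)),
    "different band schemes")
})
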