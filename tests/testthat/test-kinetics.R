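test_that("breakage law honours its limits and branches", {
  expect_equal(as.numeric(breakage_d50(0, 2, 2, 0.12, 11.4)), 11.4)
  # ODE oracle at a printed-parameter point
  expect_equal(as.numeric(breakage_d50(1, 5.10, 2.46, 0.119, 11.4)),
               ode_d50(c(0, 1), 5.10, 2.46, 0.119, 11.4)[2], tolerance = 1e-6)
  # continuity across the n -> 1 limit branch
  t <- c(0.5, 2, 20)
  lim <- as.numeric(breakage_d50(t, 1.3, 1, 0.1, 11.4))
  expect_equal(as.numeric(breakage_d50(t, 1.3, 1 + 1e-9, 0.1, 11.4)), lim,
               tolerance = 1e-6)
  expect_equal(as.numeric(breakage_d50(t, 1.3, 1 - 1e-9, 0.1, 11.4)), lim,
               tolerance = 1e-6)
  # n > 1: strictly decreasing, bounded below by d_lim
  grid <- seq(0, 180, by = 0.5)
  for (n in c(1.2, 2, 2.8)) {
    v <- as.numeric(breakage_d50(grid, 1.5, n, 0.12, 11.4))
    expect_true(all(diff(v) < 0))
    expect_true(all(v > 0.12))
  }
  # n < 1: finite extinction, flagged, clamped at d_lim
  v <- breakage_d50(c(1, 1e4), 1.5, 0.8, 0.12, 11.4)
  expect_identical(attr(v, "extinct"), c(FALSE, TRUE))
  expect_equal(as.numeric(v)[2], 0.12)
})

test_that("fitting recovers generating parameters on noise-free data", {
  ts <- model_series(1.0, 2.0, 0.12)
  f <- fit_breakage(ts)
  expect_equal(f$k, 1.0, tolerance = 1e-3)
  expect_equal(f$n, 2.0, tolerance = 1e-3)
  expect_equal(f$d_lim, 0.12, tolerance = 1e-3)
  expect_true(f$converged)
  expect_gt(f$R2, 0.999)
})

test_that("fitting recovers all 24 reference parameter triples", {
  ref <- reference_kinetics()
  k_err <- purrr::pmap_dbl(
    list(ref$k, ref$n, ref$d_lim_um),
    function(k, n, dl) abs(fit_breakage(model_series(k, n, dl))$k - k) / k
  )
  expect_lte(max(k_err), 1e-2)
})

test_that("a constant series is flagged as having no breakage signal", {
  ts <- tibble::tibble(time_min = c(0, 1, 2, 4, 8, 16), d50_um = rep(11.4, 6))
  f <- fit_breakage(ts)
  expect_true(f$boundary_k)
  expect_lt(abs(f$R2), 1e-6)
})

test_that("fit input validation rejects degenerate series", {
  expect_error(fit_breakage(tibble::tibble(time_min = 0:3, d50_um = rep(1, 4))),
               "5 time points")
  expect_error(
    fit_breakage(tibble::tibble(time_min = c(0, 2, 1, 3, 4), d50_um = rep(1, 5))),
    "increasing")
  expect_error(
    fit_breakage(tibble::tibble(time_min = 1:5, d50_um = rep(1, 5))),
    "t = 0")
})

test_that("interpolated crossing time approaches the closed form", {
  k <- 5.10; n <- 2.46; d_lim <- 0.119
  t_closed <- breakage_time_to(0.2, k, n, d_lim, 11.4)
  res <- time_to_size(model_series(k, n, d_lim))
  expect_true(res$crossed)
  # error bound from the interpolant's deviation over the bracketing
  # interval divided by the minimum curve slope there
  lo <- max(sampling_times()[sampling_times() < t_closed])
  hi <- min(sampling_times()[sampling_times() > t_closed])
  dense <- seq(lo, hi, length.out = 400)
  interp <- pracma::pchip(sampling_times(),
                          as.numeric(breakage_d50(sampling_times(), k, n, d_lim, 11.4)),
                          dense)
  dev <- max(abs(interp - as.numeric(breakage_d50(dense, k, n, d_lim, 11.4))))
  slope <- min(abs(diff(as.numeric(breakage_d50(dense, k, n, d_lim, 11.4))) / diff(dense)))
  expect_lt(abs(res$t_cross_min - t_closed), dev / slope + 1e-6)
  # denser sampling converges to the closed form
  fine <- model_series(k, n, d_lim, times = seq(0, 180, by = 0.25))
  expect_equal(time_to_size(fine)$t_cross_min, t_closed, tolerance = 1e-4)
})

test_that("crossing handles exact hits and misses explicitly", {
  ts <- model_series(1.0, 2.0, 0.12)
  i <- 8
  ts$d50_um[i] <- 0.2  # plant an exact observation at the target
  expect_equal(time_to_size(ts)$t_cross_min, ts$time_min[i])
  high <- tibble::tibble(time_min = c(0, 1, 2, 4), d50_um = c(11, 9, 8, 7))
  res <- time_to_size(high)
  expect_false(res$crossed)
  expect_true(is.na(res$t_cross_min))
})

test_that("cycle counting follows the cumulative-milling-time rule", {
  single <- simulate_thermal_cycles(0)
  expect_equal(cycles_at_time(single, 0), 1)
  expect_equal(cycles_at_time(single, 179), 1)
  # synthetic three-segment schedule starting at 0, 30, 60 min of milling
  sched <- simulate_thermal_cycles(0)
  sched$cycles <- tibble::tibble(
    mill_start = c(0, 40, 80), mill_stop = c(30, 70, 110),
    cool_stop = c(40, 80, 110)
  )
  expect_equal(cycles_at_time(sched, 45), 2)
  expect_equal(cycles_at_time(sched, 60), 3)  # boundary: a segment starting at t counts
  expect_equal(cycles_at_time(sched, 15), 1)
  expect_error(cycles_at_time(sched, -1), "non-negative")
  expect_error(cycles_at_time(sched, 95), "exceeds")
})

test_that("fit summaries agree with a two-pass oracle", {
  ref <- reference_kinetics()
  s <- summarize_fits(ref)
  for (p in c("k", "n", "d_lim_um")) {
    o <- two_pass_stats(ref[[p]])
    expect_equal(s$mean[s$parameter == p], unname(o["mean"]), tolerance = 1e-12)
    expect_equal(s$sd[s$parameter == p], unname(o["sd"]), tolerance = 1e-12)
  }
  expect_equal(k_ratio(ref, "19", "24"), 5.10 / 1.53)
  expect_error(k_ratio(ref, "19", "99"), "not found")
})
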