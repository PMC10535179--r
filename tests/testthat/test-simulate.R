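test_that("noise-free simulation equals the closed form and an ODE oracle", {
  k <- 5.10; n <- 2.46; d_lim <- 0.119
  ts <- simulate_run(k, n, d_lim, noise_cv = 0)
  expect_equal(ts$d50_um[1], 11.4)  # feed median size at t = 0
  closed <- as.numeric(breakage_d50(ts$time_min, k, n, d_lim, 11.4))
  expect_equal(ts$d50_um, closed, tolerance = 1e-10)
  ode <- ode_d50(ts$time_min, k, n, d_lim, 11.4)
  expect_equal(ts$d50_um, ode, tolerance = 1e-6)
  # d10/d90 are feed-ratio copies, SD column is cv * value
  expect_equal(ts$d10_um / ts$d50_um, rep(4.30 / 11.4, nrow(ts)))
  expect_equal(ts$d90_um / ts$d50_um, rep(23.5 / 11.4, nrow(ts)))
  expect_equal(ts$sd_um, rep(0, nrow(ts)))
})

test_that("simulation is reproducible under a seed and rejects bad times", {
  a <- simulate_run(1, 2, 0.12, seed = 42, noise_cv = 0.05)
  b <- simulate_run(1, 2, 0.12, seed = 42, noise_cv = 0.05)
  c3 <- simulate_run(1, 2, 0.12, seed = 43, noise_cv = 0.05)
  expect_identical(a, b)
  expect_false(identical(a$d50_um, c3$d50_um))
  expect_equal(a$sd_um, 0.05 * a$d50_um)
  expect_error(simulate_run(1, 2, 0.12, times = c(0, 2, 1)), "increasing")
  # simulation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_run(1, 2, 0.12, seed = 1, noise_cv = 0.05))
  expect_equal(rnorm(1), before)
})

test_that("whole-study generation is deterministic in the master seed", {
  s1 <- simulate_study(build_design(11))
  s2 <- simulate_study(build_design(11))
  s3 <- simulate_study(build_design(12))
  expect_identical(s1$timeseries, s2$timeseries)
  expect_false(identical(s1$timeseries$d50_um, s3$timeseries$d50_um))
  # per-run child seeds differ: runs are not identical copies
  d1 <- s1$timeseries$d50_um[s1$timeseries$run_id == "1"]
  d2 <- s1$timeseries$d50_um[s1$timeseries$run_id == "2"]
  expect_false(identical(d1 / d1[1], d2 / d2[1]))
})

test_that("thermal schedule is a single segment when the cutoff is unreachable", {
  s0 <- simulate_thermal_cycles(0)
  expect_equal(s0$n_cycles, 1)
  expect_equal(s0$cycles$mill_start, 0)
  expect_equal(s0$cycles$mill_stop, 180)
  s_cold <- simulate_thermal_cycles(500, thermal_defaults(UA_W_K = 1e6))
  expect_equal(s_cold$n_cycles, 1)
})

test_that("milling segments always sum to the total milling time", {
  for (p in c(0, 40, 80, 120, 200)) {
    s <- simulate_thermal_cycles(p)
    expect_equal(sum(s$cycles$mill_stop - s$cycles$mill_start), 180)
  }
})

test_that("intermittent cycling matches an event-detection ODE oracle", {
  th <- thermal_defaults()
  p <- 150  # steady-state temperature well above the 35 C cutoff
  s <- simulate_thermal_cycles(p, th)
  expect_gte(s$n_cycles, 2)
  oracle <- ode_thermal_schedule(p, th)
  expect_equal(nrow(oracle), s$n_cycles)
  expect_equal(s$cycles$mill_start, unname(oracle[, "start"]), tolerance = 1e-5)
  expect_equal(s$cycles$mill_stop, unname(oracle[, "stop"]), tolerance = 1e-5)
  # each interior milling segment ends exactly when T reaches T_max
  tau <- th$C_th_J_K / th$UA_W_K / 60
  t_inf <- th$T_coolant_C + th$eta_heat * p / th$UA_W_K
  temp_at <- function(t0, from, t) t_inf + (from - t_inf) * exp(-(t - t0) / tau)
  for (i in seq_len(s$n_cycles - 1)) {
    from <- if (i == 1) th$T_start_C else th$T_restart_C
    expect_equal(temp_at(s$cycles$mill_start[i], from, s$cycles$mill_stop[i]),
                 th$T_max_C, tolerance = 1e-8)
  }
  expect_error(simulate_thermal_cycles(100, thermal_defaults(UA_W_K = -1)),
               "positive")
  expect_error(simulate_thermal_cycles(100, thermal_defaults(T_restart_C = 40)),
               "below T_max")
})

test_that("replicate noise at 3 percent leaves k recoverable within 10 percent", {
  k <- 1.54; n <- 1.89; d_lim <- 0.130   # a mid-design generating triple
  rel_err <- vapply(1:50, function(seed) {
    ts <- simulate_run(k, n, d_lim, seed = seed, noise_cv = 0.03)
    abs(fit_breakage(ts)$k - k) / k
  }, numeric(1))
  expect_lte(median(rel_err), 0.10)
})
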