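test_that("radial distribution function matches direct evaluation", {
  expect_equal(radial_distribution(0), 1)
  expect_equal(radial_distribution(0.35), 1 / (1 - (0.35 / 0.63)^(1 / 3)))
  expect_equal(radial_distribution(0.35), 5.620, tolerance = 1e-3)
  expect_equal(radial_distribution(0.50), 13.487, tolerance = 1e-4)
  cs <- seq(0.05, 0.6, by = 0.05)
  expect_true(all(diff(radial_distribution(cs)) > 0))
  expect_true(all(radial_distribution(cs) >= 1))
  expect_error(radial_distribution(0.63), "packing limit")
})

test_that("granular temperature solves the energy balance uniquely", {
  expect_equal(granular_temperature(5e4, 5e4, 0.08, 0.5, 112e-6), 0)
  expect_error(granular_temperature(1e4, 5e4, 0.08, 0.5, 112e-6),
               "negative dissipation")
  th1 <- granular_temperature(2.5e5, 5e4, 0.08, 0.5, 112e-6)
  th2 <- granular_temperature(4.5e5, 5e4, 0.08, 0.5, 112e-6)  # doubled net power
  expect_gt(th2, th1)
  # reference case locked by the dense-grid sign-change oracle
  o <- grid_theta(2.5e5, 5e4, 0.08, 0.5, 112e-6)
  expect_lt(abs(th1 - o$theta), o$step)
})

test_that("solver matches the grid oracle on random inputs", {
  set.seed(2024)
  for (i in 1:20) {
    p_w <- runif(1, 1e5, 3e6)
    eps_ht <- runif(1, 0, 0.2) * p_w
    mu <- runif(1, 0.06, 0.12)
    c_load <- runif(1, 0.2, 0.55)
    db <- runif(1, 100e-6, 450e-6)
    th <- granular_temperature(p_w, eps_ht, mu, c_load, db)
    o <- grid_theta(p_w, eps_ht, mu, c_load, db, n_grid = 1e6)
    expect_lt(abs(th - o$theta), o$step)
  }
})

test_that("energy is conserved across a 27-run synthetic sweep", {
  study <- simulate_study(build_design(5))
  m <- compute_mhd_state(study$runs)
  expect_lte(max(m$residual_rel), 1e-8)
  expect_true(all(m$theta > 0))
  # a = p * nu exactly, and matches the closed form independently coded
  expect_equal(m$a, m$p * m$nu, tolerance = 1e-15)
  a_closed <- purrr::pmap_dbl(
    list(m$theta, study$runs$loading, study$runs$db_um * 1e-6),
    function(th, c, db) compression_frequency(th, c, db)
  )
  expect_equal(m$a, a_closed, tolerance = 1e-10)
})

test_that("contact mechanics match direct evaluation and vanish at rest", {
  z <- contact_mechanics(0, 200e-6)
  expect_equal(unlist(z), c(F_bn = 0, alpha_b = 0, sigma_bmax = 0))
  cs0 <- compression_stats(0, 0.5, 200e-6)
  expect_equal(unname(unlist(cs0[c("u_b", "nu", "p", "a", "Pi_sigma_y")])),
               rep(0, 5))
  # direct evaluation oracle at the reference state
  k <- mhd_constants()
  th <- granular_temperature(2.5e5, 5e4, 0.08, 0.5, 112e-6)
  r_b <- 112e-6 / 2
  f_direct <- 1.96 * (k$Y_b / (1 - k$eta_b^2))^0.4 * k$rho_b^0.6 * r_b^2 * th^0.6
  cm <- contact_mechanics(th, 112e-6)
  expect_equal(cm$F_bn, f_direct, tolerance = 1e-12)
  expect_equal(cm$alpha_b,
               (3 * (1 - k$eta_b^2) * r_b * f_direct / (4 * k$Y_b))^(1 / 3),
               tolerance = 1e-12)
  # the maximum contact pressure is the Hertzian 3F/(2 pi a^2)
  expect_equal(cm$sigma_bmax, 3 * cm$F_bn / (2 * pi * cm$alpha_b^2))
  expect_equal(3 * 1 / (2 * pi * 1^2), 0.4775, tolerance = 1e-4)
})

test_that("scaling laws hold to high precision", {
  th <- 0.01
  base_cs <- compression_stats(th, 0.4, 200e-6)
  dbl_cs <- compression_stats(2 * th, 0.4, 200e-6)
  expect_equal(dbl_cs$a / base_cs$a, 2^0.9, tolerance = 1e-10)
  expect_equal(dbl_cs$Pi_sigma_y / base_cs$Pi_sigma_y, 2^1.3, tolerance = 1e-10)
  # compression frequency scales as 1/R_b^2 at fixed theta and loading
  big <- compression_stats(th, 0.4, 400e-6)
  expect_equal(base_cs$a / big$a, 4, tolerance = 1e-10)
  f1 <- contact_mechanics(th, 200e-6)$F_bn
  f2 <- contact_mechanics(2 * th, 200e-6)$F_bn
  expect_equal(f2 / f1, 2^0.6, tolerance = 1e-10)
})

test_that("process directions propagate through the MHD chain", {
  base <- tibble::tibble(run_id = "lo", loading = 0.35, db_um = 194,
                         P_W = 60, mu_L_PaS = 0.09, eps_ht_W_m3 = 5e4)
  # higher speed: higher power at the same loading
  fast <- dplyr::mutate(base, run_id = "hi", P_W = 130)
  m <- compute_mhd_state(dplyr::bind_rows(base, fast))
  expect_gt(m$theta[2], m$theta[1])
  expect_gt(m$sigma_bmax[2], m$sigma_bmax[1])
  expect_gt(m$a[2], m$a[1])
  # higher loading at identical power density: more frequent but gentler
  # collisions
  dense <- dplyr::mutate(base, run_id = "dense", loading = 0.50)
  m2 <- compute_mhd_state(dplyr::bind_rows(base, dense))
  expect_gt(m2$nu[2], m2$nu[1])
  expect_gt(m2$a[2], m2$a[1])
  expect_lt(m2$theta[2], m2$theta[1])
  expect_lt(m2$sigma_bmax[2], m2$sigma_bmax[1])
})
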