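# Independent oracles used across the suite. They deliberately avoid the
# package's closed-form code paths.

# numeric integration of d(d50)/dt = -k (d50 - d_lim)^n from the feed size
ode_d50 <- function(times, k, n, d_lim, d50_0) {
  rhs <- function(t, y, parms) list(-k * max(y[1] - d_lim, 0)^n)
  out <- deSolve::ode(y = c(d = d50_0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  unname(out[, "d"])
}

# event-detection integration of the lumped mill heat balance; returns the
# milling segments (wall-clock start/stop) found by the ODE solver
ode_thermal_schedule <- function(p_watt, thermal, total_min = 180) {
  heat_on <- function(t, y, parms) {
    list(60 * (thermal$eta_heat * p_watt -
                 thermal$UA_W_K * (y[1] - thermal$T_coolant_C)) / thermal$C_th_J_K)
  }
  heat_off <- function(t, y, parms) {
    list(60 * (-thermal$UA_W_K * (y[1] - thermal$T_coolant_C)) / thermal$C_th_J_K)
  }
  segs <- list()
  wall <- 0; milled <- 0; temp <- thermal$T_start_C
  while (milled < total_min - 1e-9) {
    remaining <- total_min - milled
    root_max <- function(t, y, parms) y[1] - thermal$T_max_C
    out <- deSolve::lsodar(c(T = temp), seq(0, remaining, length.out = 2000),
                           heat_on, parms = NULL, rootfunc = root_max,
                           rtol = 1e-10, atol = 1e-10)
    t_root <- attr(out, "troot")
    dur <- if (length(t_root) > 0) t_root[1] else remaining
    segs[[length(segs) + 1L]] <- c(start = wall, stop = wall + dur)
    milled <- milled + dur; wall <- wall + dur
    if (milled >= total_min - 1e-9) break
    root_restart <- function(t, y, parms) y[1] - thermal$T_restart_C
    out <- deSolve::lsodar(c(T = thermal$T_max_C), seq(0, 1e4, length.out = 2000),
                           heat_off, parms = NULL, rootfunc = root_restart,
                           rtol = 1e-10, atol = 1e-10)
    wall <- wall + attr(out, "troot")[1]
    temp <- thermal$T_restart_C
  }
  do.call(rbind, segs)
}

# two-pass mean / sample-SD
two_pass_stats <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  c(mean = m, sd = s)
}

# granular-temperature root located by dense-grid sign change of the energy
# balance; accurate to the grid resolution
grid_theta <- function(p_w, eps_ht, mu_L, c, db_m, consts = mhd_constants(),
                       n_grid = 1e6) {
  s <- p_w - eps_ht
  g0 <- radial_distribution(c, consts$c_lim)
  rd <- drag_coefficient(c, g0, consts$eps_lub)
  a_lin <- 54 * mu_L * c * rd / db_m^2
  b_col <- (12 / db_m) * sqrt(pi) * (1 - consts$e^2) * g0 * c^2 * consts$rho_b
  hi <- 2 * max(s / a_lin, (s / b_col)^(2 / 3))
  grid <- seq(0, hi, length.out = n_grid)
  f <- a_lin * grid + b_col * grid^1.5 - s
  i <- which(f[-1] >= 0 & f[-n_grid] < 0)[1]
  list(theta = (grid[i] + grid[i + 1]) / 2, step = hi / (n_grid - 1))
}

# noise-free model series on the campaign sampling schedule
model_series <- function(k, n, d_lim, d50_0 = 11.4, times = sampling_times()) {
  tibble::tibble(time_min = times,
                 d50_um = as.numeric(breakage_d50(times, k, n, d_lim, d50_0)))
}
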