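#' Material constants for the microhydrodynamic model
#'
#' Default constants for yttrium-stabilised zirconia (YSZ) beads milling a
#' griseofulvin suspension: restitution coefficient `e` = 0.76, bead density
#' `rho_b` = 6000 kg/m3, bead Young's modulus `Y_b` = 200 GPa and Poisson's
#' ratio `eta_b` = 0.2, drug Young's modulus `Y_p` = 11.5 GPa and Poisson's
#' ratio `eta_p` = 0.3, packing limit `c_lim` = 0.63, initial median drug
#' particle radius `R_p` = 5.7 um, drug volume fraction `phi` = 0.061, mill
#' chamber volume `V_m` = 80 mL, and lubrication cut-off `eps_lub` = 0.01
#' used in the drag coefficient.
#'
#' @param ... Named overrides of individual constants.
#' @return A named list of class `mhd_constants` (strict SI units).
#' @examples
#' mhd_constants()
#' mhd_constants(e = 0.9)
#' @export
mhd_constants <- function(...) {
  consts <- list(
    e = 0.76,
    rho_b = 6000,
    Y_b = 200e9,
    eta_b = 0.2,
    Y_p = 11.5e9,
    eta_p = 0.3,
    c_lim = 0.63,
    R_p = 5.7e-6,
    phi = 0.061,
    V_m = 80e-6,
    eps_lub = 0.01
  )
  over <- list(...)
  bad <- setdiff(names(over), names(consts))
  if (length(bad)) stop("unknown constants: ", paste(bad, collapse = ", "), call. = FALSE)
  consts[names(over)] <- over
  with(consts, {
    stopifnot(e > 0, e <= 1, c_lim > 0, c_lim < 1, rho_b > 0,
              Y_b > 0, Y_p > 0, R_p > 0, phi > 0, V_m > 0, eps_lub > 0)
  })
  structure(consts, class = "mhd_constants")
}

#' Radial distribution function at contact (Lun form)
#'
#' Collision-probability correction for a bead suspension at volumetric
#' loading `c` with packing limit `c_lim`:
#' \deqn{g_0 = [1 - (c/c_{lim})^{1/3}]^{-1}}
#' `g_0` is 1 in the dilute limit and diverges as `c` approaches `c_lim`.
#'
#' @param c Volumetric bead loading(s), `0 <= c < c_lim`.
#' @param c_lim Packing limit (default 0.63).
#' @return Numeric vector `g0 >= 1`.
#' @examples
#' radial_distribution(c(0, 0.35, 0.50))
#' @export
radial_distribution <- function(c, c_lim = 0.63) {
  stopifnot(all(c >= 0))
  if (any(c >= c_lim)) {
    stop("bead loading at or above the packing limit: contact statistics diverge",
         call. = FALSE)
  }
  1 / (1 - (c / c_lim)^(1 / 3))
}

#' Effective drag coefficient of the fluctuating bead assembly
#'
#' Dimensionless drag enhancement over Stokes for a bead suspension,
#' combining the dilute/dense viscous-drag polynomial with a lubrication
#' contribution cut off at a dimensionless gap `eps_lub`:
#' \deqn{R_{diss} = 1 + 3\sqrt{c/2} + (135/64)\,c\ln c +
#'   11.26c(1 - 5.1c + 16.57c^2 - 21.77c^3) - c\,g_0\ln\varepsilon_m}
#'
#' @param c Volumetric bead loading.
#' @param g0 Radial distribution function at contact (default from
#'   [radial_distribution()]).
#' @param eps_lub Lubrication cut-off (default 0.01).
#' @return Dimensionless drag coefficient.
#' @export
drag_coefficient <- function(c, g0 = radial_distribution(c), eps_lub = 0.01) {
  stopifnot(all(c > 0), eps_lub > 0)
  1 + 3 * sqrt(c / 2) + (135 / 64) * c * log(c) +
    11.26 * c * (1 - 5.1 * c + 16.57 * c^2 - 21.77 * c^3) -
    c * g0 * log(eps_lub)
}

# dissipation terms of the granular energy balance, W/m3
.eps_visc <- function(theta, mu_L, c, r_diss, db_m) {
  54 * mu_L * c * theta * r_diss / db_m^2
}
.eps_coll <- function(theta, c, g0, e, rho_b, db_m) {
  (12 / db_m) * sqrt(pi) * (1 - e^2) * g0 * c^2 * rho_b * theta^(3 / 2)
}

#' Solve the granular energy balance for the granular temperature
#'
#' The stirrer power density net of beads-free shearing,
#' `P_w - eps_ht`, is dissipated by liquid-bead viscous friction and by
#' partially inelastic bead-bead collisions:
#' \deqn{\frac{54\mu_L c\,\theta R_{diss}}{D_b^2}
#'   + \frac{12}{D_b}\sqrt{\pi}(1-e^2)g_0c^2\rho_b\,\theta^{3/2}
#'   = P_w - \varepsilon_{ht}}
#' Both terms increase monotonically in the granular temperature `theta`
#' (one third of the bead mean-square fluctuation velocity), so the
#' non-negative root is unique. It is bracketed with [stats::uniroot()] and
#' polished by Newton iteration to a relative energy-balance residual below
#' 1e-10.
#'
#' @param p_w Stirrer power density, W/m3.
#' @param eps_ht Beads-free shearing power density, W/m3 (`p_w >= eps_ht`).
#' @param mu_L Suspension apparent shear viscosity, Pa s.
#' @param c Volumetric bead loading.
#' @param db_m Effective median bead diameter, m.
#' @param consts Material constants, see [mhd_constants()].
#' @return Granular temperature `theta`, m2/s2.
#' @export
granular_temperature <- function(p_w, eps_ht, mu_L, c, db_m,
                                 consts = mhd_constants()) {
  stopifnot(mu_L > 0, c > 0, db_m > 0)
  if (p_w < eps_ht) {
    stop("negative dissipation budget: p_w must be at least eps_ht", call. = FALSE)
  }
  s <- p_w - eps_ht
  if (s == 0) return(0)
  g0 <- radial_distribution(c, consts$c_lim)
  rd <- drag_coefficient(c, g0, consts$eps_lub)
  a_lin <- 54 * mu_L * c * rd / db_m^2
  b_col <- (12 / db_m) * sqrt(pi) * (1 - consts$e^2) * g0 * c^2 * consts$rho_b
  f <- function(th) a_lin * th + b_col * th^(3 / 2) - s
  hi <- 2 * max(s / a_lin, (s / b_col)^(2 / 3))
  while (f(hi) < 0) hi <- hi * 2
  th <- stats::uniroot(f, c(0, hi), tol = hi * 1e-14)$root
  for (i in 1:5) {                       # Newton polish to machine precision
    step <- f(th) / (a_lin + 1.5 * b_col * sqrt(th))
    th <- max(th - step, 0)
  }
  th
}

#' Hertzian bead-contact mechanics at a given granular temperature
#'
#' Average maximum normal force of a bead-bead collision (Hertzian impact
#' averaged over the fluctuation-velocity distribution),
#' \deqn{F_b^n = 1.96\,[Y_b/(1-\eta_b^2)]^{2/5}\rho_b^{3/5}R_b^2\theta^{3/5},}
#' the contact-circle radius
#' \eqn{\alpha_b = [3(1-\eta_b^2)R_bF_b^n/(4Y_b)]^{1/3}} and the maximum
#' contact pressure \eqn{\sigma_b^{max} = 3F_b^n/(2\pi\alpha_b^2)}. All three
#' are zero at `theta = 0` (no collisions).
#'
#' @param theta Granular temperature, m2/s2.
#' @param db_m Bead diameter, m (`R_b = db_m / 2`).
#' @param consts Material constants, see [mhd_constants()].
#' @return A tibble with columns `F_bn` (N), `alpha_b` (m), `sigma_bmax` (Pa).
#' @export
contact_mechanics <- function(theta, db_m, consts = mhd_constants()) {
  stopifnot(all(theta >= 0), db_m > 0)
  r_b <- db_m / 2
  f_bn <- 1.96 * (consts$Y_b / (1 - consts$eta_b^2))^(2 / 5) *
    consts$rho_b^(3 / 5) * r_b^2 * theta^(3 / 5)
  alpha_b <- (3 * (1 - consts$eta_b^2) * r_b * f_bn / (4 * consts$Y_b))^(1 / 3)
  sigma <- ifelse(alpha_b > 0, 3 * f_bn / (2 * pi * alpha_b^2), 0)
  tibble::tibble(F_bn = f_bn, alpha_b = alpha_b, sigma_bmax = sigma)
}

#' Bead oscillation and drug-compression statistics
#'
#' Kinetic-theory collision statistics at granular temperature `theta`:
#' mean bead oscillation speed `u_b = sqrt(8 theta / pi)`, single-bead
#' oscillation frequency `nu = 24 c g0 sqrt(theta/pi) / D_b`, the capture
#' probability `p` of a drug particle of radius `R_p` between two colliding
#' beads, the compression frequency `a = p * nu`, and the pseudo-energy
#' dissipation rate `Pi_sigma_y` (proportional to `theta^1.3`) used as a
#' milling-intensity predictor. The reduced bead-drug contact modulus is
#' `Y_star = [(1-eta_b^2)/Y_b + (1-eta_p^2)/Y_p]^-1`.
#'
#' All outputs vanish at `theta = 0`.
#'
#' @inheritParams contact_mechanics
#' @param c Volumetric bead loading.
#' @return A tibble with columns `u_b` (m/s), `nu` (1/s), `p` (-), `a` (1/s),
#'   `Pi_sigma_y`, `Y_star` (Pa).
#' @export
compression_stats <- function(theta, c, db_m, consts = mhd_constants()) {
  stopifnot(all(theta >= 0), c > 0, c < 1, db_m > 0)
  g0 <- radial_distribution(c, consts$c_lim)
  r_b <- db_m / 2
  u_b <- sqrt(8 * theta / pi)
  nu <- 24 * c * g0 * sqrt(theta / pi) / db_m
  kk <- consts$rho_b * (1 - consts$eta_b^2) / consts$Y_b
  p <- (11.64 / (12 * sqrt(pi))) * (c / (1 - c)) * kk^(2 / 5) *
    (consts$R_p / r_b) * theta^(2 / 5)
  a <- p * nu
  y_star <- 1 / ((1 - consts$eta_b^2) / consts$Y_b +
                   (1 - consts$eta_p^2) / consts$Y_p)
  pi_sy <- 4.46 * c^2 * g0 / (pi^(5 / 2) * consts$phi) *
    (consts$Y_b / (1 - consts$eta_b^2))^(6 / 5) *
    (y_star / consts$Y_p)^(1 / 3) *
    consts$rho_b^(4 / 5) * (consts$R_p / r_b^2) * theta^(13 / 10)
  tibble::tibble(u_b = u_b, nu = nu, p = p, a = a,
                 Pi_sigma_y = pi_sy, Y_star = y_star)
}

#' Drug-particle compression frequency, closed form
#'
#' Independent closed-form route to the compression frequency
#' \deqn{a = \frac{11.64\,c^2 g_0}{\pi(1-c)}
#'   \left[\frac{\rho_b(1-\eta_b^2)}{Y_b}\right]^{2/5}
#'   \frac{R_p}{R_b^2}\,\theta^{9/10},}
#' algebraically equal to `p * nu` from [compression_stats()]; kept as a
#' separate code path for cross-checking.
#'
#' @inheritParams compression_stats
#' @return Compression frequency `a`, 1/s.
#' @export
compression_frequency <- function(theta, c, db_m, consts = mhd_constants()) {
  g0 <- radial_distribution(c, consts$c_lim)
  r_b <- db_m / 2
  (11.64 * c^2 * g0 / (pi * (1 - c))) *
    (consts$rho_b * (1 - consts$eta_b^2) / consts$Y_b)^(2 / 5) *
    (consts$R_p / r_b^2) * theta^(9 / 10)
}

#' Compute the full microhydrodynamic state for each run
#'
#' For each run the stirrer power density is `P_w = (P - P_noload) / V_m`;
#' the granular temperature is solved from the energy balance
#' ([granular_temperature()]) and all derived collision parameters are
#' attached ([contact_mechanics()], [compression_stats()]). At the solution
#' `eps_visc + eps_coll + eps_ht = P_w` to better than 1e-8 relative
#' (reported in the `residual_rel` column).
#'
#' @param runs Tibble with one row per run and columns `run_id`, `loading`,
#'   `db_um` (effective bead size, um), `P_W` (average power, W), `mu_L_PaS`
#'   and `eps_ht_W_m3`; an optional `P_noload_W` column (default 0) is
#'   subtracted from the power.
#' @param consts Material constants, see [mhd_constants()].
#' @return A tibble with columns `run_id`, `P_w`, `theta`, `g0`, `R_diss`,
#'   `u_b`, `nu`, `p`, `F_bn`, `alpha_b`, `sigma_bmax`, `a`, `Pi_sigma_y`,
#'   `eps_visc`, `eps_coll`, `residual_rel` (SI units).
#' @export
compute_mhd_state <- function(runs, consts = mhd_constants()) {
  need <- c("run_id", "loading", "db_um", "P_W", "mu_L_PaS", "eps_ht_W_m3")
  missing <- setdiff(need, names(runs))
  if (length(missing)) {
    stop("runs table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  p_noload <- if ("P_noload_W" %in% names(runs)) runs$P_noload_W else 0
  purrr::pmap_dfr(
    list(runs$run_id, runs$loading, runs$db_um, runs$P_W, p_noload,
         runs$mu_L_PaS, runs$eps_ht_W_m3),
    function(id, c_load, db_um, p_watt, p0_watt, mu, eps_ht) {
      db_m <- db_um * 1e-6
      p_w <- (p_watt - p0_watt) / consts$V_m
      g0 <- radial_distribution(c_load, consts$c_lim)
      rd <- drag_coefficient(c_load, g0, consts$eps_lub)
      th <- granular_temperature(p_w, eps_ht, mu, c_load, db_m, consts)
      cm <- contact_mechanics(th, db_m, consts)
      cs <- compression_stats(th, c_load, db_m, consts)
      ev <- .eps_visc(th, mu, c_load, rd, db_m)
      ec <- .eps_coll(th, c_load, g0, consts$e, consts$rho_b, db_m)
      tibble::tibble(
        run_id = id, P_w = p_w, theta = th, g0 = g0, R_diss = rd,
        u_b = cs$u_b, nu = cs$nu, p = cs$p,
        F_bn = cm$F_bn, alpha_b = cm$alpha_b, sigma_bmax = cm$sigma_bmax,
        a = cs$a, Pi_sigma_y = cs$Pi_sigma_y,
        eps_visc = ev, eps_coll = ec,
        residual_rel = if (p_w > 0) abs(ev + ec + eps_ht - p_w) / p_w else 0
      )
    }
  )
}
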