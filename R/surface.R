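#' Ground-truth response surface of the synthetic milling study
#'
#' The synthetic-study generator draws its "true" breakage parameters from
#' log-linear response maps in (log omega, log c, log Db) with an
#' omega-by-c interaction, calibrated once by ordinary least squares against
#' the 24 bundled training-run fits ([reference_kinetics()]): log k is
#' regressed on the log factors, while n and d_lim are regressed on the same
#' regressors on their natural scale. Predictions are clipped to the
#' plausibility envelopes k in [0.1, 5.5] um^(1-n)/min, n in [1.1, 2.8],
#' d_lim in [0.05, 0.16] um.
#'
#' Power and viscosity responses are generated with the directions observed
#' experimentally: power increases with speed and loading (with a weak
#' positive bead-size term), viscosity decreases with speed and loading and
#' increases with bead size, clipped to 0.060-0.120 Pa s.
#'
#' @param noise_cv Relative SD of replicate d50 measurements (multiplicative
#'   lognormal noise), default 0.03.
#' @param eps_ht_W_m3 Beads-free shearing power density, W/m3.
#' @return Object of class `mill_surface`: calibrated coefficient vectors,
#'   envelopes, power/viscosity map parameters, `noise_cv` and `eps_ht_W_m3`.
#' @export
default_surface <- function(noise_cv = 0.03, eps_ht_W_m3 = 5e4) {
  stopifnot(noise_cv >= 0, eps_ht_W_m3 >= 0)
  ref <- reference_kinetics()
  cond <- parse_run_identifier(ref$identifier)
  cond$db_um <- effective_bead_size(cond$x100, cond$x200, cond$x400)
  X <- stats::model.matrix(
    ~ log(omega_rpm) * log(loading) + log(db_um), data = cond
  )
  beta <- function(y) stats::coef(stats::lm.fit(X, y))
  structure(
    list(
      coef_logk = beta(log(ref$k)),
      coef_n = beta(ref$n),
      coef_dlim = beta(ref$d_lim_um),
      envelopes = list(k = c(0.1, 5.5), n = c(1.1, 2.8), d_lim = c(0.05, 0.16)),
      power = list(P0_W = 60, ref_omega = 3000, ref_c = 0.425, ref_db = 194,
                   exp_omega = 2.5, exp_c = 1.0, exp_db = 0.12),
      viscosity = list(mu0_PaS = 0.085, exp_omega = -0.45, exp_c = -0.25,
                       exp_db = 0.10, range_PaS = c(0.060, 0.120)),
      rho_susp_kg_m3 = 1050,
      eps_ht_W_m3 = eps_ht_W_m3,
      noise_cv = noise_cv
    ),
    class = "mill_surface"
  )
}

.surface_design_matrix <- function(cond) {
  stats::model.matrix(~ log(omega_rpm) * log(loading) + log(db_um), data = cond)
}

#' Map milling conditions to ground-truth breakage parameters
#'
#' Deterministic evaluation of the calibrated surface at the given
#' conditions. The map is strictly increasing in stirrer speed and bead
#' loading and non-increasing in bead size for `k` over the design region;
#' predictions are clipped to the surface's envelopes, and values outside
#' the canonical plausibility envelopes raise a configuration error.
#'
#' @param cond Data frame with columns `omega_rpm`, `loading` and `db_um`
#'   (or `x100`, `x200`, `x400` from which the effective bead size is
#'   computed).
#' @param surface A `mill_surface`, see [default_surface()].
#' @return `cond` with added columns `k_true`, `n_true`, `d_lim_true_um`.
#' @export
sample_true_params <- function(cond, surface = default_surface()) {
  stopifnot(inherits(surface, "mill_surface"))
  cond <- tibble::as_tibble(cond)
  if (!"db_um" %in% names(cond)) {
    cond$db_um <- effective_bead_size(cond$x100, cond$x200, cond$x400)
  }
  stopifnot(all(c("omega_rpm", "loading") %in% names(cond)),
            all(is.finite(unlist(surface$coef_logk))))
  X <- .surface_design_matrix(cond)
  clip <- function(x, env) pmin(pmax(x, env[1]), env[2])
  env <- surface$envelopes
  k <- clip(exp(drop(X %*% surface$coef_logk)), env$k)
  n <- clip(drop(X %*% surface$coef_n), env$n)
  dl <- clip(drop(X %*% surface$coef_dlim), env$d_lim)
  canonical <- list(k = c(0.1, 5.5), n = c(1.1, 2.8), d_lim = c(0.05, 0.16))
  ok <- k >= canonical$k[1] & k <= canonical$k[2] &
    n >= canonical$n[1] & n <= canonical$n[2] &
    dl >= canonical$d_lim[1] & dl <= canonical$d_lim[2]
  if (!all(ok)) {
    stop("surface generated parameters outside the plausibility envelopes; ",
         "check the surface configuration", call. = FALSE)
  }
  dplyr::mutate(cond, k_true = k, n_true = n, d_lim_true_um = dl)
}

#' Synthetic bulk responses (power, viscosity, density) of a run
#'
#' Power follows `P0 * (omega/ref)^a * (c/ref)^b * (Db/ref)^g` with a weak
#' positive bead-size exponent; viscosity follows a power law decreasing in
#' speed and loading and increasing in bead size, clipped to the plausible
#' 0.060-0.120 Pa s range. Deterministic (measurement noise on bulk
#' responses is not modelled).
#'
#' @inheritParams sample_true_params
#' @return `cond` with added columns `P_W`, `P_noload_W`, `mu_L_PaS`,
#'   `rho_susp_kg_m3`, `eps_ht_W_m3`.
#' @export
synth_bulk_responses <- function(cond, surface = default_surface()) {
  stopifnot(inherits(surface, "mill_surface"))
  cond <- tibble::as_tibble(cond)
  pw <- surface$power
  vs <- surface$viscosity
  P <- pw$P0_W * (cond$omega_rpm / pw$ref_omega)^pw$exp_omega *
    (cond$loading / pw$ref_c)^pw$exp_c *
    (cond$db_um / pw$ref_db)^pw$exp_db
  mu <- vs$mu0_PaS * (cond$omega_rpm / pw$ref_omega)^vs$exp_omega *
    (cond$loading / pw$ref_c)^vs$exp_c *
    (cond$db_um / pw$ref_db)^vs$exp_db
  mu <- pmin(pmax(mu, vs$range_PaS[1]), vs$range_PaS[2])
  dplyr::mutate(cond, P_W = P, P_noload_W = 0, mu_L_PaS = mu,
                rho_susp_kg_m3 = surface$rho_susp_kg_m3,
                eps_ht_W_m3 = surface$eps_ht_W_m3)
}
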