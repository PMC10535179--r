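#' Characteristic sizes of the as-received milling beads
#'
#' Laser-diffraction characteristic sizes (`d10`, `d50`, `d90`) of the three
#' narrowly sized yttrium-stabilised zirconia (YSZ) bead lots used in the
#' griseofulvin milling campaign, together with the median sizes used for the
#' microhydrodynamic calculations. The distribution span is
#' `(d90 - d10) / d50`.
#'
#' `mhd_d50_um` is the measured median reported for the microhydrodynamic
#' analysis; for the 400 um lot it differs by 2 um from the tabulated `d50_um`
#' (403 vs 405), an inconsistency in the source data that is preserved here
#' rather than silently merged.
#'
#' @return A tibble with one row per nominal bead size and columns
#'   `nominal_um`, `d10_um`, `d50_um`, `d90_um`, `mhd_d50_um`.
#' @examples
#' bead_size_table()
#' @export
bead_size_table <- function() {
  tibble::tibble(
    nominal_um = c(100, 200, 400),
    d10_um     = c(87, 140, 293),
    d50_um     = c(112, 194, 405),
    d90_um     = c(145, 263, 560),
    mhd_d50_um = c(112, 194, 403)
  )
}

#' Feed (unmilled) griseofulvin particle sizes
#'
#' Characteristic sizes of the as-received micronised griseofulvin feed:
#' d10 = 4.30 um, d50 = 11.4 um, d90 = 23.5 um.
#'
#' @return A named numeric vector with elements `d10_um`, `d50_um`, `d90_um`.
#' @export
feed_psd <- function() {
  c(d10_um = 4.30, d50_um = 11.4, d90_um = 23.5)
}

#' Fitted nth-order breakage parameters for the 24 training runs
#'
#' Reference breakage-kinetics fits (rate constant `k`, order `n`, limiting
#' median size `d_lim`) with their fit statistics for the 24 full-factorial
#' training runs of the griseofulvin milling campaign. These values are used
#' to calibrate the synthetic ground-truth surface (see [default_surface()])
#' and as targets in the empirical-prediction example.
#'
#' Units: `k` in um^(1-n)/min, `d_lim_um` in um.
#'
#' @return A tibble with columns `run_id`, `identifier`, `k`, `n`, `d_lim_um`,
#'   `R2`, `adjR2`, `SSR`.
#' @export
reference_kinetics <- function() {
  tibble::tibble(
    run_id = as.character(1:24),
    identifier = c(
      "3000 0.35 100-0-0", "3000 0.35 50-50-0", "3000 0.35 0-100-0",
      "3000 0.35 50-0-50", "3000 0.35 0-50-50", "3000 0.35 0-0-100",
      "3000 0.50 100-0-0", "3000 0.50 50-50-0", "3000 0.50 0-100-0",
      "3000 0.50 50-0-50", "3000 0.50 0-50-50", "3000 0.50 0-0-100",
      "4000 0.35 100-0-0", "4000 0.35 50-50-0", "4000 0.35 0-100-0",
      "4000 0.35 50-0-50", "4000 0.35 0-50-50", "4000 0.35 0-0-100",
      "4000 0.50 100-0-0", "4000 0.50 50-50-0", "4000 0.50 0-100-0",
      "4000 0.50 50-0-50", "4000 0.50 0-50-50", "4000 0.50 0-0-100"
    ),
    k = c(
      0.292, 0.191, 0.214, 0.116, 0.248, 0.210,
      1.54, 1.46, 1.39, 1.18, 1.28, 0.85,
      1.22, 1.17, 0.571, 0.511, 0.808, 0.497,
      5.10, 4.65, 3.08, 2.42, 1.87, 1.53
    ),
    n = c(
      1.62, 2.25, 2.07, 2.26, 2.01, 2.37,
      1.89, 1.91, 1.92, 2.01, 1.99, 1.85,
      1.18, 1.27, 1.88, 2.01, 1.76, 2.10,
      2.46, 2.71, 2.64, 2.28, 2.23, 1.92
    ),
    d_lim_um = c(
      0.148, 0.083, 0.107, 0.048, 0.117, 0.076,
      0.130, 0.139, 0.142, 0.138, 0.141, 0.150,
      0.133, 0.136, 0.140, 0.130, 0.156, 0.127,
      0.119, 0.113, 0.114, 0.126, 0.128, 0.153
    ),
    R2 = c(
      0.992, 0.965, 0.978, 0.960, 0.976, 0.954,
      0.969, 0.968, 0.973, 0.980, 0.990, 0.996,
      0.890, 0.938, 0.981, 0.986, 0.997, 0.976,
      0.996, 0.995, 0.994, 0.997, 0.995, 0.990
    ),
    adjR2 = c(
      0.991, 0.958, 0.974, 0.953, 0.972, 0.946,
      0.964, 0.962, 0.968, 0.976, 0.988, 0.995,
      0.870, 0.927, 0.977, 0.983, 0.997, 0.971,
      0.995, 0.994, 0.992, 0.996, 0.994, 0.989
    ),
    SSR = c(
      0.066, 0.263, 0.167, 0.310, 0.183, 0.343,
      0.189, 0.184, 0.158, 0.123, 0.062, 0.027,
      0.777, 0.427, 0.149, 0.109, 0.018, 0.181,
      0.014, 0.018, 0.025, 0.013, 0.024, 0.063
    )
  )
}

#' Bead price and wear reference data
#'
#' Vendor small-quantity bead prices and six-hour zirconium contamination
#' levels (a proxy for bead wear) for the three narrowly sized YSZ bead lots,
#' together with the wear rates used in the capital-cost comparison for a
#' small media mill charged with 0.196 kg of beads.
#'
#' @return A tibble with columns `nominal_um`, `price_usd_kg`,
#'   `zr_ug_per_g_6h`, `wear_mg_day`, `wear_pct_day`.
#' @seealso [bead_economics()] for the derived lifetimes and capital costs.
#' @export
bead_wear_table <- function() {
  tibble::tibble(
    nominal_um     = c(100, 200, 400),
    price_usd_kg   = c(549.3, 312.7, 160.2),
    zr_ug_per_g_6h = c(307, 453, 832),
    wear_mg_day    = c(35.0, 51.6, 94.8),
    wear_pct_day   = c(0.0178, 0.0263, 0.0484)
  )
}
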