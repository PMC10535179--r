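#' Simulate one noisy particle-size time series
#'
#' Forward-simulates the nth-order breakage law at the given sampling times
#' and applies multiplicative lognormal measurement noise with relative SD
#' `noise_cv` (mean-one, mimicking replicate laser-diffraction scatter).
#' `d10` and `d90` are scaled copies of the `d50` trajectory using the feed
#' ratios d10/d50 and d90/d50; the replicate-SD column is
#' `noise_cv * value`.
#'
#' @param k,n,d_lim Ground-truth breakage parameters (um^(1-n)/min, -, um).
#' @param times Sampling times in minutes, strictly increasing, starting at 0.
#' @param seed Integer seed; identical seeds give identical series.
#' @param noise_cv Relative SD of the multiplicative noise (>= 0).
#' @param feed Named vector of feed sizes as from [feed_psd()].
#' @return A tibble with columns `time_min`, `d10_um`, `d50_um`, `d90_um`,
#'   `sd_um`.
#' @export
simulate_run <- function(k, n, d_lim, times = sampling_times(), seed = 1L,
                         noise_cv = 0.03, feed = feed_psd()) {
  stopifnot(noise_cv >= 0, feed["d50_um"] > d_lim)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  d50_true <- as.numeric(breakage_d50(times, k, n, d_lim, feed[["d50_um"]]))
  noise <- rep(1, length(times))
  if (noise_cv > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  d50 <- d50_true * noise
  tibble::tibble(
    time_min = times,
    d10_um = d50 * feed[["d10_um"]] / feed[["d50_um"]],
    d50_um = d50,
    d90_um = d50 * feed[["d90_um"]] / feed[["d50_um"]],
    sd_um = noise_cv * d50
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# deterministic per-run child seed below 2^31
.child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 131L + 7919 * index) %% 2147483629)
}

#' Simulate a complete synthetic milling study
#'
#' Generates every layer the downstream analysis consumes: ground-truth
#' breakage parameters from the calibrated response surface, synthetic power
#' and viscosity responses, intermittent thermal-cycle schedules under the
#' 35 C cutoff, and noisy particle-size time series at the campaign's
#' sampling schedule. Per-run child seeds are derived deterministically from
#' the design's master seed, so the whole study is reproducible.
#'
#' @param design A `mill_design` from [build_design()].
#' @param surface A `mill_surface`, see [default_surface()].
#' @param thermal Thermal parameters, see [thermal_defaults()].
#' @param noise_cv Overrides the surface's replicate noise CV if not `NULL`.
#' @return Object of class `mill_study`: list with
#'   \describe{
#'     \item{runs}{design tibble with ground truth, bulk responses and
#'       `n_mc` (total milling cycles).}
#'     \item{timeseries}{long tibble of noisy size series for all runs.}
#'     \item{schedules}{named list of `thermal_schedule` objects.}
#'     \item{seed, surface, thermal}{the generating configuration.}
#'   }
#' @examples
#' study <- simulate_study(build_design(seed = 7))
#' dplyr::glimpse(study$runs)
#' @export
simulate_study <- function(design = build_design(), surface = default_surface(),
                           thermal = thermal_defaults(), noise_cv = NULL) {
  stopifnot(inherits(design, "mill_design"))
  times <- attr(design, "sampling_times_min")
  seed <- attr(design, "seed")
  cv <- if (is.null(noise_cv)) surface$noise_cv else noise_cv
  runs <- sample_true_params(design, surface)
  runs <- synth_bulk_responses(runs, surface)
  schedules <- purrr::map(seq_len(nrow(runs)), function(i) {
    simulate_thermal_cycles(runs$P_W[i], thermal, total_min = max(times))
  })
  names(schedules) <- runs$run_id
  runs$n_mc <- purrr::map_int(schedules, function(s) as.integer(s$n_cycles))
  timeseries <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    ts <- simulate_run(
      runs$k_true[i], runs$n_true[i], runs$d_lim_true_um[i],
      times = times, seed = .child_seed(seed, i), noise_cv = cv
    )
    dplyr::mutate(ts, run_id = runs$run_id[i], .before = 1)
  })
  structure(
    list(runs = runs, timeseries = timeseries, schedules = schedules,
         seed = seed, surface = surface, thermal = thermal, noise_cv = cv),
    class = "mill_study"
  )
}
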