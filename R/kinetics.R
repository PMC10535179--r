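#' Evaluate the nth-order breakage model
#'
#' Median-size decay law for wet media milling:
#' \deqn{d_{50}(t) = d_{lim} + [(d_{50,0}-d_{lim})^{1-n} - (1-n)kt]^{1/(1-n)}}
#' with rate constant `k` (um^(1-n)/min), breakage order `n` and limiting
#' median size `d_lim`. For `|n - 1| < 1e-8` the exponential limit
#' `d_lim + (d50_0 - d_lim) exp(-kt)` is used. For `n < 1` the bracket reaches
#' zero at a finite extinction time; beyond it the function returns `d_lim`
#' and marks the affected times in the `"extinct"` attribute.
#'
#' @param t Milling times, minutes (non-negative).
#' @param k Breakage rate constant, um^(1-n)/min.
#' @param n Breakage order.
#' @param d_lim Limiting median size, um.
#' @param d50_0 Initial (feed) median size, um; must exceed `d_lim`.
#' @return Numeric vector of median sizes (um); logical attribute `"extinct"`
#'   flags times past the finite extinction point when `n < 1`.
#' @examples
#' breakage_d50(c(0, 1, 5), k = 5.10, n = 2.46, d_lim = 0.119, d50_0 = 11.4)
#' @export
breakage_d50 <- function(t, k, n, d_lim, d50_0) {
  stopifnot(all(t >= 0), k >= 0, d_lim >= 0, d50_0 > d_lim)
  if (abs(n - 1) < 1e-8) {
    out <- d_lim + (d50_0 - d_lim) * exp(-k * t)
    attr(out, "extinct") <- rep(FALSE, length(t))
    return(out)
  }
  bracket <- (d50_0 - d_lim)^(1 - n) - (1 - n) * k * t
  extinct <- bracket <= 0          # only reachable for n < 1
  out <- numeric(length(t))
  out[!extinct] <- d_lim + bracket[!extinct]^(1 / (1 - n))
  out[extinct] <- d_lim
  attr(out, "extinct") <- extinct
  out
}

#' Closed-form time for the model median size to reach a target
#'
#' Inverts the nth-order decay law; used as an oracle for the
#' interpolation-based [time_to_size()].
#'
#' @inheritParams breakage_d50
#' @param target Target median size, um (`d_lim < target < d50_0`).
#' @return Time in minutes.
#' @export
breakage_time_to <- function(target, k, n, d_lim, d50_0) {
  stopifnot(target > d_lim, target < d50_0, k > 0)
  if (abs(n - 1) < 1e-8) {
    return(log((d50_0 - d_lim) / (target - d_lim)) / k)
  }
  ((d50_0 - d_lim)^(1 - n) - (target - d_lim)^(1 - n)) / ((1 - n) * k)
}

# log-scale residuals of the breakage model; par = c(log k, n, d_lim)
.breakage_resid <- function(par, t, d50, d50_0) {
  pred <- breakage_d50(t, exp(par[1]), par[2], par[3], d50_0)
  log(pmax(pred, 1e-12)) - log(d50)
}

#' Fit the nth-order breakage model to one size time series
#'
#' Estimates `(k, n, d_lim)` by Levenberg-Marquardt least squares on the
#' log-transformed median sizes, with `d50_0` fixed at the t = 0 observation
#' (removing its degeneracy with `d_lim`) and `d_lim` constrained below the
#' final measured median size. A small deterministic multi-start grid guards
#' against local minima; the start with the lowest log-scale SSR wins.
#'
#' Fit statistics (`R2`, `adjR2` with 3 parameters, `SSR`) are computed on
#' the log scale, consistently with the objective; linear-scale versions are
#' stored alongside (`R2_linear`, `SSR_linear`).
#'
#' @param series Data frame with columns `time_min` and `d50_um`; at least 5
#'   time points, first at t = 0 (the feed), strictly positive sizes.
#' @param n_bounds Box constraints for the breakage order.
#' @return Object of class `breakage_fit`: a list with elements `k`, `n`,
#'   `d_lim`, `d50_0`, `R2`, `adjR2`, `SSR`, `R2_linear`, `SSR_linear`,
#'   `boundary_k` (TRUE when the series carries no breakage signal: k
#'   collapsed to its lower bound or the sizes have zero variance),
#'   `converged` and the fitted `data`.
#' @examples
#' ts <- tibble::tibble(
#'   time_min = sampling_times(),
#'   d50_um = breakage_d50(sampling_times(), 1, 2, 0.12, 11.4)
#' )
#' fit <- fit_breakage(ts)
#' glance(fit)
#' @export
fit_breakage <- function(series, n_bounds = c(0.5, 4)) {
  stopifnot(all(c("time_min", "d50_um") %in% names(series)))
  t <- series$time_min
  d50 <- series$d50_um
  if (length(t) < 5) stop("need at least 5 time points", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing", call. = FALSE)
  if (any(d50 <= 0)) stop("sizes must be positive", call. = FALSE)
  if (t[1] != 0) stop("first observation must be the feed at t = 0", call. = FALSE)
  d50_0 <- d50[1]
  d_final <- d50[length(d50)]
  d_lim_hi <- min(d_final * 0.999, d50_0 * 0.999)

  lower <- c(log(1e-6), n_bounds[1], 1e-6)
  upper <- c(log(1e3), n_bounds[2], d_lim_hi)
  starts <- expand.grid(
    logk = log(c(0.2, 2)),
    n = c(1.2, 2.0, 2.6),
    d_lim = c(0.5, 0.9) * d_lim_hi
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    res <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper,
      fn = .breakage_resid, t = t[-1], d50 = d50[-1], d50_0 = d50_0,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ), silent = TRUE)
    if (inherits(res, "try-error")) next
    ssr <- sum(res$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-15) best <- list(fit = res, ssr = ssr)
  }
  if (is.null(best)) {
    stop("breakage fit failed to converge from any start", call. = FALSE)
  }
  par <- best$fit$par
  k <- exp(par[1]); n <- par[2]; d_lim <- par[3]
  obs_log <- log(d50[-1])
  sst <- sum((obs_log - mean(obs_log))^2)
  ssr <- best$ssr
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  n_obs <- length(obs_log)
  adj <- 1 - (1 - r2) * (n_obs - 1) / (n_obs - 3 - 1)
  pred_lin <- breakage_d50(t[-1], k, n, d_lim, d50_0)
  ssr_lin <- sum((pred_lin - d50[-1])^2)
  sst_lin <- sum((d50[-1] - mean(d50[-1]))^2)
  structure(
    list(
      k = k, n = n, d_lim = d_lim, d50_0 = d50_0,
      R2 = r2, adjR2 = adj, SSR = ssr,
      R2_linear = if (sst_lin > 0) 1 - ssr_lin / sst_lin else 0,
      SSR_linear = ssr_lin,
      boundary_k = k <= 1e-5 || sst == 0,
      converged = best$fit$info %in% 1:4,
      data = tibble::as_tibble(series[, c("time_min", "d50_um")])
    ),
    class = "breakage_fit"
  )
}

#' Fit the breakage model to every run of a study
#'
#' @param timeseries Long tibble with columns `run_id`, `time_min`, `d50_um`.
#' @return A tibble with one row per run: the fitted parameters and log-scale
#'   fit statistics of [fit_breakage()].
#' @export
fit_study <- function(timeseries) {
  stopifnot(all(c("run_id", "time_min", "d50_um") %in% names(timeseries)))
  timeseries |>
    dplyr::group_by(.data$run_id) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_breakage(df)
      tibble::tibble(
        k = f$k, n = f$n, d_lim_um = f$d_lim, d50_0_um = f$d50_0,
        R2 = f$R2, adjR2 = f$adjR2, SSR = f$SSR, converged = f$converged
      )
    }) |>
    dplyr::ungroup()
}

#' Interpolated time for the measured median size to reach a target
#'
#' Builds a shape-preserving piecewise-cubic Hermite (pchip) interpolant of
#' the d50 time series and locates the first downward crossing of `target`
#' by bracketed root finding (to 1e-6 min). If an observation equals the
#' target exactly, that time is returned. If the series never reaches the
#' target the result is `NA` with `crossed = FALSE` rather than an error.
#'
#' @param series Data frame with columns `time_min`, `d50_um` (times strictly
#'   increasing).
#' @param target Target median size, um (default 0.2 um).
#' @return One-row tibble with `t_cross_min` and `crossed`.
#' @export
time_to_size <- function(series, target = 0.2) {
  stopifnot(all(c("time_min", "d50_um") %in% names(series)))
  t <- series$time_min
  y <- series$d50_um
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing", call. = FALSE)
  hit <- which(y == target)
  if (length(hit) > 0) {
    return(tibble::tibble(t_cross_min = t[min(hit)], crossed = TRUE))
  }
  f <- pracma::pchipfun(t, y)
  g <- function(x) f(x) - target
  # earliest interval whose endpoints bracket the target wins
  for (i in seq_len(length(t) - 1L)) {
    if ((y[i] - target) * (y[i + 1] - target) < 0) {
      root <- stats::uniroot(g, c(t[i], t[i + 1]), tol = 1e-9)$root
      return(tibble::tibble(t_cross_min = root, crossed = TRUE))
    }
  }
  tibble::tibble(t_cross_min = NA_real_, crossed = FALSE)
}

#' Count milling cycles begun by a given milling time
#'
#' Counts the milling segments of a thermal schedule whose start (in
#' cumulative milling-time coordinates, i.e. excluding cooling pauses) is at
#' or before `t`. A segment starting exactly at `t` counts.
#'
#' @param schedule A `thermal_schedule` from [simulate_thermal_cycles()].
#' @param t Cumulative milling time, minutes; must lie within the schedule's
#'   total milling time.
#' @return Integer cycle count (>= 1).
#' @export
cycles_at_time <- function(schedule, t) {
  stopifnot(inherits(schedule, "thermal_schedule"))
  if (!is.finite(t) || t < 0) stop("t must be a non-negative milling time", call. = FALSE)
  dur <- schedule$cycles$mill_stop - schedule$cycles$mill_start
  total <- sum(dur)
  if (t > total + 1e-9) stop("t exceeds the total milling time", call. = FALSE)
  starts <- cumsum(c(0, dur[-length(dur)]))
  sum(starts <= t + 1e-12)
}

#' Summary statistics of breakage fits across runs
#'
#' Mean and sample standard deviation (n - 1 denominator) of the fitted
#' `k`, `n` and `d_lim` over a set of runs.
#'
#' @param fits Data frame with columns `k`, `n` and `d_lim_um` (one row per
#'   run), e.g. from [fit_study()] or [reference_kinetics()].
#' @return A tibble with columns `parameter`, `mean`, `sd`.
#' @examples
#' summarize_fits(reference_kinetics())
#' @export
summarize_fits <- function(fits) {
  stopifnot(all(c("k", "n", "d_lim_um") %in% names(fits)), nrow(fits) >= 2)
  tibble::tibble(
    parameter = c("k", "n", "d_lim_um"),
    mean = c(mean(fits$k), mean(fits$n), mean(fits$d_lim_um)),
    sd = c(stats::sd(fits$k), stats::sd(fits$n), stats::sd(fits$d_lim_um))
  )
}

#' Ratio of breakage rate constants between two runs
#'
#' @param fits Data frame with columns `run_id` and `k`.
#' @param run_a,run_b Run identifiers; the result is `k[run_a] / k[run_b]`.
#' @return Numeric scalar.
#' @examples
#' k_ratio(reference_kinetics(), "19", "24")
#' @export
k_ratio <- function(fits, run_a, run_b) {
  ka <- fits$k[match(run_a, fits$run_id)]
  kb <- fits$k[match(run_b, fits$run_id)]
  if (anyNA(c(ka, kb))) stop("run not found in fits", call. = FALSE)
  ka / kb
}
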