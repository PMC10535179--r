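#' Min-max normalize a metric across runs
#'
#' `(v - min) / (max - min)`: the best (smallest) value maps to 0, the worst
#' to 1. A degenerate set where all values are equal maps to all zeros with
#' a warning, so single-condition comparisons stay defined.
#'
#' @param values Numeric vector (length >= 2).
#' @return Normalized values in `[0, 1]`.
#' @examples
#' normalize_metric(c(2, 4, 10))
#' @export
normalize_metric <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  rng <- range(values)
  if (diff(rng) == 0) {
    warning("all values equal: degenerate normalization, returning zeros",
            call. = FALSE)
    return(rep(0, length(values)))
  }
  (values - rng[1]) / diff(rng)
}

#' Process merit score from normalized metrics
#'
#' \deqn{\mathrm{Merit} = 100 / 10^{(\bar m + \bar P + \bar N_{d50})/3}}
#' where the three arguments are min-max normalized metrics in `[0, 1]`:
#' a cycle-time measure (normalized `1/k` or normalized `t_d50`), the power,
#' and the number of intermittent milling cycles needed to reach a 0.2 um
#' median size. The score is strictly decreasing in each argument and ranges
#' from 10 (all metrics worst) to 100 (all metrics best).
#'
#' @param norm_rate Normalized cycle-time metric (`1/k` or `t_d50`).
#' @param norm_power Normalized power.
#' @param norm_cycles Normalized `N_d50`.
#' @return Merit score in `[10, 100]`.
#' @examples
#' merit_score(0, 0, 0)  # 100
#' merit_score(1, 1, 1)  # 10
#' @export
merit_score <- function(norm_rate, norm_power, norm_cycles) {
  args <- cbind(norm_rate, norm_power, norm_cycles)
  if (any(args < 0 | args > 1)) {
    stop("normalized inputs must lie in [0, 1]", call. = FALSE)
  }
  100 / 10^((norm_rate + norm_power + norm_cycles) / 3)
}

#' Merit-score table for a set of runs
#'
#' Normalizes `1/k`, `t_d50`, `P` and `N_d50` across the comparison set and
#' computes both merit-score variants: one using the inverse breakage rate
#' constant as the cycle-time measure, one using the specific time `t_d50`.
#'
#' @param metrics Tibble with columns `run_id`, `k`, `t_d50_min`, `P_W`,
#'   `N_d50` (one row per run in the comparison set).
#' @return `metrics` plus normalized columns (`inv_k_norm`, `t_d50_norm`,
#'   `P_norm`, `N_d50_norm`) and `merit_score_k`, `merit_score_t`.
#' @export
merit_table <- function(metrics) {
  need <- c("run_id", "k", "t_d50_min", "P_W", "N_d50")
  stopifnot(all(need %in% names(metrics)), nrow(metrics) >= 2)
  stopifnot(all(metrics$k > 0), all(metrics$t_d50_min > 0), all(metrics$P_W > 0),
            all(metrics$N_d50 >= 1))
  dplyr::mutate(
    tibble::as_tibble(metrics),
    inv_k_norm = normalize_metric(1 / .data$k),
    t_d50_norm = normalize_metric(.data$t_d50_min),
    P_norm = normalize_metric(.data$P_W),
    N_d50_norm = normalize_metric(.data$N_d50),
    merit_score_k = merit_score(.data$inv_k_norm, .data$P_norm, .data$N_d50_norm),
    merit_score_t = merit_score(.data$t_d50_norm, .data$P_norm, .data$N_d50_norm)
  )
}

#' Particle-size distribution span
#'
#' `(d90 - d10) / d50`, a dimensionless width measure of a size
#' distribution.
#'
#' @param d10,d50,d90 Characteristic sizes (same units, `d10 < d50 < d90`).
#' @return Span (dimensionless).
#' @examples
#' span(293, 405, 560)
#' @export
span <- function(d10, d50, d90) {
  stopifnot(all(d10 > 0))
  if (any(!(d10 < d50 & d50 < d90))) {
    stop("sizes must satisfy d10 < d50 < d90", call. = FALSE)
  }
  (d90 - d10) / d50
}
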