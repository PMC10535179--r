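#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @exportS3Method base::print
print.breakage_fit <- function(x, ...) {
  cat("nth-order breakage fit\n")
  cat(sprintf("  k = %.4g um^(1-n)/min, n = %.3f, d_lim = %.4g um (d50_0 = %.3g um)\n",
              x$k, x$n, x$d_lim, x$d50_0))
  cat(sprintf("  log-scale R2 = %.4f (adj %.4f), SSR = %.4g\n",
              x$R2, x$adjR2, x$SSR))
  if (x$boundary_k) cat("  note: k at lower bound (no breakage signal)\n")
  invisible(x)
}

#' @export
tidy.breakage_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "n", "d_lim", "d50_0"),
    estimate = c(x$k, x$n, x$d_lim, x$d50_0),
    unit = c("um^(1-n)/min", "", "um", "um")
  )
}

#' @export
glance.breakage_fit <- function(x, ...) {
  tibble::tibble(R2 = x$R2, adjR2 = x$adjR2, SSR = x$SSR,
                 R2_linear = x$R2_linear, SSR_linear = x$SSR_linear,
                 converged = x$converged, boundary_k = x$boundary_k)
}

#' Plot a breakage fit over its data
#'
#' Observed median sizes (points) and the fitted nth-order decay curve
#' (line) on a log y-axis.
#'
#' @param object A `breakage_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breakage_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_min = seq(0, max(object$data$time_min), length.out = 200)
  )
  grid$d50_um <- as.numeric(
    breakage_d50(grid$time_min, object$k, object$n, object$d_lim, object$d50_0)
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_min, y = .data$d50_um)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "milling time (min)", y = expression(d[50] ~ (mu * m)),
                  title = sprintf("k = %.3g, n = %.2f, d_lim = %.3g um",
                                  object$k, object$n, object$d_lim)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method base::print
print.mill_ml_report <- function(x, ...) {
  cat(sprintf("kinetics prediction report (%s predictors)\n", x$mode))
  cat(sprintf("  candidates evaluated: %d\n", nrow(x$scores)))
  cat(sprintf("  selected: %s (test RMSE %.4g, LOO-CV RMSE %.4g)\n",
              x$selected$label, x$scores$test_rmse[x$selected$index],
              x$scores$loo_rmse[x$selected$index]))
  invisible(x)
}

#' @export
tidy.mill_ml_report <- function(x, ...) x$scores

#' @export
glance.mill_ml_report <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, selected = x$selected$label, family = x$selected$family,
    loo_rmse = x$scores$loo_rmse[x$selected$index],
    test_rmse = x$scores$test_rmse[x$selected$index]
  )
}

#' @exportS3Method base::print
print.thermal_schedule <- function(x, ...) {
  cat(sprintf("thermal schedule: %d milling cycle(s), %.0f min milled, P = %.3g W\n",
              x$n_cycles, sum(x$cycles$mill_stop - x$cycles$mill_start), x$p_watt))
  invisible(x)
}

#' @exportS3Method base::print
print.mill_study <- function(x, ...) {
  cat(sprintf("synthetic milling study: %d runs (%d train, %d test), seed %d\n",
              nrow(x$runs), sum(x$runs$role == "train"),
              sum(x$runs$role == "test"), x$seed))
  cat(sprintf("  noise CV %.3g, %d sampling times\n", x$noise_cv,
              length(unique(x$timeseries$time_min))))
  invisible(x)
}

#' Plot the simulated size trajectories of a study
#'
#' @param study A `mill_study` from [simulate_study()].
#' @return A ggplot with one d50 decay curve per run on a log y-axis.
#' @export
plot_study_timeseries <- function(study) {
  stopifnot(inherits(study, "mill_study"))
  ggplot2::ggplot(study$timeseries,
                  ggplot2::aes(x = .data$time_min, y = .data$d50_um,
                               group = .data$run_id, colour = .data$run_id)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "milling time (min)", y = expression(d[50] ~ (mu * m))) +
    ggplot2::theme_minimal()
}

#' Plot merit scores across runs
#'
#' @param merit A tibble from [merit_table()].
#' @param variant `"rate"` (1/k-based) or `"time"` (t_d50-based).
#' @return A ggplot bar chart of merit scores by run.
#' @export
plot_merit <- function(merit, variant = c("rate", "time")) {
  variant <- match.arg(variant)
  col <- if (variant == "rate") "merit_score_k" else "merit_score_t"
  ggplot2::ggplot(merit,
                  ggplot2::aes(x = stats::reorder(.data$run_id, -.data[[col]]),
                               y = .data[[col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "run", y = "merit score") +
    ggplot2::theme_minimal()
}
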