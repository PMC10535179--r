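#' Assemble the feature matrix for kinetics prediction
#'
#' Joins each run's predictors with its fitted breakage parameters
#' (`k`, `n`, `d_lim_um`, the regression targets). Two predictor modes are
#' supported: `"process"` uses the process parameters (`omega_rpm`,
#' `loading`, `x100`, `x200`, `x400`); `"mhd"` uses the microhydrodynamic
#' collision parameters (`sigma_bmax`, `alpha_b`, `a`, `Pi_sigma_y`).
#' Predictors are z-scored on the training rows (test rows reuse the
#' training statistics); zero-variance columns are dropped with a warning.
#' Tree-based models consume the raw (unscaled) features.
#'
#' @param runs Run table with a `role` column (`"train"` / `"test"`) and the
#'   process columns.
#' @param fits Tibble with `run_id`, `k`, `n`, `d_lim_um` for every run.
#' @param mhd Optional tibble from [compute_mhd_state()]; required for
#'   `mode = "mhd"`.
#' @param mode `"process"` or `"mhd"`.
#' @return Object of class `mill_features`: list with raw and scaled
#'   train/test predictor matrices, target matrices, run ids and scaling
#'   statistics.
#' @export
assemble_features <- function(runs, fits, mhd = NULL,
                              mode = c("process", "mhd")) {
  mode <- match.arg(mode)
  stopifnot(all(c("run_id", "role") %in% names(runs)),
            all(c("run_id", "k", "n", "d_lim_um") %in% names(fits)))
  if (mode == "process") {
    cols <- c("omega_rpm", "loading", "x100", "x200", "x400")
    feat <- runs[, c("run_id", "role", cols)]
  } else {
    if (is.null(mhd)) stop("mhd state table required for mode = 'mhd'", call. = FALSE)
    cols <- c("sigma_bmax", "alpha_b", "a", "Pi_sigma_y")
    missing_runs <- setdiff(runs$run_id, mhd$run_id)
    if (length(missing_runs)) {
      stop("missing MHD state for runs: ", paste(missing_runs, collapse = ", "),
           call. = FALSE)
    }
    feat <- dplyr::inner_join(runs[, c("run_id", "role")], mhd[, c("run_id", cols)],
                              by = "run_id")
  }
  feat <- dplyr::inner_join(feat, fits[, c("run_id", "k", "n", "d_lim_um")],
                            by = "run_id")
  tr <- feat[feat$role == "train", ]
  te <- feat[feat$role == "test", ]
  x_tr <- as.matrix(tr[, cols])
  x_te <- as.matrix(te[, cols])
  sds <- apply(x_tr, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance predictor(s): ",
            paste(cols[!keep], collapse = ", "), call. = FALSE)
    x_tr <- x_tr[, keep, drop = FALSE]
    x_te <- x_te[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  mus <- colMeans(x_tr)
  scale_mat <- function(x) sweep(sweep(x, 2, mus), 2, sds, "/")
  y_cols <- c("k", "n", "d_lim_um")
  structure(
    list(
      mode = mode,
      x_train = x_tr, x_test = x_te,
      z_train = scale_mat(x_tr), z_test = scale_mat(x_te),
      y_train = as.matrix(tr[, y_cols]), y_test = as.matrix(te[, y_cols]),
      train_ids = tr$run_id, test_ids = te$run_id,
      center = mus, scale = sds
    ),
    class = "mill_features"
  )
}

#' Candidate model specifications for kinetics prediction
#'
#' A small grid of model families exercised by the selection protocol:
#' ordinary linear regression, ridge, elastic net (mixing 0.1/0.5/0.9,
#' log-spaced penalties), decision trees (depth 1-4, minimum leaf 1/2/4) and
#' gradient boosting. Linear-family models consume standardized predictors;
#' trees and boosting consume raw features. Grids are deliberately small
#' because the training set has 24 runs. Each response is fitted by its own
#' model (one regression per response).
#'
#' @return A list of model specs, each a list with `label`, `family` and a
#'   `fit(x, y)` function returning a `predict(x)` closure.
#' @export
default_candidates <- function() {
  specs <- list()
  add <- function(spec) specs[[length(specs) + 1L]] <<- spec

  add(list(
    label = "linear", family = "linear", scaled = TRUE,
    fit = function(x, y) {
      cf <- stats::coef(stats::lm.fit(cbind(1, x), y))
      cf[is.na(cf)] <- 0   # aliased (collinear) columns drop out
      function(newx) drop(cbind(1, newx) %*% cf)
    }
  ))
  glmnet_spec <- function(alpha, lambda) {
    list(
      label = sprintf("%s(alpha=%.1f, lambda=%.4g)",
                      if (alpha == 0) "ridge" else "enet", alpha, lambda),
      family = if (alpha == 0) "ridge" else "elastic_net", scaled = TRUE,
      fit = function(x, y) {
        fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda,
                              standardize = FALSE)
        function(newx) drop(stats::predict(fit, newx, s = lambda))
      }
    )
  }
  lambdas <- 10^seq(-4, 1, length.out = 6)
  for (lam in lambdas) add(glmnet_spec(0, lam))
  for (alpha in c(0.1, 0.5, 0.9)) for (lam in lambdas) add(glmnet_spec(alpha, lam))
  tree_spec <- function(depth, minbucket) {
    list(
      label = sprintf("tree(depth=%d, minbucket=%d)", depth, minbucket),
      family = "decision_tree", scaled = FALSE,
      fit = function(x, y) {
        df <- data.frame(y = y, x)
        fit <- rpart::rpart(
          y ~ ., data = df, method = "anova",
          control = rpart::rpart.control(
            maxdepth = depth, minbucket = minbucket,
            minsplit = max(2L, 2L * minbucket), cp = 0, xval = 0
          )
        )
        function(newx) unname(stats::predict(fit, data.frame(newx)))
      }
    )
  }
  for (d in 1:4) for (mb in c(1, 2, 4)) add(tree_spec(d, mb))
  gbm_spec <- function(depth) {
    list(
      label = sprintf("gbm(depth=%d)", depth),
      family = "gradient_boosting", scaled = FALSE,
      fit = function(x, y) {
        fit <- xgboost::xgb.train(
          params = list(max_depth = depth, eta = 0.1, nthread = 1,
                        tree_method = "exact",
                        objective = "reg:squarederror"),
          data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
          nrounds = 60
        )
        function(newx) stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
      }
    )
  }
  for (d in 1:3) add(gbm_spec(d))
  specs
}

.fit_multiresponse <- function(spec, x, y) {
  models <- lapply(seq_len(ncol(y)), function(j) spec$fit(x, y[, j]))
  function(newx) {
    out <- vapply(models, function(m) m(newx), numeric(nrow(newx)))
    matrix(out, nrow = nrow(newx), dimnames = list(NULL, colnames(y)))
  }
}

.rmse_sum <- function(pred, obs) {
  sum(sqrt(colMeans((pred - obs)^2)))
}

#' Leave-one-out cross-validation RMSE of a candidate model
#'
#' For each training run, fits the candidate on the remaining runs and
#' predicts the three responses for the held-out run; returns the total
#' (summed over responses) RMSE of the held-out predictions. Responses are
#' not rescaled before summing. Folds whose fit fails are skipped with a
#' warning.
#'
#' @param spec One candidate from [default_candidates()].
#' @param features A `mill_features` from [assemble_features()].
#' @return Scalar total LOO-CV RMSE.
#' @export
loo_cv_rmse <- function(spec, features) {
  stopifnot(inherits(features, "mill_features"))
  x <- if (isTRUE(spec$scaled)) features$z_train else features$x_train
  y <- features$y_train
  n <- nrow(x)
  if (n < 3) stop("need at least 3 training rows", call. = FALSE)
  preds <- matrix(NA_real_, n, ncol(y), dimnames = list(NULL, colnames(y)))
  for (i in seq_len(n)) {
    p <- try(.fit_multiresponse(spec, x[-i, , drop = FALSE],
                                y[-i, , drop = FALSE])(x[i, , drop = FALSE]),
             silent = TRUE)
    if (inherits(p, "try-error")) {
      warning("LOO fold ", i, " failed for ", spec$label, "; fold skipped",
              call. = FALSE)
      next
    }
    preds[i, ] <- p
  }
  ok <- stats::complete.cases(preds)
  .rmse_sum(preds[ok, , drop = FALSE], y[ok, , drop = FALSE])
}

#' Fit all candidates, select by test RMSE, and report
#'
#' Fits every candidate on the 24 training runs (one regression per
#' response), records its total LOO-CV RMSE and its total test RMSE on the
#' held-out test runs, and selects the candidate with the lowest test RMSE
#' (ties broken by grid order). The selected model's per-run predicted
#' `(k, n, d_lim)` are returned for the test runs.
#'
#' @param features A `mill_features` from [assemble_features()].
#' @param candidates List of model specs, see [default_candidates()].
#' @return Object of class `mill_ml_report`: list with `scores` (tibble of
#'   label, family, LOO-CV and test RMSE), `selected` (label and index),
#'   `predictions` (tibble of test-run predicted parameters) and the
#'   refitted predictor closure.
#' @export
select_and_fit <- function(features, candidates = default_candidates()) {
  stopifnot(inherits(features, "mill_features"), length(candidates) > 0)
  scores <- purrr::map_dfr(candidates, function(spec) {
    x_tr <- if (isTRUE(spec$scaled)) features$z_train else features$x_train
    x_te <- if (isTRUE(spec$scaled)) features$z_test else features$x_test
    predict_fn <- .fit_multiresponse(spec, x_tr, features$y_train)
    test_rmse <- .rmse_sum(predict_fn(x_te), features$y_test)
    tibble::tibble(
      label = spec$label, family = spec$family,
      loo_rmse = loo_cv_rmse(spec, features),
      test_rmse = test_rmse
    )
  })
  best <- which.min(scores$test_rmse)   # ties: first in grid order
  spec <- candidates[[best]]
  x_tr <- if (isTRUE(spec$scaled)) features$z_train else features$x_train
  x_te <- if (isTRUE(spec$scaled)) features$z_test else features$x_test
  predict_fn <- .fit_multiresponse(spec, x_tr, features$y_train)
  pred <- predict_fn(x_te)
  predictions <- tibble::tibble(
    run_id = features$test_ids,
    k = pred[, "k"], n = pred[, "n"], d_lim_um = pred[, "d_lim_um"]
  )
  structure(
    list(mode = features$mode, scores = scores,
         selected = list(index = best, label = spec$label, family = spec$family),
         predictions = predictions, predict = predict_fn),
    class = "mill_ml_report"
  )
}

#' RMSE of a predicted median-size curve against a measured series
#'
#' Evaluates the nth-order model with the predicted `(k, n, d_lim)` and the
#' series' own t = 0 median size, and returns the root-mean-square deviation
#' (um) from the observed `d50` over all time points.
#'
#' @param k,n,d_lim Predicted breakage parameters.
#' @param series Data frame with `time_min` and `d50_um`; first point is the
#'   feed at t = 0.
#' @return RMSE in um.
#' @export
predicted_curve_rmse <- function(k, n, d_lim, series) {
  stopifnot(all(c("time_min", "d50_um") %in% names(series)), nrow(series) > 0)
  d50_0 <- series$d50_um[series$time_min == 0][1]
  if (is.na(d50_0)) stop("series must contain a t = 0 observation", call. = FALSE)
  if (d_lim >= d50_0) {
    stop("invalid parameters: d_lim must be below the initial median size",
         call. = FALSE)
  }
  pred <- breakage_d50(series$time_min, k, n, d_lim, d50_0)
  sqrt(mean((as.numeric(pred) - series$d50_um)^2))
}
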