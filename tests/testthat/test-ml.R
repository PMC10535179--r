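# synthetic targets attached to the real 27-run design
make_fits <- function(runs, fun) {
  tibble::tibble(
    run_id = runs$run_id,
    k = fun(runs), n = 2 + 0.1 * fun(runs), d_lim_um = 0.1 + 0.01 * fun(runs)
  )
}

test_that("feature assembly produces the documented shapes and scaling", {
  runs <- build_design(1)
  fits <- make_fits(runs, function(r) r$loading * 2)
  fp <- assemble_features(runs, fits, mode = "process")
  expect_equal(dim(fp$x_train), c(24, 5))
  expect_equal(dim(fp$x_test), c(3, 5))
  expect_equal(colMeans(fp$z_train), rep(0, 5), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(apply(fp$z_train, 2, sd), rep(1, 5), ignore_attr = TRUE)
  mhd <- tibble::tibble(run_id = runs$run_id, sigma_bmax = seq_len(27),
                        alpha_b = sqrt(seq_len(27)), a = log(1 + seq_len(27)),
                        Pi_sigma_y = seq_len(27)^2)
  fm <- assemble_features(runs, fits, mhd = mhd, mode = "mhd")
  expect_equal(dim(fm$x_train), c(24, 4))
  expect_error(assemble_features(runs, fits, mode = "mhd"), "required")
  expect_error(assemble_features(runs, fits, mhd = mhd[1:5, ], mode = "mhd"),
               "missing MHD state")
  # a constant predictor column is dropped with a warning
  sub <- runs[runs$x400 == 0, ]
  expect_warning(
    fsub <- assemble_features(sub, fits[runs$x400 == 0, ], mode = "process"),
    "zero-variance"
  )
  expect_false("x400" %in% colnames(fsub$x_train))
})

test_that("LOO-CV of mean-like predictors matches the closed-form oracle", {
  runs <- build_design(1)
  fits <- make_fits(runs, function(r) r$omega_rpm / 1000 + r$loading)
  feats <- assemble_features(runs, fits, mode = "process")
  # elastic net at an absurd penalty shrinks to the training mean
  flat_enet <- list(
    label = "enet(flat)", family = "elastic_net", scaled = TRUE,
    fit = function(x, y) {
      fit <- glmnet::glmnet(x, y, alpha = 0.5, lambda = 1e9, standardize = FALSE)
      function(newx) drop(stats::predict(fit, newx, s = 1e9))
    }
  )
  # a tree that never splits is the same mean predictor
  stump <- list(
    label = "tree(stump)", family = "decision_tree", scaled = FALSE,
    fit = function(x, y) {
      df <- data.frame(y = y, x)
      fit <- rpart::rpart(y ~ ., data = df,
                          control = rpart::rpart.control(minsplit = 1e6, xval = 0))
      function(newx) unname(stats::predict(fit, data.frame(newx)))
    }
  )
  y <- feats$y_train
  oracle <- sum(vapply(seq_len(ncol(y)), function(j) {
    preds <- vapply(seq_len(nrow(y)), function(i) mean(y[-i, j]), numeric(1))
    sqrt(mean((preds - y[, j])^2))
  }, numeric(1)))
  expect_equal(loo_cv_rmse(flat_enet, feats), oracle, tolerance = 1e-6)
  expect_equal(loo_cv_rmse(stump, feats), oracle, tolerance = 1e-12)
  # identical targets: the mean predictor is perfect
  const <- make_fits(runs, function(r) rep(1, nrow(r)))
  fc <- assemble_features(runs, const, mode = "process")
  expect_equal(loo_cv_rmse(stump, fc), 0, tolerance = 1e-12)
})

test_that("near-unpenalized elastic net recovers linear MHD relationships", {
  runs <- build_design(1)
  mhd <- tibble::tibble(
    run_id = runs$run_id,
    sigma_bmax = 1e8 * (1 + runs$loading) * runs$omega_rpm / 3000,
    alpha_b = 1e-7 * sqrt(runs$db_um),
    a = 1e3 * runs$loading^2,
    Pi_sigma_y = 1e14 * runs$loading / runs$db_um
  )
  lin <- function(r) {
    z <- dplyr::inner_join(r["run_id"], mhd, by = "run_id")
    2 + 3 * z$sigma_bmax / 1e8 + 0.5 * z$a / 1e3
  }
  fits <- make_fits(runs, lin)
  feats <- assemble_features(runs, fits, mhd = mhd, mode = "mhd")
  enet <- list(
    label = "enet(tiny)", family = "elastic_net", scaled = TRUE,
    fit = function(x, y) {
      fit <- glmnet::glmnet(x, y, alpha = 0.5, lambda = 1e-8,
                            standardize = FALSE,
                            thresh = 1e-14)
      function(newx) drop(stats::predict(fit, newx, s = 1e-8))
    }
  )
  rep <- select_and_fit(feats, list(enet))
  expect_lt(rep$scores$test_rmse, 1e-5)
  expect_equal(rep$predictions$k, feats$y_test[, "k"], ignore_attr = TRUE,
               tolerance = 1e-5)
})

test_that("trees are selected when the response is a step in the factors", {
  runs <- build_design(1)
  step <- function(r) 1 + 4 * as.numeric(r$omega_rpm > 3200 & r$loading > 0.40)
  fits <- make_fits(runs, step)
  feats <- assemble_features(runs, fits, mode = "process")
  rep <- select_and_fit(feats)
  expect_equal(rep$selected$family, "decision_tree")
  expect_lt(rep$scores$test_rmse[rep$selected$index], 1e-8)
  # the report carries every candidate's LOO-CV and test RMSE
  expect_true(all(c("label", "family", "loo_rmse", "test_rmse") %in%
                    names(rep$scores)))
  expect_true(all(rep$scores$test_rmse >= 0 & rep$scores$loo_rmse >= 0))
})

test_that("selection is invariant to training-row order", {
  runs <- build_design(1)
  fits <- make_fits(runs, function(r) r$omega_rpm / 1000 + 2 * r$loading +
                      r$db_um / 400)
  feats1 <- assemble_features(runs, fits, mode = "process")
  perm <- c(sample(1:24), 25:27)
  feats2 <- assemble_features(runs[perm, ], fits[perm, ], mode = "process")
  r1 <- select_and_fit(feats1)
  r2 <- select_and_fit(feats2)
  expect_identical(r1$selected$label, r2$selected$label)
  expect_equal(r1$predictions[order(r1$predictions$run_id), ],
               r2$predictions[order(r2$predictions$run_id), ],
               tolerance = 1e-10)
})

test_that("curve RMSE behaves like a root-mean-square deviation", {
  ts <- model_series(1.54, 1.89, 0.130)
  expect_equal(predicted_curve_rmse(1.54, 1.89, 0.130, ts), 0)
  bumped <- ts
  bumped$d50_um[5] <- bumped$d50_um[5] + 0.25
  expect_equal(predicted_curve_rmse(1.54, 1.89, 0.130, bumped),
               0.25 / sqrt(nrow(ts)))
  expect_error(predicted_curve_rmse(1, 2, 12, ts), "d_lim")
  expect_error(predicted_curve_rmse(1, 2, 0.1, ts[ts$time_min > 0, ]), "t = 0")
})
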