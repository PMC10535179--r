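#' Default pipeline configuration
#'
#' Nested configuration list consumed by [run_pipeline()]. Every field can
#' be overridden by a YAML file via [read_config()] or edited directly.
#'
#' @return A named list with components `seed`, `noise_cv`, `eps_ht_W_m3`,
#'   `target_size_um`, `material` (overrides for [mhd_constants()]),
#'   `thermal` ([thermal_defaults()]), and `econ` (arguments of
#'   [bead_economics()]).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    noise_cv = 0.03,
    eps_ht_W_m3 = 5e4,
    target_size_um = 0.2,
    material = list(),
    thermal = thermal_defaults(),
    econ = list(load_mass_kg = 0.196, horizon_years = 9,
                policy = "wear_threshold", threshold = 0.20,
                reference_um = 100)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file with any subset of the [default_config()] sections and
#' merges it (recursively) over the defaults.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

.schema_runs <- c("run_id", "role", "omega_rpm", "loading", "x100", "x200",
                  "x400", "db_um", "P_W", "mu_L_PaS", "eps_ht_W_m3")
.schema_timeseries <- c("run_id", "time_min", "d10_um", "d50_um", "d90_um", "sd_um")

.check_schema <- function(df, expected, what) {
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "),
         "; expected at least: ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read and validate a run table CSV
#'
#' Columns carry units in their suffixes (`_W`, `_um`, `_PaS`, `_W_m3`) to
#' prevent unit confusion at the interchange boundary.
#'
#' @param path CSV path.
#' @return Validated tibble of run conditions.
#' @export
read_runs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(run_id = readr::col_character()))
  .check_schema(df, .schema_runs, "runs table")
  if (any(abs(df$x100 + df$x200 + df$x400 - 1) > 1e-6)) {
    stop("runs table: bead mass fractions must sum to 1", call. = FALSE)
  }
  df
}

#' Read and validate a particle-size time-series CSV
#'
#' @param path CSV path.
#' @return Validated tibble; times must be strictly increasing within each
#'   run and all sizes positive.
#' @export
read_timeseries_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(run_id = readr::col_character()))
  .check_schema(df, .schema_timeseries, "timeseries table")
  bad <- df |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_min, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop("timeseries table: times not strictly increasing for run(s) ",
         paste(bad$run_id, collapse = ", "), call. = FALSE)
  }
  if (any(df$d50_um <= 0)) stop("timeseries table: sizes must be positive", call. = FALSE)
  df
}

#' Run the full milling analysis pipeline
#'
#' Executes every stage in order on a synthetic study: simulate (design,
#' size series, power/viscosity, thermal cycles), fit the breakage model per
#' run, compute the microhydrodynamic state, predict the test-run kinetics
#' with both predictor modes, rank the training conditions by merit score,
#' and evaluate bead economics. All results are written as CSV under
#' `out_dir` (`runs.csv`, `timeseries/`, `fits.csv`, `mhd.csv`,
#' `predictions.csv`, `merit.csv`, `economics.csv`, `summary.txt`). The run
#' is fully determined by `config$seed`: repeated calls produce identical
#' files.
#'
#' @param out_dir Output directory (created if needed); set `NULL` to skip
#'   writing.
#' @param config Configuration list, see [default_config()].
#' @return (Invisibly) a list with elements `study`, `fits`, `mhd`,
#'   `ml_process`, `ml_mhd`, `predictions`, `merit`, `economics`.
#' @export
run_pipeline <- function(out_dir = NULL, config = default_config()) {
  consts <- do.call(mhd_constants, config$material)
  thermal <- utils::modifyList(thermal_defaults(), config$thermal)
  surface <- default_surface(noise_cv = config$noise_cv,
                             eps_ht_W_m3 = config$eps_ht_W_m3)
  design <- build_design(seed = config$seed)
  study <- simulate_study(design, surface, thermal)

  fits <- fit_study(study$timeseries)
  per_run <- study$timeseries |>
    dplyr::group_by(.data$run_id) |>
    dplyr::group_modify(~ time_to_size(.x, target = config$target_size_um)) |>
    dplyr::ungroup()
  fits <- dplyr::left_join(fits, per_run, by = "run_id")
  fits$N_d50 <- purrr::map2_int(fits$run_id, fits$t_cross_min, function(id, t) {
    if (is.na(t)) return(NA_integer_)
    as.integer(cycles_at_time(study$schedules[[id]], t))
  })
  fits <- dplyr::rename(fits, t_d50_min = "t_cross_min")

  mhd <- compute_mhd_state(study$runs, consts)

  feats_p <- assemble_features(study$runs, fits, mode = "process")
  feats_m <- assemble_features(study$runs, fits, mhd = mhd, mode = "mhd")
  ml_p <- select_and_fit(feats_p)
  ml_m <- select_and_fit(feats_m)

  test_ids <- study$runs$run_id[study$runs$role == "test"]
  pred_rows <- function(approach, params) {
    purrr::map_dfr(seq_len(nrow(params)), function(i) {
      id <- params$run_id[i]
      series <- dplyr::filter(study$timeseries, .data$run_id == id)
      rmse <- tryCatch(
        predicted_curve_rmse(params$k[i], params$n[i], params$d_lim_um[i], series),
        error = function(e) NA_real_
      )
      tibble::tibble(run_id = id, approach = approach, k = params$k[i],
                     n = params$n[i], d_lim_um = params$d_lim_um[i],
                     rmse_um = rmse)
    })
  }
  direct <- dplyr::filter(fits, .data$run_id %in% test_ids)
  predictions <- dplyr::bind_rows(
    pred_rows("direct_fit", direct[, c("run_id", "k", "n", "d_lim_um")]),
    pred_rows("mhd_prediction", ml_m$predictions),
    pred_rows("empirical_prediction", ml_p$predictions)
  )

  train_fits <- dplyr::filter(fits, !.data$run_id %in% test_ids)
  merit_in <- dplyr::inner_join(
    train_fits[, c("run_id", "k", "t_d50_min", "N_d50")],
    study$runs[, c("run_id", "P_W")], by = "run_id"
  )
  merit <- merit_table(merit_in)
  economics <- bead_economics(
    load_mass_kg = config$econ$load_mass_kg,
    policy = config$econ$policy,
    horizon_years = config$econ$horizon_years,
    threshold = config$econ$threshold,
    reference_um = config$econ$reference_um
  )

  result <- list(study = study, fits = fits, mhd = mhd,
                 ml_process = ml_p, ml_mhd = ml_m,
                 predictions = predictions, merit = merit,
                 economics = economics, config = config)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  invisible(result)
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "timeseries"), showWarnings = FALSE)
  study <- result$study
  readr::write_csv(study$runs, file.path(out_dir, "runs.csv"))
  for (id in study$runs$run_id) {
    ts <- dplyr::filter(study$timeseries, .data$run_id == id)
    readr::write_csv(ts, file.path(out_dir, "timeseries",
                                   paste0("run_", id, ".csv")))
  }
  readr::write_csv(result$fits, file.path(out_dir, "fits.csv"))
  readr::write_csv(result$mhd, file.path(out_dir, "mhd.csv"))
  readr::write_csv(result$predictions, file.path(out_dir, "predictions.csv"))
  readr::write_csv(result$merit, file.path(out_dir, "merit.csv"))
  readr::write_csv(result$economics, file.path(out_dir, "economics.csv"))

  train <- dplyr::filter(result$fits,
                         .data$run_id %in% study$runs$run_id[study$runs$role == "train"])
  s <- summarize_fits(train)
  top <- result$merit$run_id[which.max(result$merit$merit_score_k)]
  lines <- c(
    sprintf("synthetic milling study: %d runs, seed %d",
            nrow(study$runs), study$seed),
    sprintf("d_lim across %d training runs: %.3f +/- %.3f um",
            nrow(train), s$mean[s$parameter == "d_lim_um"],
            s$sd[s$parameter == "d_lim_um"]),
    sprintf("n across training runs: %.2f +/- %.2f",
            s$mean[s$parameter == "n"], s$sd[s$parameter == "n"]),
    sprintf("selected process-predictor model: %s", result$ml_process$selected$label),
    sprintf("selected MHD-predictor model: %s", result$ml_mhd$selected$label),
    sprintf("highest merit score (rate variant): run %s", top)
  )
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(result)
}
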