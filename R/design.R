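#' Sampling schedule of the milling campaign
#'
#' Milling times (minutes) at which the particle size distribution is
#' sampled: the feed at t = 0, the geometric schedule 2^s for s = 0..7, plus
#' 40 s and 24, 48, 96, 128 and 180 min.
#'
#' @return Strictly increasing numeric vector of times in minutes.
#' @export
sampling_times <- function() {
  sort(unique(c(0, 2^(0:7), 40 / 60, 24, 48, 96, 128, 180)))
}

#' Effective median bead size of a bead charge
#'
#' Single bead lots use their measured median size (112, 194 and 403 um for
#' the 100, 200 and 400 um nominal lots); 50-50 binary mixtures use the
#' arithmetic mean of the two medians, a rough first approximation that
#' treats the mixture as an equivalent monodisperse charge. Three-way
#' mixtures are outside the supported design and raise an error.
#'
#' @param x100,x200,x400 Bead mass fractions (must sum to 1).
#' @param use_nominal If `TRUE`, use the nominal sizes (100/200/400 um)
#'   instead of the measured medians.
#' @return Effective median bead diameter in um.
#' @examples
#' effective_bead_size(1, 0, 0)      # 112
#' effective_bead_size(0.5, 0.5, 0)  # 153
#' @export
effective_bead_size <- function(x100, x200, x400, use_nominal = FALSE) {
  stopifnot(length(x100) == length(x200), length(x200) == length(x400))
  sizes <- if (use_nominal) c(100, 200, 400) else bead_size_table()$mhd_d50_um
  purrr::pmap_dbl(list(x100, x200, x400), function(a, b, d) {
    w <- c(a, b, d)
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("bead mass fractions must be non-negative and sum to 1", call. = FALSE)
    }
    nz <- which(w > 0)
    if (length(nz) == 1L) return(sizes[nz])
    if (length(nz) == 2L) {
      if (any(abs(w[nz] - 0.5) > 1e-8)) {
        stop("binary bead mixtures must be 50-50 by mass", call. = FALSE)
      }
      return(mean(sizes[nz]))
    }
    stop("three-way bead mixtures are not supported", call. = FALSE)
  })
}

#' Build the milling study design
#'
#' Returns the 27-run design of the milling campaign: a 24-run full factorial
#' of stirrer speed {3000, 4000} rpm x bead loading {0.35, 0.50} x six bead
#' charges (three narrowly sized lots and their three 50-50 binary mixtures),
#' plus three test runs at the centre of the design space (3500 rpm, 0.43)
#' with the single bead lots. The sampling schedule is attached as the
#' `sampling_times_min` attribute.
#'
#' @param seed Integer master seed, stored on the design and used by
#'   [simulate_study()] to derive per-run child seeds.
#' @return A tibble of class `mill_design` with columns `run_id`, `role`
#'   (`"train"` or `"test"`), `omega_rpm`, `loading`, `x100`, `x200`, `x400`,
#'   `identifier` and `db_um` (effective median bead size).
#' @examples
#' design <- build_design(seed = 1)
#' attr(design, "sampling_times_min")
#' @export
build_design <- function(seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  comps <- tibble::tribble(
    ~comp, ~x100, ~x200, ~x400,
    1L, 1.0, 0.0, 0.0,
    2L, 0.5, 0.5, 0.0,
    3L, 0.0, 1.0, 0.0,
    4L, 0.5, 0.0, 0.5,
    5L, 0.0, 0.5, 0.5,
    6L, 0.0, 0.0, 1.0
  )
  train <- tidyr::crossing(
    tibble::tibble(omega_rpm = c(3000, 4000)),
    tibble::tibble(loading = c(0.35, 0.50)),
    comps
  )
  # run 1..24: speed slowest-varying, then loading, then the charge order
  # single 100, 50-50 of 100-200, single 200, 50-50 of 100-400, 50-50 of
  # 200-400, single 400
  train <- dplyr::arrange(train, .data$omega_rpm, .data$loading, .data$comp)
  train <- dplyr::mutate(train, run_id = as.character(dplyr::row_number()),
                         role = "train")
  test <- dplyr::mutate(comps[c(1, 3, 6), ],
                        omega_rpm = 3500, loading = 0.43,
                        run_id = paste0("T", 1:3), role = "test")
  design <- dplyr::bind_rows(train, test)
  design <- dplyr::mutate(
    design,
    identifier = format_run_identifier(design),
    db_um = effective_bead_size(.data$x100, .data$x200, .data$x400)
  )
  design <- dplyr::select(
    design, -"comp"
  )
  design <- dplyr::select(
    design, "run_id", "role", "omega_rpm", "loading",
    "x100", "x200", "x400", "identifier", "db_um"
  )
  attr(design, "sampling_times_min") <- sampling_times()
  attr(design, "seed") <- as.integer(seed)
  class(design) <- c("mill_design", class(design))
  design
}
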