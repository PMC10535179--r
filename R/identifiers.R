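#' Parse a run identifier string
#'
#' Run identifiers encode a milling condition as three whitespace-separated
#' tokens: stirrer speed in rpm, volumetric bead loading, and the bead mass
#' percentages of the 100/200/400 um lots joined with dashes, e.g.
#' `"4000 0.50 50-50-0"`.
#'
#' @param text Character vector of identifiers.
#' @return A tibble with columns `omega_rpm`, `loading`, `x100`, `x200`,
#'   `x400` (mass fractions in 0..1), one row per identifier.
#' @examples
#' parse_run_identifier("4000 0.50 50-50-0")
#' @export
parse_run_identifier <- function(text) {
  stopifnot(is.character(text))
  purrr::map_dfr(text, function(x) {
    tokens <- strsplit(trimws(x), "\\s+")[[1]]
    if (length(tokens) != 3L) {
      stop("run identifier '", x, "' must have three tokens: ",
           "'<rpm> <loading> <x100-x200-x400>'", call. = FALSE)
    }
    omega <- suppressWarnings(as.numeric(tokens[1]))
    if (!is.finite(omega) || omega <= 0) {
      stop("run identifier '", x, "': stirrer speed token '", tokens[1],
           "' is not a positive number", call. = FALSE)
    }
    loading <- suppressWarnings(as.numeric(tokens[2]))
    if (!is.finite(loading) || loading <= 0 || loading >= 1) {
      stop("run identifier '", x, "': bead loading token '", tokens[2],
           "' must be a number in (0, 1)", call. = FALSE)
    }
    comp <- suppressWarnings(as.numeric(strsplit(tokens[3], "-")[[1]]))
    if (length(comp) != 3L || anyNA(comp) || any(comp < 0)) {
      stop("run identifier '", x, "': composition token '", tokens[3],
           "' must be three non-negative percentages joined by '-'",
           call. = FALSE)
    }
    if (abs(sum(comp) - 100) > 1e-8) {
      stop("run identifier '", x, "': bead mass percentages ", tokens[3],
           " must sum to 100", call. = FALSE)
    }
    tibble::tibble(
      omega_rpm = omega, loading = loading,
      x100 = comp[1] / 100, x200 = comp[2] / 100, x400 = comp[3] / 100
    )
  })
}

#' Format milling conditions as run identifiers
#'
#' Inverse of [parse_run_identifier()]: `format_run_identifier(parse_run_identifier(x))`
#' reproduces `x` for identifiers in canonical form.
#'
#' @param cond Data frame with columns `omega_rpm`, `loading`, `x100`, `x200`,
#'   `x400`.
#' @return Character vector of identifiers.
#' @export
format_run_identifier <- function(cond) {
  stopifnot(all(c("omega_rpm", "loading", "x100", "x200", "x400") %in% names(cond)))
  fmt_pct <- function(x) formatC(round(x * 100), format = "d")
  paste(
    formatC(cond$omega_rpm, format = "d"),
    formatC(cond$loading, format = "f", digits = 2),
    paste(fmt_pct(cond$x100), fmt_pct(cond$x200), fmt_pct(cond$x400), sep = "-")
  )
}
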