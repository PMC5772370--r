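#' Full stability report for a measurement series
#'
#' Runs the whole analysis for one formulation followed across conditions:
#' per-condition excipient molecules per particle and particle molarity, the
#' excipient-conservation audit, instability classification against the
#' first condition, and the overall size-concentration Pearson correlation
#' (marked not computable for a single-condition series).
#'
#' @param data A series tibble ([read_series()] schema).
#' @param formulation A [formulation()] describing the constant excipient.
#' @param molecules_per_ml Optional override of the total molecules per mL
#'   (e.g. a reported rounded count); defaults to the full-precision value
#'   implied by the formulation.
#' @param size_threshold,conc_threshold Instability thresholds, see
#'   [classify_instability()].
#' @param audit_tolerance Relative tolerance for [conservation_audit()].
#' @return An object of class `"stability_report"`: use [tidy()] for the
#'   per-condition table, [glance()] for the one-row summary,
#'   [report_to_json()] to serialise.
#' @examples
#' series <- read_series(example_series("table1_dppc"))
#' rep <- stability_report(series, formulation("DPPC", 0.125e-3),
#'                         molecules_per_ml = 7.5e16)
#' glance(rep)
#' @export
stability_report <- function(data, formulation,
                             molecules_per_ml = NULL,
                             size_threshold = 0.10, conc_threshold = 0.10,
                             audit_tolerance = 0.05) {
  assert_series(data)
  if (!inherits(formulation, "formulation")) {
    abort("`formulation` must be a formulation() object.")
  }
  n_ml <- molecules_per_ml %||%
    nanocount::molecules_per_ml(formulation$molar_concentration)
  conditions <- as_tibble(data)
  if (!"molecules_per_particle" %in% names(conditions)) {
    conditions$molecules_per_particle <-
      molecules_per_particle(n_ml, conditions$particles_per_ml)
  }
  conditions <- conditions |>
    dplyr::mutate(particle_molarity = particle_molarity(.data$particles_per_ml)) |>
    conservation_audit(n_ml, tolerance = audit_tolerance) |>
    classify_instability(size_threshold = size_threshold,
                         conc_threshold = conc_threshold)
  correlation <- if (nrow(data) >= 2 &&
                     stats::sd(data$size_nm) > 0 &&
                     stats::sd(data$particles_per_ml) > 0) {
    stability_correlation(data)
  } else {
    tibble(r = NA_real_, n = nrow(data))
  }
  structure(
    list(conditions = conditions, correlation = correlation,
         molecules_per_ml = n_ml, formulation = formulation),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s, %.3g molecules/mL, %d condition(s)\n",
              x$formulation$excipient_name, x$molecules_per_ml,
              nrow(x$conditions)))
  if (is.na(x$correlation$r)) {
    cat("  size-concentration correlation: not computable\n")
  } else {
    cat(sprintf("  size-concentration correlation r = %.2f (n = %d)\n",
                x$correlation$r, x$correlation$n))
  }
  shown <- dplyr::select(x$conditions, dplyr::any_of(c(
    "condition", "size_nm", "particles_per_ml", "molecules_per_particle",
    "conservation_pass", "status"
  )))
  print(shown, n = nrow(shown))
  invisible(x)
}

#' Per-condition table of a stability report
#' @param x A `"stability_report"`.
#' @param ... Unused.
#' @return Tibble with stoichiometry, audit and instability columns.
#' @export
tidy.stability_report <- function(x, ...) {
  x$conditions
}

#' One-row summary of a stability report
#' @param x A `"stability_report"`.
#' @param ... Unused.
#' @return One-row tibble: correlation, molecule budget, audit and verdict
#'   counts.
#' @export
glance.stability_report <- function(x, ...) {
  tibble(
    excipient = x$formulation$excipient_name,
    molecules_per_ml = x$molecules_per_ml,
    n_conditions = nrow(x$conditions),
    r = x$correlation$r,
    n_audit_fail = sum(!x$conditions$conservation_pass),
    n_unstable = sum(x$conditions$status != "stable")
  )
}

#' Serialise a stability report to JSON
#'
#' Lossless round trip: numbers are written at full precision.
#'
#' @param x A `"stability_report"`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(x, path = NULL) {
  payload <- list(
    formulation = x$formulation[!vapply(x$formulation, is.null, logical(1))],
    molecules_per_ml = x$molecules_per_ml,
    correlation = x$correlation,
    conditions = x$conditions
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
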