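series_required_cols <- c("condition", "size_nm", "particles_per_ml")
series_optional_cols <- c("size_sd_nm", "particles_sd", "pdi", "span")

#' Read a stability series from CSV
#'
#' Expects columns `condition`, `size_nm`, `particles_per_ml` (mandatory)
#' and optionally `size_sd_nm`, `particles_sd`, `pdi`, `span`. Header
#' matching is case-insensitive; extra columns are kept; scientific notation
#' ("9.4e11") is accepted; row order is preserved.
#'
#' @param path Path to a CSV file (UTF-8, period decimal separator).
#' @return A validated tibble, one row per condition.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "nanocount_schema_error")
  }
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_guess())),
    error = function(e) abort(sprintf("Cannot parse %s as CSV: %s", path,
                                      conditionMessage(e)),
                              class = "nanocount_schema_error")
  )
  names(data) <- tolower(names(data))
  missing_cols <- setdiff(series_required_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing mandatory column(s): %s.",
                  basename(path), paste(missing_cols, collapse = ", ")),
          class = "nanocount_schema_error")
  }
  for (col in c("size_nm", "particles_per_ml")) {
    vals <- suppressWarnings(as.numeric(data[[col]]))
    bad <- which(!is.finite(vals) | vals <= 0)
    if (length(bad) > 0) {
      abort(sprintf("Column `%s` of %s must be positive and numeric; offending row(s): %s.",
                    col, basename(path), paste(bad, collapse = ", ")),
            class = "nanocount_schema_error")
    }
    data[[col]] <- vals
  }
  if (anyDuplicated(data$condition)) {
    abort(sprintf("Condition labels in %s must be unique.", basename(path)),
          class = "nanocount_schema_error")
  }
  data
}

#' Write a stability series to CSV
#'
#' Inverse of [read_series()]: UTF-8, period decimal separator, full numeric
#' precision (round-trips to at least 12 significant digits).
#'
#' @param data A series tibble.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_series <- function(data, path) {
  assert_series(data, series_required_cols)
  readr::write_csv(data, path)
  invisible(data)
}

#' Packaged example series
#'
#' Paths to the measurement tables shipped with the package:
#' `"table1_dppc"` (extruded DPPC liposomes destabilised with increasing
#' chloroform, 4 conditions) and `"table2_sln"` (cetyl palmitate solid lipid
#' nanoparticles with decreasing poloxamer 188, 5 conditions).
#'
#' @param name `"table1_dppc"` or `"table2_sln"`.
#' @return Path to the packaged CSV.
#' @export
example_series <- function(name = c("table1_dppc", "table2_sln")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".csv"), package = "nanocount",
              mustWork = TRUE)
}
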