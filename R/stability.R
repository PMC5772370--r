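# Stability analysis over an ordered series of (size, concentration)
# measurements: Pearson size-concentration correlation, instability
# classification against a baseline, and the excipient-conservation audit.

assert_series <- function(data, need = c("size_nm", "particles_per_ml")) {
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Series is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "nanocount_schema_error")
  }
  invisible(data)
}

#' Pearson correlation across a stability series
#'
#' Sample Pearson product-moment correlation between two per-condition
#' columns, by default particle size against particle concentration — the
#' headline stability statistic: destabilising colloids show a strong
#' negative size-concentration correlation. Computed over per-condition
#' means; `n` is the number of conditions.
#'
#' @param data A data frame with one row per condition.
#' @param x,y Column names (tidy-select style strings or bare names) to
#'   correlate; defaults `size_nm` and `particles_per_ml`.
#' @param p_value If `TRUE`, attach a two-sided t-based p-value (warned
#'   against for the tiny n typical of stability series).
#' @return One-row tibble with `r`, `n`, and optionally `p_value`.
#' @export
stability_correlation <- function(data, x = "size_nm", y = "particles_per_ml",
                                  p_value = FALSE) {
  x <- rlang::as_name(rlang::enquo(x))
  y <- rlang::as_name(rlang::enquo(y))
  assert_series(data, c(x, y))
  xs <- data[[x]]
  ys <- data[[y]]
  if (length(xs) < 2) {
    abort("Correlation needs at least two conditions.",
          class = "nanocount_domain_error")
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    abort("Correlation is undefined when a variable is constant across conditions.",
          class = "nanocount_undefined_correlation")
  }
  out <- tibble(r = stats::cor(xs, ys), n = length(xs))
  if (p_value) {
    if (length(xs) <= 5) {
      warn(sprintf("p-value from only %d conditions; interpret with caution.",
                   length(xs)))
    }
    out$p_value <- stats::cor.test(xs, ys)$p.value
  }
  out
}

#' Classify colloid instability against a baseline
#'
#' Implements the diagnostic that motivates monitoring particle
#' concentration: growth processes (fusion, agglutination, Ostwald ripening)
#' show fewer, larger particles, while degradation shows fewer particles
#' *without* a concomitant size increase — a signature invisible to
#' size-only monitoring. A record is compared with a baseline; with default
#' 10\% thresholds:
#' concentration drop > threshold and size rise > threshold gives
#' `"aggregation_or_fusion"`; concentration drop > threshold with size rise
#' at or below threshold gives `"degradation"`; anything else is `"stable"`.
#' Threshold comparisons are strict inequalities, so an exactly-threshold
#' change stays in the milder class.
#'
#' @param data A data frame of measurement records with `size_nm` and
#'   `particles_per_ml`; each row is classified.
#' @param baseline Baseline record: a one-row data frame or list with
#'   `size_nm` and `particles_per_ml`. Defaults to the first row of `data`.
#' @param size_threshold Relative size change regarded as a real increase.
#' @param conc_threshold Relative concentration change regarded as a real
#'   decrease.
#' @return `data` with columns `relative_size_change`,
#'   `relative_concentration_change` and `status` appended.
#' @export
classify_instability <- function(data, baseline = NULL,
                                 size_threshold = 0.10,
                                 conc_threshold = 0.10) {
  assert_series(data)
  baseline <- baseline %||% data[1, ]
  if (baseline$size_nm[1] <= 0 || baseline$particles_per_ml[1] <= 0) {
    abort_domain("Baseline size and concentration must be > 0.")
  }
  ds <- (data$size_nm - baseline$size_nm[1]) / baseline$size_nm[1]
  dc <- (data$particles_per_ml - baseline$particles_per_ml[1]) /
    baseline$particles_per_ml[1]
  status <- dplyr::case_when(
    dc < -conc_threshold & ds > size_threshold ~ "aggregation_or_fusion",
    dc < -conc_threshold ~ "degradation",
    .default = "stable"
  )
  dplyr::mutate(as_tibble(data),
    relative_size_change = ds,
    relative_concentration_change = dc,
    status = status
  )
}

#' Excipient-conservation audit of a series
#'
#' In a constant-excipient experiment the product (molecules per particle) x
#' (particles per mL) must equal the total molecules per mL in every
#' condition; deviations flag inconsistent rows. If the series lacks a
#' `molecules_per_particle` column it is derived from `molecules_per_ml`
#' (making the audit exact), so the audit is most informative on externally
#' reported per-particle counts.
#'
#' @param data A series with `particles_per_ml` and ideally
#'   `molecules_per_particle`.
#' @param molecules_per_ml The constant total excipient molecules per mL.
#' @param tolerance Allowed relative deviation (default 0.02).
#' @return `data` with `conservation_product`, `conservation_deviation`
#'   (relative) and logical `conservation_pass` appended.
#' @export
conservation_audit <- function(data, molecules_per_ml, tolerance = 0.02) {
  assert_series(data, "particles_per_ml")
  check_positive(molecules_per_ml, "molecules_per_ml")
  npp <- if ("molecules_per_particle" %in% names(data)) {
    data$molecules_per_particle
  } else {
    molecules_per_particle(molecules_per_ml, data$particles_per_ml)
  }
  product <- npp * data$particles_per_ml
  deviation <- abs(product - molecules_per_ml) / molecules_per_ml
  dplyr::mutate(as_tibble(data),
    conservation_product = product,
    conservation_deviation = deviation,
    conservation_pass = deviation <= tolerance
  )
}
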