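#' Weighted quantiles of a diameter distribution
#'
#' Quantiles of the number-weighted cumulative size distribution, with linear
#' interpolation between order statistics (midpoint plotting positions).
#' With unit weights and two values 100 and 200 the median is 150.
#'
#' @param diameters Particle diameters in nm.
#' @param probs Quantile fractions in (0, 1).
#' @param weights Optional non-negative number weights (counts); default 1.
#' @return Diameters at the requested quantiles, in nm.
#' @export
weighted_percentiles <- function(diameters, probs, weights = NULL) {
  if (length(diameters) == 0) abort("Empty population: no diameters to summarise.")
  if (any(probs <= 0 | probs >= 1)) abort_domain("`probs` must lie strictly in (0, 1).")
  weights <- weights %||% rep(1, length(diameters))
  if (any(weights < 0) || sum(weights) == 0) abort_domain("`weights` must be non-negative with positive sum.")
  ord <- order(diameters)
  d <- diameters[ord]
  w <- weights[ord]
  cw <- cumsum(w)
  W <- sum(w)
  # midpoint plotting positions; a count weight w > 1 contributes a flat
  # block [cw_prev + 1/2, cw - 1/2], which makes integer counts behave
  # exactly like repeated particles
  lo <- (cw - w + pmin(w, 1) / 2) / W
  hi <- (cw - pmin(w, 1) / 2) / W
  pos <- as.vector(rbind(lo, hi))
  val <- rep(d, each = 2)
  keep <- !duplicated(pos)
  if (sum(keep) == 1) return(rep(d[1], length(probs)))
  stats::approx(pos[keep], val[keep], xout = probs, rule = 2,
                ties = "ordered")$y
}

#' Span of a size distribution
#'
#' The width metric reported by particle-tracking instruments:
#' (D90 - D10) / D50 on the number-weighted distribution. Span below 1 is
#' conventionally monodisperse.
#'
#' @param d10,d50,d90 Number-weighted 10th/50th/90th percentile diameters, nm.
#' @return Dimensionless span.
#' @examples
#' span(100, 150, 250) # 1
#' @export
span <- function(d10, d50, d90) {
  if (any(d50 <= 0)) abort_domain("`d50` must be > 0.")
  if (any(d10 > d90)) abort_domain("`d10` must not exceed `d90`.")
  (d90 - d10) / d50
}

#' Rayleigh intensity weights
#'
#' Scattering weights proportional to diameter^6 (Rayleigh regime),
#' normalised to sum to one. This is the weighting that makes dynamic light
#' scattering blind to small particles next to large ones.
#'
#' @param diameters Diameters in nm (> 0).
#' @param weights Optional number weights.
#' @return Normalised intensity weights.
#' @export
intensity_weights <- function(diameters, weights = NULL) {
  check_positive(diameters, "diameters")
  weights <- weights %||% rep(1, length(diameters))
  w <- weights * diameters^6
  w / sum(w)
}

#' Z-average diameter and polydispersity index
#'
#' Cumulant-style DLS summary computed directly from the diameter
#' distribution. The z-average is the intensity-weighted harmonic-style mean
#' sum(n d^6) / sum(n d^5); the PDI is the relative variance mu2 / Gamma^2 of
#' the decay-rate distribution, where each particle's decay rate is
#' proportional to 1/d and rates are averaged with intensity (d^6) weights.
#' PDI is 0 iff the sample is monodisperse; below 0.2 is conventionally
#' monodisperse.
#'
#' @param population A [particle_population()], or a numeric vector of
#'   diameters in nm.
#' @param weights Optional number weights (ignored when `population` is a
#'   particle_population).
#' @return One-row tibble with `z_average_nm` and `pdi`.
#' @examples
#' z_average_and_pdi(c(100, 300)) # z-average 299.2 nm
#' @export
z_average_and_pdi <- function(population, weights = NULL) {
  d <- pop_diameters(population)
  if (length(d) == 0) abort("Empty population.")
  check_positive(d, "diameters")
  n <- weights %||% rep(1, length(d))
  z <- sum(n * d^6) / sum(n * d^5)
  wi <- n * d^6
  wi <- wi / sum(wi)
  gamma_i <- 1 / d # decay rate up to a constant; PDI is scale-free
  gbar <- sum(wi * gamma_i)
  mu2 <- sum(wi * (gamma_i - gbar)^2)
  tibble(z_average_nm = z, pdi = mu2 / gbar^2)
}

#' Dispersity classification
#'
#' A sample is called monodisperse when PDI < 0.2 and Span < 1, the
#' conventional thresholds for DLS and particle-tracking width metrics.
#'
#' @param pdi Polydispersity index (>= 0).
#' @param span Span (>= 0).
#' @return `"monodisperse"` or `"polydisperse"` (vectorised).
#' @export
classify_dispersity <- function(pdi, span) {
  check_positive(pdi, "pdi", strict = FALSE)
  check_positive(span, "span", strict = FALSE)
  ifelse(pdi < 0.2 & span < 1, "monodisperse", "polydisperse")
}

#' Full size-distribution summary
#'
#' Number- and intensity-weighted means, z-average, D10/D50/D90, PDI, Span
#' and the dispersity class for a particle population.
#'
#' @inheritParams z_average_and_pdi
#' @return A one-row tibble.
#' @export
size_summary <- function(population, weights = NULL) {
  d <- pop_diameters(population)
  if (length(d) == 0) abort("Empty population.")
  n <- weights %||% rep(1, length(d))
  q <- weighted_percentiles(d, c(0.1, 0.5, 0.9), n)
  iw <- intensity_weights(d, n)
  zp <- z_average_and_pdi(d, n)
  sp <- span(q[1], q[2], q[3])
  tibble(
    mean_number_nm = sum(n * d) / sum(n),
    mean_intensity_nm = sum(iw * d),
    z_average_nm = zp$z_average_nm,
    d10_nm = q[1], d50_nm = q[2], d90_nm = q[3],
    pdi = zp$pdi,
    span = sp,
    dispersity = classify_dispersity(zp$pdi, sp)
  )
}
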