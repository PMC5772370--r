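# Nanoparticle tracking analysis forward model. Track-level (not
# image-level): particles in the observation volume perform 2-D Brownian
# walks; sizing is per-track via the lag-1 mean-squared-displacement
# estimator and Stokes-Einstein inversion; concentration comes from the mean
# number of particles visible per frame.

#' Simulate Brownian NTA tracks from a population
#'
#' The number of particles resident in the observation volume at any instant
#' is Poisson with mean (diluted concentration x sampling volume); over the
#' recorded video, particles enter and leave so that the number of distinct
#' tracks is Poisson with mean (residents x n_frames / mean track length).
#' Each track takes its true diameter from a number-weighted draw from the
#' population, a geometrically distributed length (mean `track_length_mean`),
#' and per-axis Gaussian steps of variance 2 D dt with D from
#' [stokes_einstein()].
#'
#' @param population A [particle_population()].
#' @param config An [instrument_config()].
#' @return A tibble with one row per track: `track`, `diameter_true_nm`,
#'   `n_frames`, and list-columns `dx`, `dy` of displacements in metres.
#' @export
simulate_tracks <- function(population, config = instrument_config()) {
  conc_diluted <- concentration(population) / config$dilution_factor
  lambda_resident <- conc_diluted * config$sampling_volume_ml
  lambda_tracks <- lambda_resident * config$n_frames / config$track_length_mean
  with_seed_or_stream(config$seed, {
    n_tracks <- stats::rpois(1, lambda_tracks)
    if (n_tracks == 0) {
      return(tibble(track = integer(), diameter_true_nm = numeric(),
                    n_frames = integer(), dx = list(), dy = list()))
    }
    d_true <- sample(population$diameters, n_tracks, replace = TRUE)
    len <- 1L + stats::rgeom(n_tracks, 1 / config$track_length_mean)
    D <- stokes_einstein(d_true, config$temperature_K, config$viscosity_Pa_s)
    step_sd <- sqrt(2 * D * config$frame_interval_s)
    steps <- pmax(len - 1L, 0L)
    tibble(
      track = seq_len(n_tracks),
      diameter_true_nm = d_true,
      n_frames = len,
      dx = purrr::map2(steps, step_sd, ~ stats::rnorm(.x, 0, .y)),
      dy = purrr::map2(steps, step_sd, ~ stats::rnorm(.x, 0, .y))
    )
  })
}

#' Estimate sizes and concentration from NTA tracks
#'
#' Per accepted track (length >= `min_track_length` frames) the diffusion
#' coefficient is estimated from lag-1 displacements,
#' D = sum(dx^2 + dy^2) / (4 n dt), and inverted through Stokes-Einstein to a
#' hydrodynamic diameter. Concentration is the mean number of particles
#' visible per frame (all tracks, unfiltered) divided by the sampling volume
#' and corrected for dilution. Span and percentiles come from the
#' number-weighted estimated-diameter distribution.
#'
#' @param tracks A track tibble from [simulate_tracks()].
#' @param config The [instrument_config()] used to record the tracks.
#' @return An object of class `"nta_result"`; see [tidy.nta_result()] and
#'   [glance.nta_result()].
#' @export
estimate_from_tracks <- function(tracks, config = instrument_config()) {
  accepted <- dplyr::filter(tracks, .data$n_frames >= config$min_track_length)
  if (nrow(accepted) == 0) {
    abort("No track passes the minimum-length filter: not enough data to size particles.",
          class = "nanocount_insufficient_data")
  }
  d_hat <- purrr::pmap_dbl(
    accepted[c("dx", "dy", "n_frames")],
    function(dx, dy, n_frames) {
      D_hat <- sum(dx^2 + dy^2) / (4 * (n_frames - 1) * config$frame_interval_s)
      diameter_from_diffusion(D_hat, config$temperature_K, config$viscosity_Pa_s)
    }
  )
  mean_per_frame <- sum(tracks$n_frames) / config$n_frames
  conc <- mean_per_frame / config$sampling_volume_ml * config$dilution_factor
  q <- weighted_percentiles(d_hat, c(0.1, 0.5, 0.9))
  structure(
    list(
      estimated_diameters_nm = d_hat,
      particles_per_ml = conc,
      mean_size_nm = mean(d_hat),
      d10_nm = q[1], d50_nm = q[2], d90_nm = q[3],
      span = span(q[1], q[2], q[3]),
      n_tracks = length(d_hat),
      n_tracks_total = nrow(tracks),
      config = config
    ),
    class = "nta_result"
  )
}

#' Simulate a complete NTA measurement
#'
#' Convenience wrapper: [simulate_tracks()] then [estimate_from_tracks()].
#'
#' @inheritParams simulate_tracks
#' @return An `"nta_result"`.
#' @export
simulate_nta <- function(population, config = instrument_config()) {
  estimate_from_tracks(simulate_tracks(population, config), config)
}

#' @export
print.nta_result <- function(x, ...) {
  cat(sprintf(
    "<nta_result> %d sized tracks (of %d): mean %.1f nm, span %.2f, %.3g particles/mL\n",
    x$n_tracks, x$n_tracks_total, x$mean_size_nm, x$span, x$particles_per_ml
  ))
  invisible(x)
}

#' Per-track tidy view of an NTA result
#' @param x An `"nta_result"`.
#' @param ... Unused.
#' @return Tibble with one row per accepted track.
#' @export
tidy.nta_result <- function(x, ...) {
  tibble(track = seq_len(x$n_tracks),
         diameter_nm = x$estimated_diameters_nm)
}

#' One-row summary of an NTA result
#' @param x An `"nta_result"`.
#' @param ... Unused.
#' @return One-row tibble with size, span, concentration and track counts.
#' @export
glance.nta_result <- function(x, ...) {
  tibble(
    mean_size_nm = x$mean_size_nm, d10_nm = x$d10_nm, d50_nm = x$d50_nm,
    d90_nm = x$d90_nm, span = x$span,
    particles_per_ml = x$particles_per_ml,
    n_tracks = x$n_tracks, n_tracks_total = x$n_tracks_total
  )
}
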