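#' Simulate a DLS measurement
#'
#' Forward model of cumulant-analysis dynamic light scattering: the
#' deterministic intensity-weighted z-average and PDI of the population
#' ([z_average_and_pdi()]), optionally perturbed by independent
#' multiplicative Gaussian noise on each reported quantity. With
#' `noise_sd = 0` the result is exact, which makes the simulator useful as a
#' no-noise oracle in tests.
#'
#' @param population A [particle_population()] (or diameter vector).
#' @param noise_sd Relative SD of the multiplicative measurement noise
#'   (default 0).
#' @param config Optional [instrument_config()]; only its `seed` is used.
#' @param seed Optional integer seed (overrides the config seed).
#' @return One-row tibble with `z_average_nm` and `pdi`.
#' @examples
#' simulate_dls(particle_population(rep(100, 5))) # exactly (100, 0)
#' @export
simulate_dls <- function(population, noise_sd = 0, config = NULL, seed = NULL) {
  base <- z_average_and_pdi(population)
  if (noise_sd == 0) return(base)
  seed <- seed %||% (if (!is.null(config)) config$seed)
  with_seed_or_stream(seed, {
    eps <- stats::rnorm(2, 0, noise_sd)
    tibble(z_average_nm = base$z_average_nm * (1 + eps[1]),
           pdi = max(0, base$pdi * (1 + eps[2])))
  })
}
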