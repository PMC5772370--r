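#' Ground-truth particle population
#'
#' The substrate of all simulation in the package: an explicit list of
#' particle diameters suspended in a known volume. Vesicle populations track
#' total membrane area (sum of d^2, proportional to lipid molecules in the
#' shell); solid populations track total core volume (sum of d^3,
#' proportional to excipient mass in the bulk). All destabilisation
#' operations conserve the relevant total.
#'
#' @param diameters Particle diameters in nm (> 0).
#' @param volume_ml Suspension volume in mL the particles live in.
#' @param architecture `"vesicle"` or `"solid"`.
#' @return An object of class `"particle_population"`.
#' @export
particle_population <- function(diameters, volume_ml = 1,
                                architecture = c("vesicle", "solid")) {
  architecture <- match.arg(architecture)
  if (length(diameters) > 0) check_positive(diameters, "diameters")
  check_positive(volume_ml, "volume_ml")
  structure(
    list(diameters = as.numeric(diameters), volume_ml = volume_ml,
         architecture = architecture),
    class = "particle_population"
  )
}

pop_diameters <- function(x) {
  if (inherits(x, "particle_population")) x$diameters else as.numeric(x)
}

#' Generate a lognormal-mixture population
#'
#' Draws particle diameters from a mixture of lognormal modes, the standard
#' model for colloid size distributions. A geometric SD of 1 collapses a mode
#' to its median (useful for monodisperse fixtures). Multimodal mixtures
#' emulate e.g. non-extruded multilamellar vesicle suspensions.
#'
#' @param n Number of particles to draw.
#' @param modes A data frame (or tibble) with columns `median_nm`, `gsd`
#'   (geometric SD, >= 1) and `weight` (mixture weights summing to 1), one
#'   row per mode.
#' @param particles_per_ml Target concentration; sets the suspension volume
#'   to `n / particles_per_ml`. Default 1e12/mL, a typical extruded-liposome
#'   working concentration.
#' @param architecture `"vesicle"` or `"solid"`.
#' @param seed Optional integer seed for reproducibility.
#' @return A [particle_population()].
#' @examples
#' make_population(1000, modes = data.frame(median_nm = 150, gsd = 1.2, weight = 1),
#'                 seed = 1)
#' @export
make_population <- function(n,
                            modes = data.frame(median_nm = 150, gsd = 1.2, weight = 1),
                            particles_per_ml = 1e12,
                            architecture = c("vesicle", "solid"),
                            seed = NULL) {
  if (n <= 0) abort_domain("`n` must be > 0.")
  modes <- as_tibble(modes)
  if (!all(c("median_nm", "gsd", "weight") %in% names(modes))) {
    abort("`modes` needs columns median_nm, gsd, weight.")
  }
  check_positive(modes$median_nm, "median_nm")
  if (any(modes$gsd < 1)) abort_domain("Geometric SD must be >= 1.")
  if (abs(sum(modes$weight) - 1) > 1e-8 || any(modes$weight < 0)) {
    abort_domain("Mixture weights must be non-negative and sum to 1.")
  }
  check_positive(particles_per_ml, "particles_per_ml")
  d <- with_seed_or_stream(seed, {
    comp <- sample.int(nrow(modes), n, replace = TRUE, prob = modes$weight)
    stats::rlnorm(n, meanlog = log(modes$median_nm[comp]),
                  sdlog = log(modes$gsd[comp]))
  })
  particle_population(d, volume_ml = n / particles_per_ml,
                      architecture = match.arg(architecture))
}

#' Particle concentration of a population
#'
#' @param population A [particle_population()].
#' @return Particles per mL.
#' @export
concentration <- function(population) {
  length(population$diameters) / population$volume_ml
}

#' Conserved excipient total of a population
#'
#' The quantity the destabilisation operations conserve: sum of d^2 (membrane
#' area, up to constants) for vesicles, sum of d^3 (core volume) for solid
#' particles. Units nm^2 or nm^3.
#'
#' @param population A [particle_population()].
#' @return A single number.
#' @export
conserved_total <- function(population) {
  p <- if (population$architecture == "vesicle") 2 else 3
  sum(population$diameters^p)
}

#' Ground-truth excipient molecules in a vesicle population
#'
#' Sums the geometric per-vesicle lipid count over all particles; divide by
#' `volume_ml` for molecules per mL, or by the particle count for the mean
#' stoichiometry. Vesicle architecture only.
#'
#' @param population A [particle_population()] with vesicle architecture.
#' @inheritParams theoretical_molecules_per_vesicle
#' @return Total lipid molecules in the population.
#' @export
population_molecules <- function(population, headgroup_area_A2 = 55, leaflets = 2) {
  if (population$architecture != "vesicle") {
    abort("Geometric lipid counting is defined for vesicle populations only.")
  }
  sum(theoretical_molecules_per_vesicle(population$diameters,
                                        headgroup_area_A2, leaflets))
}

#' @export
print.particle_population <- function(x, ...) {
  cat(sprintf(
    "<particle_population> %d %s particle(s) in %.3g mL (%.3g /mL)\n",
    length(x$diameters), x$architecture, x$volume_ml, concentration(x)
  ))
  if (length(x$diameters) > 0) {
    cat(sprintf("  diameters: median %.1f nm, range [%.1f, %.1f] nm\n",
                stats::median(x$diameters), min(x$diameters), max(x$diameters)))
  }
  invisible(x)
}

#' @export
tidy.particle_population <- function(x, ...) {
  tibble(diameter_nm = x$diameters)
}

#' @export
glance.particle_population <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_particles = length(x$diameters),
           particles_per_ml = concentration(x),
           architecture = x$architecture),
    size_summary(x)
  )
}
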