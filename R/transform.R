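# Destabilisation / processing operations on particle populations.
# Vesicle operations conserve total membrane area (sum d^2); solid-particle
# operations conserve total core volume (sum d^3). Lipid lives in the shell
# of a vesicle but in the bulk of a solid lipid nanoparticle, so these are
# the excipient-conserving rules for each architecture.

#' Extrude a vesicle population through a membrane pore
#'
#' Models passage through a track-etched membrane: every vesicle larger than
#' the pore fragments into `ceiling(d^2 / pore^2)` daughters whose diameters
#' are drawn around the pore size (lognormal jitter) and then rescaled so the
#' daughters' total membrane area equals the parent's exactly. Vesicles at or
#' below the pore size pass unchanged. Repeated passages narrow the
#' distribution towards the pore size, raise the particle count, and leave
#' total area (hence total lipid) untouched.
#'
#' @param population A vesicle [particle_population()].
#' @param pore_diameter_nm Pore size in nm (default 100, the standard
#'   polycarbonate membrane for preparing unilamellar liposomes).
#' @param passages Number of consecutive passes (>= 0).
#' @param jitter_gsd Geometric SD of the daughter-size jitter (1 = equal
#'   daughters; default 1.1, i.e. 10\% geometric noise).
#' @param fragmentation_prob Probability that an oversize vesicle actually
#'   fragments on a given passage (default 0.5). Not every large vesicle
#'   meets a pore on each pass, which is why repeated passages are needed in
#'   practice and why size and Span converge gradually rather than in one
#'   step; set to 1 for the idealised every-vesicle-fragments rule.
#' @param seed Optional integer seed.
#' @return The extruded [particle_population()].
#' @export
extrude <- function(population, pore_diameter_nm = 100, passages = 1,
                    jitter_gsd = 1.1, fragmentation_prob = 0.5, seed = NULL) {
  if (population$architecture != "vesicle") {
    abort("extrude() applies to vesicle populations only.",
          class = "nanocount_unsupported_operation")
  }
  check_positive(pore_diameter_nm, "pore_diameter_nm")
  if (passages < 0) abort_domain("`passages` must be >= 0.")
  if (jitter_gsd < 1) abort_domain("`jitter_gsd` must be >= 1.")
  if (fragmentation_prob < 0 || fragmentation_prob > 1) {
    abort_domain("`fragmentation_prob` must lie in [0, 1].")
  }
  with_seed_or_stream(seed, {
    d <- population$diameters
    for (p in seq_len(passages)) {
      big <- d > pore_diameter_nm &
        stats::runif(length(d)) < fragmentation_prob
      if (!any(big)) break
      daughters <- lapply(d[big], function(dp) {
        m <- ceiling(dp^2 / pore_diameter_nm^2)
        raw <- if (jitter_gsd == 1) rep(pore_diameter_nm, m) else
          stats::rlnorm(m, log(pore_diameter_nm), log(jitter_gsd))
        raw * dp / sqrt(sum(raw^2)) # exact area conservation
      })
      d <- c(d[!big], unlist(daughters))
    }
    particle_population(d, population$volume_ml, "vesicle")
  })
}

#' Fuse vesicles pairwise (solvent-type destabilisation)
#'
#' Models bilayer fusion such as that induced by chloroform partitioning into
#' the acyl chains: in each round a fraction of randomly chosen disjoint
#' vesicle pairs merges, the fused diameter being sqrt(d1^2 + d2^2) so that
#' membrane area (lipid content) is conserved. The count falls by one per
#' merge; mean size rises.
#'
#' @param population A vesicle [particle_population()].
#' @param pair_fraction Fraction of available disjoint pairs that merge per
#'   round, in [0, 1].
#' @param rounds Number of fusion rounds.
#' @param seed Optional integer seed.
#' @return The fused [particle_population()].
#' @examples
#' p <- particle_population(c(100, 100))
#' fuse(p, pair_fraction = 1)$diameters # 141.42
#' @export
fuse <- function(population, pair_fraction, rounds = 1, seed = NULL) {
  if (population$architecture != "vesicle") {
    abort("fuse() applies to vesicle populations only.",
          class = "nanocount_unsupported_operation")
  }
  if (pair_fraction < 0 || pair_fraction > 1) {
    abort_domain("`pair_fraction` must lie in [0, 1].")
  }
  with_seed_or_stream(seed, {
    d <- population$diameters
    for (r in seq_len(rounds)) {
      n_pairs <- round(pair_fraction * floor(length(d) / 2))
      if (n_pairs == 0) next
      idx <- sample.int(length(d), 2 * n_pairs)
      a <- idx[seq_len(n_pairs)]
      b <- idx[n_pairs + seq_len(n_pairs)]
      merged <- sqrt(d[a]^2 + d[b]^2)
      d <- c(d[-idx], merged)
    }
    particle_population(d, population$volume_ml, "vesicle")
  })
}

#' Aggregate solid particles under surfactant depletion
#'
#' Models agglutination of solid lipid nanoparticles when steric surfactant
#' coverage is insufficient. `surfactant_fraction` is the coverage relative
#' to a fully stabilising level (1 = fully covered, 0 = bare); the merge
#' propensity is p = 1 - surfactant_fraction^gamma, and particles coalesce
#' into an expected `n * (1 - p)` random clusters. Each cluster fuses into
#' one particle of diameter (sum d^3)^(1/3), conserving core volume exactly.
#' Full coverage returns the population untouched.
#'
#' @param population A solid [particle_population()].
#' @param surfactant_fraction Relative surfactant coverage in [0, 1].
#' @param gamma Merge-propensity exponent (default 2): smaller coverage is
#'   penalised super-linearly.
#' @param seed Optional integer seed.
#' @return The aggregated [particle_population()].
#' @export
aggregate_particles <- function(population, surfactant_fraction, gamma = 2,
                                seed = NULL) {
  if (population$architecture != "solid") {
    abort("aggregate_particles() applies to solid populations only.",
          class = "nanocount_unsupported_operation")
  }
  if (surfactant_fraction < 0 || surfactant_fraction > 1) {
    abort_domain("`surfactant_fraction` must lie in [0, 1].")
  }
  p <- 1 - surfactant_fraction^gamma
  if (p <= 0) return(population)
  with_seed_or_stream(seed, {
    d <- population$diameters
    n_clusters <- max(1L, ceiling(length(d) * (1 - p)))
    cluster <- sample.int(n_clusters, length(d), replace = TRUE)
    merged <- vapply(split(d, cluster), function(g) sum(g^3)^(1 / 3), numeric(1))
    particle_population(unname(merged), population$volume_ml, "solid")
  })
}
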