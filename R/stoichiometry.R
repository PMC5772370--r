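#' Molecules per millilitre from a molar concentration
#'
#' Converts an excipient molar concentration (mol/L) to an absolute number of
#' molecules per mL of suspension. For a 0.125 mM phosphatidylcholine
#' suspension this is 7.5 x 10^16 molecules/mL (2 s.f.), the figure that
#' anchors every per-particle stoichiometry in the package.
#'
#' @param molar_concentration Excipient concentration in mol/L. Vectorised.
#' @return Molecules per mL (count/mL).
#' @examples
#' molecules_per_ml(0.125e-3) # ~7.5e16
#' @export
molecules_per_ml <- function(molar_concentration) {
  check_positive(molar_concentration, "molar_concentration", strict = FALSE)
  molar_concentration * AVOGADRO / 1000
}

#' Molarity from a mass/volume percentage
#'
#' Converts a \% w/v excipient content to molarity: a 10\% w/v cetyl
#' palmitate phase (MW 480.85 g/mol) is 0.208 mol/L.
#'
#' @param mass_percent Mass/volume percentage (g per 100 mL).
#' @param molecular_weight Molecular weight in g/mol.
#' @return Concentration in mol/L.
#' @export
mass_fraction_to_molarity <- function(mass_percent, molecular_weight) {
  check_positive(mass_percent, "mass_percent", strict = FALSE)
  check_positive(molecular_weight, "molecular_weight")
  10 * mass_percent / molecular_weight
}

#' Excipient molecules per particle
#'
#' The core stoichiometric quotient: total molecules per mL divided by
#' particles per mL, i.e. how many excipient molecules build each particle.
#'
#' @param molecules_per_ml Total excipient molecules per mL (> 0).
#' @param particles_per_ml Particle concentration in particles/mL (> 0).
#' @return Molecules per particle (full precision; round for display with
#'   [signif()], the source tables print 2-3 significant figures).
#' @examples
#' molecules_per_particle(7.5e16, 9.4e11) # ~8.0e4 DPPC per liposome
#' @export
molecules_per_particle <- function(molecules_per_ml, particles_per_ml) {
  check_positive(molecules_per_ml, "molecules_per_ml")
  if (any(!is.finite(particles_per_ml)) || any(particles_per_ml <= 0)) {
    abort("`particles_per_ml` must be > 0: molecules per particle is undefined for an empty suspension.",
      class = "nanocount_undefined_stoichiometry")
  }
  molecules_per_ml / particles_per_ml
}

#' Geometric estimate of lipids per vesicle
#'
#' Area-based estimate for a spherical unilamellar vesicle: the membrane area
#' contributed by `leaflets` monolayers (inner + outer for a bilayer) divided
#' by the area one lipid headgroup occupies (55 A^2 for phosphatidylcholine).
#' Scales with diameter squared.
#'
#' @param diameter_nm Vesicle diameter in nm.
#' @param headgroup_area_A2 Area per lipid molecule in square Angstrom.
#' @param leaflets Number of monolayers contributing area (2 for a
#'   unilamellar bilayer vesicle).
#' @return Lipid molecules per vesicle.
#' @examples
#' theoretical_molecules_per_vesicle(162.5) # ~3.0e5
#' @export
theoretical_molecules_per_vesicle <- function(diameter_nm,
                                              headgroup_area_A2 = 55,
                                              leaflets = 2) {
  check_positive(diameter_nm, "diameter_nm")
  check_positive(headgroup_area_A2, "headgroup_area_A2")
  if (any(leaflets < 1)) abort_domain("`leaflets` must be >= 1.")
  radius_A <- diameter_nm * NM_TO_ANGSTROM / 2
  leaflets * 4 * pi * radius_A^2 / headgroup_area_A2
}

#' Particle concentration predicted from stoichiometry
#'
#' Inverts the stoichiometric quotient: given the molecules available per mL
#' and a per-particle molecule count (e.g. the geometric vesicle estimate),
#' predicts how many particles the suspension can hold.
#'
#' @inheritParams molecules_per_particle
#' @param molecules_per_particle Molecules per particle (> 0).
#' @return Particles per mL.
#' @export
predicted_particle_concentration <- function(molecules_per_ml,
                                             molecules_per_particle) {
  check_positive(molecules_per_ml, "molecules_per_ml", strict = FALSE)
  check_positive(molecules_per_particle, "molecules_per_particle")
  molecules_per_ml / molecules_per_particle
}

#' Particle molarity
#'
#' Expresses a particle count concentration as a molar concentration of
#' particles, mol of particles per litre.
#'
#' @param particles_per_ml Particle concentration in particles/mL.
#' @return Particle molarity in mol/L.
#' @export
particle_molarity <- function(particles_per_ml) {
  check_positive(particles_per_ml, "particles_per_ml", strict = FALSE)
  particles_per_ml * 1000 / AVOGADRO
}

#' One-shot stoichiometry summary
#'
#' Combines the conversions above for a single formulation/measurement pair.
#'
#' @param formulation A [formulation()] object (or molar concentration in
#'   mol/L as a bare number).
#' @param particles_per_ml Measured particle concentration (particles/mL).
#' @param molecules_per_ml Optional override of the total molecule count per
#'   mL; defaults to the value implied by the formulation at full precision.
#' @return A one-row tibble with `molecules_per_ml`, `particles_per_ml`,
#'   `molecules_per_particle` and `particle_molarity`.
#' @examples
#' stoichiometry(formulation("DPPC", molar_concentration = 0.125e-3),
#'               particles_per_ml = 9.4e11)
#' @export
stoichiometry <- function(formulation, particles_per_ml,
                          molecules_per_ml = NULL) {
  conc <- if (inherits(formulation, "formulation")) {
    formulation$molar_concentration
  } else {
    as.numeric(formulation)
  }
  n_ml <- molecules_per_ml %||% nanocount::molecules_per_ml(conc)
  tibble(
    molecules_per_ml = n_ml,
    particles_per_ml = particles_per_ml,
    molecules_per_particle = molecules_per_particle(n_ml, particles_per_ml),
    particle_molarity = particle_molarity(particles_per_ml)
  )
}
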