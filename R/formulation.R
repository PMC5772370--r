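#' Describe a colloidal formulation
#'
#' Captures the excipient bookkeeping needed for per-particle stoichiometry:
#' how much excipient the suspension holds, and (for vesicles) the membrane
#' geometry used by the area-based lipid-count model. The concentration may
#' be given directly in mol/L or as \% w/v plus molecular weight.
#'
#' For mixed-lipid vesicles the convention here is that `molar_concentration`
#' refers to the phospholipid whose headgroup area is supplied; sterols such
#' as cholesterol are excluded from the stoichiometry.
#'
#' @param excipient_name Label for the structural excipient (e.g. "DPPC").
#' @param molar_concentration Excipient concentration in mol/L.
#' @param mass_percent Alternative input: \% w/v (requires
#'   `molecular_weight`).
#' @param molecular_weight g/mol; used to convert `mass_percent` and kept for
#'   reporting.
#' @param architecture `"vesicle"` (excipient in the shell, area-scaling) or
#'   `"solid"` (excipient in the core, volume-scaling).
#' @param headgroup_area_A2 Area per lipid headgroup in square Angstrom
#'   (vesicles only; default 55, phosphatidylcholine).
#' @param leaflets Monolayers contributing membrane area (2 = unilamellar).
#' @return An object of class `"formulation"`.
#' @examples
#' formulation("DPPC", molar_concentration = 0.125e-3)
#' formulation("cetyl palmitate", mass_percent = 10,
#'             molecular_weight = 480.85, architecture = "solid")
#' @export
formulation <- function(excipient_name,
                        molar_concentration = NULL,
                        mass_percent = NULL,
                        molecular_weight = NULL,
                        architecture = c("vesicle", "solid"),
                        headgroup_area_A2 = 55,
                        leaflets = 2) {
  architecture <- match.arg(architecture)
  if (is.null(molar_concentration)) {
    if (is.null(mass_percent) || is.null(molecular_weight)) {
      abort("Supply either `molar_concentration`, or `mass_percent` together with `molecular_weight`.")
    }
    molar_concentration <- mass_fraction_to_molarity(mass_percent, molecular_weight)
  }
  check_positive(molar_concentration, "molar_concentration", strict = FALSE)
  if (architecture == "vesicle") {
    check_positive(headgroup_area_A2, "headgroup_area_A2")
    if (leaflets < 1) abort_domain("`leaflets` must be >= 1.")
  }
  structure(
    list(
      excipient_name = excipient_name,
      molar_concentration = molar_concentration,
      molecular_weight = molecular_weight,
      architecture = architecture,
      headgroup_area_A2 = if (architecture == "vesicle") headgroup_area_A2 else NA_real_,
      leaflets = if (architecture == "vesicle") leaflets else NA_integer_
    ),
    class = "formulation"
  )
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf(
    "<formulation> %s (%s): %.4g mol/L (%.3g molecules/mL)\n",
    x$excipient_name, x$architecture, x$molar_concentration,
    molecules_per_ml(x$molar_concentration)
  ))
  if (x$architecture == "vesicle") {
    cat(sprintf("  headgroup area %g A^2, %d leaflet(s)\n",
                x$headgroup_area_A2, x$leaflets))
  }
  invisible(x)
}

#' Read a formulation from a YAML file
#'
#' Expected keys: `name`; either `molar_concentration_mM` or `mass_percent`
#' plus `molecular_weight`; optional `architecture`, `headgroup_area_A2`,
#' `leaflets`.
#'
#' @param path Path to a YAML file.
#' @return A [formulation()] object.
#' @export
read_formulation <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name)) abort("Formulation YAML needs a `name` key.")
  formulation(
    excipient_name = y$name,
    molar_concentration = if (!is.null(y$molar_concentration_mM)) y$molar_concentration_mM / 1000,
    mass_percent = y$mass_percent,
    molecular_weight = y$molecular_weight,
    architecture = y$architecture %||% "vesicle",
    headgroup_area_A2 = y$headgroup_area_A2 %||% 55,
    leaflets = y$leaflets %||% 2
  )
}
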