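Package: nanocount
Title: Nanoparticle Concentration as a Structural and Stability Probe for Colloids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for using nanoparticle concentration, alongside particle
    size, to characterise pharmaceutical colloids (liposomes, solid lipid
    nanoparticles). Computes per-particle excipient stoichiometry from molar
    excipient concentration and particle counts, geometric predictions of
    lipids per vesicle and particle concentration, number- and
    intensity-weighted dispersity metrics (PDI, Span), and size-concentration
    correlation with instability classification. Includes a synthetic colloid
    generator (extrusion, solvent-induced vesicle fusion, surfactant-depletion
    aggregation, all excipient-conserving) and forward simulators of
    nanoparticle tracking analysis (Brownian tracks, number-weighted sizing,
    counting-based concentration) and dynamic light scattering
    (intensity-weighted z-average and cumulant PDI), so the whole analysis
    pipeline can be exercised end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
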