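# Shared fixtures built in code. The liposome and SLN measurement tables
# are also shipped as packaged CSVs; the in-code copies keep unit tests
# independent of the reader under test.

liposome_series <- function() {
  tibble::tibble(
    condition = paste0("step", 0:3),
    size_nm = c(116.5, 171.8, 491.9, 657.6),
    size_sd_nm = c(1.8, 2.3, 19.4, 17.0),
    particles_per_ml = c(9.4e11, 6.4e11, 3.1e11, 2.1e11),
    molecules_per_particle = c(8.0e4, 11.7e4, 24.2e4, 35.7e4)
  )
}

sln_series <- function() {
  tibble::tibble(
    condition = paste0("SLN", 1:5),
    poloxamer_percent = c(5, 3, 1, 0.25, 0.1),
    size_nm = c(232.1, 284.2, 499.1, 540.9, 1644.3),
    particles_per_ml = c(61.3e12, 33.6e12, 27.2e12, 23.3e12, 4.8e12),
    molecules_per_particle = c(2.0e6, 3.7e6, 4.6e6, 5.4e6, 2.6e7)
  )
}

# broad near-pore lognormal start used for extrusion-series simulations
broad_start <- function(n = 4000, seed = 42) {
  make_population(
    n,
    modes = data.frame(median_nm = 150, gsd = 1.6, weight = 1),
    particles_per_ml = 7.8e10, seed = seed
  )
}

# five-level chloroform-like fusion sweep; returns per-step z-average and
# concentration
fusion_sweep <- function(seed, n = 4000, steps = 4) {
  base <- make_population(
    n, modes = data.frame(median_nm = 116, gsd = 1.05, weight = 1),
    particles_per_ml = 9.4e11, seed = seed
  )
  purrr::map_dfr(0:steps, function(i) {
    p <- if (i == 0) base else
      fuse(base, pair_fraction = 1 - 0.75^i, rounds = i, seed = seed + i)
    tibble::tibble(step = i,
                   size_nm = z_average_and_pdi(p)$z_average_nm,
                   particles_per_ml = concentration(p))
  })
}
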