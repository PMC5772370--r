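test_that("Stokes-Einstein relation and its inverse", {
  D <- stokes_einstein(100, 298.15, 8.9e-4)
  expect_equal(D, 4.91e-12, tolerance = 0.002)
  expect_equal(diameter_from_diffusion(D), 100, tolerance = 1e-12)
  set.seed(71)
  d <- runif(20, 30, 2000)
  expect_equal(diameter_from_diffusion(stokes_einstein(d)), d,
               tolerance = 1e-12)
  expect_equal(stokes_einstein(200), D / 2, tolerance = 1e-12)
  expect_error(stokes_einstein(-5), class = "nanocount_domain_error")
  expect_error(instrument_config(dilution_factor = 0.5),
               class = "nanocount_domain_error")
})

test_that("track simulation: counts follow the dilution and steps the diffusion law", {
  pop <- make_population(5000, modes = data.frame(median_nm = 100, gsd = 1,
                                                  weight = 1),
                         particles_per_ml = 9.4e11, seed = 81)
  # dilute to (effectively) zero concentration: no tracks
  empty_cfg <- instrument_config(dilution_factor = 1e12, seed = 1)
  expect_equal(nrow(simulate_tracks(pop, empty_cfg)), 0)
  cfg <- instrument_config(dilution_factor = 200, n_frames = 128, seed = 3)
  tr <- simulate_tracks(pop, cfg)
  expect_identical(tr$dx, simulate_tracks(pop, cfg)$dx)
  steps <- unlist(c(tr$dx, tr$dy))
  expect_gt(length(steps), 1e5)
  expected_var <- 2 * stokes_einstein(100) * cfg$frame_interval_s
  expect_equal(var(steps), expected_var, tolerance = 0.05)
})

test_that("a planted constant-step track is sized by the closed form", {
  cfg <- instrument_config(seed = NULL)
  sx <- 4e-7
  sy <- 3e-7
  tr <- tibble::tibble(track = 1L, diameter_true_nm = NA_real_,
                       n_frames = 21L,
                       dx = list(rep(sx, 20)), dy = list(rep(sy, 20)))
  res <- estimate_from_tracks(tr, cfg)
  D_hat <- (20 * (sx^2 + sy^2)) / (4 * 20 * cfg$frame_interval_s)
  expect_equal(res$estimated_diameters_nm, diameter_from_diffusion(D_hat))
  short <- dplyr::mutate(tr, n_frames = 5L)
  expect_error(estimate_from_tracks(short, cfg),
               class = "nanocount_insufficient_data")
})

test_that("NTA sizing is consistent on a monodisperse sample", {
  pop <- make_population(5000, modes = data.frame(median_nm = 100, gsd = 1,
                                                  weight = 1),
                         particles_per_ml = 9.4e11, seed = 5)
  cfg <- instrument_config(dilution_factor = 200, n_frames = 40, seed = 7)
  res <- simulate_nta(pop, cfg)
  expect_gt(res$n_tracks, 300)
  expect_equal(res$d50_nm, 100, tolerance = 0.06)
  expect_equal(glance(res)$particles_per_ml, 9.4e11, tolerance = 0.15)
  expect_equal(nrow(tidy(res)), res$n_tracks)
})

test_that("the concentration estimator is unbiased over repeated runs", {
  pop <- make_population(2000, modes = data.frame(median_nm = 150, gsd = 1.2,
                                                  weight = 1),
                         particles_per_ml = 1e12, seed = 11)
  cfg0 <- instrument_config(dilution_factor = 2000, n_frames = 60)
  est <- sapply(1:50, function(s) {
    cfg <- instrument_config(dilution_factor = 2000, n_frames = 60, seed = s)
    simulate_nta(pop, cfg)$particles_per_ml
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1e12), 2 * se + 1e-9)
})

test_that("DLS forward model: exact in the no-noise limit, unbiased with noise", {
  expect_equal(simulate_dls(rep(100, 8)),
               tibble::tibble(z_average_nm = 100, pdi = 0))
  # number distribution rich in 300 nm particles with a heavy large tail:
  # intensity weighting pulls DLS far above the number mean
  pop <- make_population(3000, modes = data.frame(median_nm = c(300, 800),
                                                  gsd = c(1.2, 1.3),
                                                  weight = c(0.9, 0.1)),
                         seed = 13)
  dls <- simulate_dls(pop)
  expect_gt(dls$z_average_nm, mean(pop$diameters))
  z <- sapply(1:100, function(s) simulate_dls(pop, noise_sd = 0.01,
                                              seed = s)$z_average_nm)
  expect_equal(mean(z), dls$z_average_nm, tolerance = 0.005)
})

test_that("end-to-end: simulated NTA recovers the per-particle lipid stoichiometry", {
  pop <- make_population(20000, modes = data.frame(median_nm = 162.5,
                                                   gsd = 1.05, weight = 1),
                         particles_per_ml = 2.3e11, seed = 19)
  cfg <- instrument_config(dilution_factor = 50, n_frames = 128, seed = 20)
  nta <- simulate_nta(pop, cfg)
  truth_npp <- population_molecules(pop) / length(pop$diameters)
  N_per_ml <- population_molecules(pop) / pop$volume_ml
  recovered_npp <- molecules_per_particle(N_per_ml, nta$particles_per_ml)
  expect_equal(recovered_npp, truth_npp, tolerance = 0.15)
  # and the number-weighted NTA mean sits below the DLS z-average for a
  # polydisperse sample
  poly <- make_population(20000, modes = data.frame(median_nm = c(150, 500),
                                                    gsd = c(1.2, 1.2),
                                                    weight = c(0.8, 0.2)),
                          particles_per_ml = 2.3e11, seed = 21)
  nta_poly <- simulate_nta(poly, cfg)
  expect_lt(nta_poly$mean_size_nm, simulate_dls(poly)$z_average_nm)
})
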