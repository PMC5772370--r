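test_that("lognormal-mixture generator hits its medians and is reproducible", {
  mono <- make_population(50, modes = data.frame(median_nm = 150, gsd = 1,
                                                 weight = 1), seed = 1)
  expect_equal(mono$diameters, rep(150, 50))
  big <- make_population(1e4, modes = data.frame(median_nm = 569, gsd = 1.5,
                                                 weight = 1), seed = 2)
  expect_equal(median(big$diameters), 569, tolerance = 0.03)
  a <- make_population(500, seed = 99)
  b <- make_population(500, seed = 99)
  expect_identical(a$diameters, b$diameters)
  expect_false(identical(a$diameters, make_population(500, seed = 98)$diameters))
  expect_error(make_population(100, modes = data.frame(median_nm = 100,
                                                       gsd = 0.8, weight = 1)),
               class = "nanocount_domain_error")
  expect_error(make_population(100, modes = data.frame(median_nm = 100,
                                                       gsd = 1.2, weight = 0.5)),
               class = "nanocount_domain_error")
})

test_that("population bookkeeping: concentration, conserved totals, tidiers", {
  p <- particle_population(c(100, 200), volume_ml = 1e-9)
  expect_equal(concentration(p), 2e9)
  expect_equal(conserved_total(p), 100^2 + 200^2)
  s <- particle_population(c(100, 200), architecture = "solid")
  expect_equal(conserved_total(s), 100^3 + 200^3)
  expect_equal(tidy(p)$diameter_nm, c(100, 200))
  g <- glance(p)
  expect_equal(g$n_particles, 2)
  expect_equal(
    population_molecules(p),
    sum(theoretical_molecules_per_vesicle(c(100, 200)))
  )
  expect_error(population_molecules(s), "vesicle")
})

test_that("extrusion fragments oversize vesicles and conserves membrane area", {
  one <- particle_population(300, volume_ml = 1)
  out <- extrude(one, 100, passages = 1, jitter_gsd = 1,
                 fragmentation_prob = 1, seed = 1)
  expect_equal(out$diameters, rep(100, 9))
  small <- particle_population(c(60, 80, 99.9))
  expect_identical(extrude(small, 100, passages = 3, seed = 1)$diameters,
                   small$diameters)
  p <- broad_start(seed = 7)
  for (jit in c(1, 1.15)) {
    e <- extrude(p, 100, passages = 2, jitter_gsd = jit, seed = 3)
    expect_equal(conserved_total(e), conserved_total(p), tolerance = 1e-6)
    expect_gte(length(e$diameters), length(p$diameters))
    expect_lte(mean(e$diameters), mean(p$diameters))
  }
  solid <- make_population(10, architecture = "solid", seed = 1)
  expect_error(extrude(solid), class = "nanocount_unsupported_operation")
})

test_that("consecutive extrusions compose: k1 then k2 passes matches k1+k2 in distribution", {
  stat <- function(passes) {
    sapply(1:12, function(s) {
      p <- broad_start(n = 1500, seed = 200 + s)
      q <- if (length(passes) == 1) extrude(p, passages = passes, seed = s) else
        extrude(extrude(p, passages = passes[1], seed = s),
                passages = passes[2], seed = 1000 + s)
      c(n = length(q$diameters), m = mean(q$diameters))
    })
  }
  a <- stat(4)
  b <- stat(c(2, 2))
  se <- function(x, y) sqrt(var(x) / length(x) + var(y) / length(y))
  expect_lt(abs(mean(a["n", ]) - mean(b["n", ])), 3 * se(a["n", ], b["n", ]))
  expect_lt(abs(mean(a["m", ]) - mean(b["m", ])), 3 * se(a["m", ], b["m", ]))
})

test_that("vesicle fusion merges by membrane area and thins the suspension", {
  two <- particle_population(c(100, 100))
  fused <- fuse(two, pair_fraction = 1, seed = 1)
  expect_equal(fused$diameters, sqrt(2) * 100, tolerance = 1e-12)
  p <- broad_start(n = 1000, seed = 9)
  expect_identical(fuse(p, pair_fraction = 0, seed = 2)$diameters, p$diameters)
  f <- fuse(p, pair_fraction = 0.6, rounds = 2, seed = 2)
  expect_equal(conserved_total(f), conserved_total(p), tolerance = 1e-6)
  expect_lt(length(f$diameters), length(p$diameters))
  # increasing fusion extent: size strictly up, count strictly down
  sw <- fusion_sweep(seed = 13)
  expect_true(all(diff(sw$size_nm) > 0))
  expect_true(all(diff(sw$particles_per_ml) < 0))
})

test_that("surfactant-depletion aggregation merges by core volume", {
  two <- particle_population(c(100, 100), architecture = "solid")
  merged <- aggregate_particles(two, surfactant_fraction = 0, seed = 1)
  expect_equal(merged$diameters, 2^(1 / 3) * 100, tolerance = 1e-9)
  expect_equal(round(merged$diameters, 2), 125.99)
  p <- make_population(2000, modes = data.frame(median_nm = 230, gsd = 1.15,
                                                weight = 1),
                       particles_per_ml = 6.1e13, architecture = "solid",
                       seed = 17)
  expect_identical(aggregate_particles(p, 1, seed = 3)$diameters, p$diameters)
  a <- aggregate_particles(p, 0.3, seed = 3)
  expect_equal(conserved_total(a), conserved_total(p), tolerance = 1e-6)
  # poloxamer-like sweep 5% -> 0.1% (coverage relative to 5%)
  sweep <- purrr::map_dfr(c(5, 3, 1, 0.25, 0.1) / 5, function(f) {
    q <- aggregate_particles(p, f, seed = 23)
    tibble::tibble(size_nm = size_summary(q)$mean_number_nm,
                   particles_per_ml = concentration(q))
  })
  expect_true(all(diff(sweep$size_nm) > 0))
  expect_true(all(diff(sweep$particles_per_ml) < 0))
  ves <- particle_population(c(100, 100))
  expect_error(aggregate_particles(ves, 0.5),
               class = "nanocount_unsupported_operation")
})

test_that("transforms are seed-deterministic and seed-stable in distribution", {
  p <- broad_start(n = 800, seed = 31)
  expect_identical(extrude(p, seed = 5)$diameters, extrude(p, seed = 5)$diameters)
  expect_identical(fuse(p, 0.5, seed = 5)$diameters, fuse(p, 0.5, seed = 5)$diameters)
  means <- sapply(1:20, function(s) mean(extrude(p, passages = 2, seed = s)$diameters))
  # different seeds agree statistically: each run within 3 SE-equivalents of
  # the cross-seed mean
  expect_true(all(abs(means - mean(means)) < 3 * sd(means) + 1e-9))
  grp <- matrix(means, ncol = 2)
  se <- sqrt(var(grp[, 1]) / 10 + var(grp[, 2]) / 10)
  expect_lt(abs(mean(grp[, 1]) - mean(grp[, 2])), 3 * se)
})
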