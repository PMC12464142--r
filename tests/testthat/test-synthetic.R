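test_that("pair energy closed forms: LJ zero crossing and well depth", {
  # two neutral LJ-only sites, bodies 1 and 2
  pp <- microhydrate:::.make_pairs(c(1L, 2L), charge = c(0, 0),
                                   eps = c(0.2, 0.2), sigma = c(3, 3))
  at <- function(r) microhydrate:::.pair_energy(rbind(c(0, 0, 0),
                                                      c(r, 0, 0)), pp)
  expect_equal(at(3), 0, tolerance = 1e-12)           # r = sigma
  expect_equal(at(2^(1 / 6) * 3), -0.2, tolerance = 1e-12)  # minimum -eps
  # charged pair adds the Coulomb term exactly
  pq <- microhydrate:::.make_pairs(c(1L, 2L), charge = c(0.4, -0.4),
                                   eps = c(0, 0), sigma = c(1, 1))
  r <- 3.2
  expect_equal(microhydrate:::.pair_energy(rbind(c(0, 0, 0), c(r, 0, 0)), pq),
               332.06371 * 0.4 * -0.4 / r, tolerance = 1e-12)
})

test_that("classical energy: H-bonded dimer is bound, oracle agreement, overlap error", {
  dimer <- make_water_dimer(2.9)
  e <- classical_energy(dimer)
  expect_lt(e, 0)
  # independent oracle: direct double loop over inter-fragment sites
  p <- ff_params()$water
  q <- rep(p$charge, 2); eps <- rep(p$eps, 2); sig <- rep(p$sigma, 2)
  e_direct <- 0
  for (i in 1:3) for (j in 4:6) {
    r <- sqrt(sum((dimer$coords[i, ] - dimer$coords[j, ])^2))
    sr6 <- ((sig[i] + sig[j]) / 2 / r)^6
    e_direct <- e_direct + 332.06371 * q[i] * q[j] / r +
      4 * sqrt(eps[i] * eps[j]) * (sr6^2 - sr6)
  }
  expect_equal(e, e_direct, tolerance = 1e-10)
  # overlapping sites -> singular-configuration error (fragments fixed
  # from the intact geometry, as for any rigid-body move)
  f_dimer <- perceive_fragments(dimer)
  clash <- dimer
  clash$coords[4, ] <- clash$coords[1, ] + c(1e-4, 0, 0)
  expect_error(classical_energy(clash, f = f_dimer), "singular|overlap")
  # a single fragment has zero inter-fragment energy
  expect_identical(classical_energy(water_template()), 0)
})

test_that("sampler: trivial case, determinism, elitism, descent", {
  bare <- sample_clusters(sampler_config(0, seed = 3))
  expect_length(bare, 1L)
  expect_identical(bare[[1]]$elements, imidazole_template()$elements)
  expect_identical(attr(bare[[1]], "classical_energy"), 0)

  a <- sample_clusters(sampler_config(2, pool = 2, iterations = 4,
                                      seed = 17))
  b <- sample_clusters(sampler_config(2, pool = 2, iterations = 4,
                                      seed = 17))
  expect_identical(lapply(a, `[[`, "coords"), lapply(b, `[[`, "coords"))
  expect_identical(vapply(a, attr, numeric(1), "classical_energy"),
                   vapply(b, attr, numeric(1), "classical_energy"))
  # returned structures are sorted by energy
  ea <- vapply(a, attr, numeric(1), "classical_energy")
  expect_true(!is.unsorted(ea))
  # more search effort never worsens the best energy (elitist pool)
  short <- sample_clusters(sampler_config(2, pool = 2, iterations = 0,
                                          seed = 31))
  long <- sample_clusters(sampler_config(2, pool = 2, iterations = 12,
                                         seed = 31))
  expect_lte(attr(long[[1]], "classical_energy"),
             attr(short[[1]], "classical_energy") + 1e-12)
  # all returned geometries are clash-free valid clusters
  f <- perceive_fragments(long[[1]])
  expect_identical(sort(f$formulas), c("C3H4N2", "H2O", "H2O"))
})

test_that("1-water global minimum is imidazole-bound, vs a coarse grid scan", {
  best <- sample_clusters(sampler_config(1, pool = 4, iterations = 12,
                                         seed = 7))[[1]]
  e_best <- attr(best, "classical_energy")
  # coarse grid oracle over placement directions, radii and orientations
  efn <- microhydrate:::.energy_fn(1, "imidazole", ff_params())
  e_grid <- Inf
  for (theta in seq(0, pi, length.out = 7))
    for (phi in seq(0, 2 * pi, length.out = 13)[-13])
      for (r in c(2.8, 3.2, 3.6))
        for (a1 in seq(0, 2 * pi, length.out = 5)[-5])
          for (a2 in seq(0, pi, length.out = 3)) {
            par <- c(r * sin(theta) * cos(phi), r * sin(theta) * sin(phi),
                     r * cos(theta), a1, a2, 0)
            e <- efn(par)
            if (is.finite(e)) e_grid <- min(e_grid, e)
          }
  # the sampler (which also minimises locally) must beat the raw grid
  expect_lte(e_best, e_grid)
  # and its minimum is a genuine single H-bond to N3 or to N1-H
  census <- detect_contacts(best)$census
  expect_identical(unname(census["N3_accepted"] + census["N1H_donated"]),
                   1L)
})

test_that("mock energies: exact at zero noise, bias per added molecule", {
  cfg0 <- mock_qm_config(method_bias = c(ref = 0, biased = 0.5),
                         noise_sd = 0)
  wat <- water_template()
  imz <- imidazole_template()
  cl <- sample_clusters(sampler_config(2, pool = 2, iterations = 3,
                                       seed = 13))
  e_ref <- mock_qm_energies(c(list(imz, wat), cl[1]), cfg0, "ref")
  # zero bias, zero noise: energy minus the monomer baseline equals the
  # classical energy exactly
  e_class <- attr(cl[[1]], "classical_energy")
  base <- microhydrate:::.E0_IMZ + 2 * microhydrate:::.E0_WATER
  expect_equal(convert_energy(e_ref[3] - base, "hartree", "kcal/mol"),
               e_class, tolerance = 1e-9)
  expect_equal(convert_energy(e_ref[2] - microhydrate:::.E0_WATER,
                              "hartree", "kcal/mol"), 0,
               tolerance = 1e-9)
  # bias b per added molecule: binding-energy deviation is exactly n b
  e_b <- mock_qm_energies(c(list(imz, wat), cl[1]), cfg0, "biased")
  lad_r <- energy_ladder(2, e_ref[3], E_water = e_ref[2], E_imz = e_ref[1])
  lad_b <- energy_ladder(2, e_b[3], E_water = e_b[2], E_imz = e_b[1])
  dev <- convert_energy(binding_energy(lad_b, 2) - binding_energy(lad_r, 2),
                        "hartree", "kcal/mol")
  expect_equal(dev, 2 * 0.5, tolerance = 1e-9)
  expect_error(mock_qm_energies(cl[1], cfg0, "nope"), "unknown method")
})

test_that("noisy-bias MAD agrees with a Monte-Carlo oracle over 50 seeds", {
  b <- 0.5; sd_ <- 0.2
  sizes <- 1:4
  cfg <- mock_qm_config(method_bias = c(ref = 0, biased = b),
                        noise_sd = sd_)
  wat <- water_template()
  imz <- imidazole_template()
  structs <- lapply(sizes, function(n) {
    sample_clusters(sampler_config(n, pool = 2, iterations = 2,
                                   seed = 50 + n))[[1]]
  })
  mads <- vapply(1:50, function(s) {
    er <- mock_qm_energies(c(list(imz, wat), structs), cfg, "ref",
                           seed = s)
    eb <- mock_qm_energies(c(list(imz, wat), structs), cfg, "biased",
                           seed = s)
    lr <- energy_ladder(sizes, er[-(1:2)], E_water = er[2], E_imz = er[1])
    lb <- energy_ladder(sizes, eb[-(1:2)], E_water = eb[2], E_imz = eb[1])
    mean(abs(convert_energy(binding_energy(lb) - binding_energy(lr),
                            "hartree", "kcal/mol")))
  }, numeric(1))
  # Monte-Carlo oracle from the generative formula: deviation(n) =
  # n b + (eps_cl_b - eps_cl_r) - n (eps_w_b - eps_w_r) -
  # (eps_imz_b - eps_imz_r), each eps ~ N(0, sd)
  set.seed(999)
  oracle <- replicate(4000, {
    dw <- rnorm(1, 0, sd_) - rnorm(1, 0, sd_)
    di <- rnorm(1, 0, sd_) - rnorm(1, 0, sd_)
    dc <- rnorm(length(sizes), 0, sd_) - rnorm(length(sizes), 0, sd_)
    mean(abs(sizes * b + dc - sizes * dw - di))
  })
  se <- sd(mads) / sqrt(length(mads))
  expect_lt(abs(mean(mads) - mean(oracle)), 3 * se + 3 * sd(oracle) / sqrt(4000))
})

test_that("mock frequencies: counts and positivity per composition", {
  cfg <- mock_qm_config()
  ar <- structure_xyz("Ar", matrix(0, 1, 3))
  expect_length(mock_frequencies(ar, cfg)$frequencies, 0L)
  expect_length(mock_frequencies(water_template(), cfg)$frequencies, 3L)
  # assembled IMZ(H2O)6: 27 atoms -> 75 modes, all positive
  par <- as.numeric(vapply(1:6, function(w) {
    u <- c(cos(w), sin(w), 0.5 * (-1)^w)
    c(4 * u / sqrt(sum(u^2)), 0.3 * w, 0.1 * w, 0)
  }, numeric(6)))
  s6 <- pose_structure(par, solute = "imidazole")
  fs <- mock_frequencies(s6, cfg)
  expect_length(fs$frequencies, 75L)
  expect_true(all(fs$frequencies > 0))
  # deterministic for a fixed seed
  expect_identical(mock_frequencies(s6, cfg, seed = 5)$frequencies,
                   mock_frequencies(s6, cfg, seed = 5)$frequencies)
})

test_that("study generation is deterministic and self-consistent", {
  a <- generate_study(n_max = 2, members = 2, seed = 99, pool = 2,
                      iterations = 3, maxit_local = 15)
  b <- generate_study(n_max = 2, members = 2, seed = 99, pool = 2,
                      iterations = 3, maxit_local = 15)
  expect_identical(a$energy_table$values, b$energy_table$values)
  expect_identical(a$clusters[[2]]$gas[[1]]$structure$coords,
                   b$clusters[[2]]$gas[[1]]$structure$coords)
  # solvated copies carry the same geometry with the solvent tag
  expect_identical(a$clusters[[1]]$imzw_solv[[1]]$coords,
                   a$clusters[[1]]$gas[[1]]$structure$coords)
  expect_identical(a$clusters[[1]]$imzw_solv[[1]]$phase, "solvent")
  # every stored member has matching mode counts
  for (cl in a$clusters) {
    for (m in cl$gas)
      expect_length(m$freqs$frequencies,
                    3L * n_atoms(m$structure) - 6L)
  }
})
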