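test_that("spec validation rejects out-of-range parameters", {
  expect_error(bilayer_spec(scd_target = 1.2), "scd_target")
  expect_error(bilayer_spec(scd_target = -0.6), "scd_target")
  expect_error(bilayer_spec(temperature = 0), "temperature")
  expect_error(bilayer_spec(apl_target = -1), "apl_target")
  expect_error(bilayer_spec(n_per_leaflet = 0), "n_per_leaflet")
  expect_error(bilayer_spec(solute_pmf = "gaussian"), "solute_pmf")
})

test_that("builder counts and box area follow the spec arithmetic", {
  ens <- build_bilayer_system(small_spec(n_per_leaflet = 8, hydration = 8))
  cnt <- species_counts(ens)
  gt <- ground_truth(ens)
  expect_identical(unname(cnt["water"]), 16L * 8L)
  expect_identical(unname(cnt["lipid-head"]), 16L)
  expect_identical(unname(cnt["solute"]), 10L)
  # ion count from slab volume and salt concentration
  slab_nm3 <- 128 * memperm:::WATER_VOLUME_NM3
  expect_identical(unname(gt$counts[["sodium"]]),
                   as.integer(round(0.150 * slab_nm3 * 1e-24 *
                                      memperm:::AVOGADRO)))
  # lattice area identity: Lx * Ly = n_per_leaflet * apl_target
  ens2 <- build_bilayer_system(small_spec(n_per_leaflet = 4, apl_target = 0.5,
                                          hydration = 30, n_solute = 0))
  expect_equal(prod(ens2$box[1, 1:2]), 2.0, tolerance = 1e-12)
  # zero-solute case leaves everything else unchanged
  expect_false("solute" %in% ens2$particles$species)
})

test_that("builder refuses aqueous slabs too thin to hold a bulk region", {
  expect_error(build_bilayer_system(small_spec(n_per_leaflet = 4,
                                               apl_target = 0.5,
                                               hydration = 1)),
               "no bulk region")
})

test_that("identical spec and seed give bit-identical ensembles", {
  a <- build_bilayer_system(small_spec())
  b <- build_bilayer_system(small_spec())
  expect_identical(a$frames, b$frames)
  c <- build_bilayer_system(small_spec(seed = 12L))
  expect_false(identical(a$frames[[1]], c$frames[[1]]))
})

test_that("solute position sampler reproduces the Boltzmann density", {
  # flat PMF -> uniform draws
  z <- sample_solute_positions(function(z) 0 * z, c(-2, 3), 1e5, 330, seed = 2)
  ks <- suppressWarnings(stats::ks.test(z, "punif", -2, 3))
  expect_gt(ks$p.value, 0.01)
  # harmonic PMF with kappa = RT/sigma^2 -> Gaussian with known sigma
  sigma <- 0.3
  kappa <- RT_330 / sigma^2
  z <- sample_solute_positions(function(z) 0.5 * kappa * z^2, c(-2, 2),
                               1e6, 330, seed = 3)
  expect_lt(abs(sd(z) - sigma) / sigma, 0.01)
  # double-well PMF -> histogram matches the quadrature oracle bin by bin
  dw <- double_well(a = 5, b = 1)
  z <- sample_solute_positions(dw, c(-1.5, 1.5), 1e6, 330, seed = 4)
  breaks <- seq(-1.5, 1.5, by = 0.1)
  obs <- hist(z, breaks = breaks, plot = FALSE)$density
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  expected <- boltzmann_density(dw, mid)
  expect_lt(max(abs(obs - expected) / expected), 0.05)
  # non-finite PMF is rejected
  expect_error(suppressWarnings(
    sample_solute_positions(function(z) log(z), c(-1, 1), 10, 330)),
    "non-finite")
})

test_that("orientation samples realize the target order parameter", {
  scd_of <- function(v) mean((3 * v[, 3]^2 - 1) / 2)
  # perpendicular limit is exact
  v <- generate_orientation_sample(-0.5, 1000, seed = 5)
  expect_equal(scd_of(v), -0.5, tolerance = 1e-12)
  expect_true(all(abs(sqrt(rowSums(v^2)) - 1) < 1e-12))
  # isotropic case
  v <- generate_orientation_sample(0, 1e5, seed = 6)
  expect_lt(abs(scd_of(v)), 3 / sqrt(1e5))
  # mixture cases converge to the analytic moment
  for (target in c(-0.2, 0.6)) {
    v <- generate_orientation_sample(target, 1e6, seed = 7)
    expect_lt(abs(scd_of(v) - target), 0.002)
  }
  expect_error(generate_orientation_sample(1.5, 10), "scd_target")
})
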