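uniform_box_ensemble <- function(n = 1000, box = c(4, 4, 10), seed = 21) {
  set.seed(seed)
  particles <- data.frame(species = "water", mass = 1, electron_count = 1,
                          residue = seq_len(n), leaflet = "none",
                          carbon_index = NA_integer_, parent = NA_integer_)
  xyz <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  particle_ensemble(list(xyz), box, particles)
}

test_that("uniform particles give a flat profile with an exact integral", {
  ens <- uniform_box_ensemble()
  p <- compute_density_profile(ens, "water", "mass", 0.5, recenter = FALSE)
  # conservation: integral x area recovers the total mass exactly
  expect_equal(sum(p$value) * p$bin_width * p$box_area, 1000,
               tolerance = 1e-9)
  # flat at 1000/160 = 6.25 within binomial noise (5 sigma per bin)
  pbin <- p$bin_width / 10
  sd_bin <- sqrt(1000 * pbin * (1 - pbin)) / (p$bin_width * 16)
  expect_true(all(abs(p$value - 6.25) < 5 * sd_bin))
  # grid is uniform, symmetric, and has a bin centered on zero
  expect_equal(p$z, -rev(p$z))
  expect_true(any(p$z == 0))
})

test_that("point masses land in exactly two bins", {
  particles <- data.frame(species = "water", mass = 2, electron_count = 1,
                          residue = 1:4, leaflet = "none",
                          carbon_index = NA_integer_, parent = NA_integer_)
  xyz <- cbind(1, 1, 5 + c(1.9, 1.9, -1.9, -1.9))
  ens <- particle_ensemble(list(xyz), c(4, 4, 10), particles)
  p <- compute_density_profile(ens, "water", "mass", 0.2, recenter = FALSE)
  nz <- which(p$value > 0)
  expect_length(nz, 2)
  expect_equal(p$value[nz[1]], p$value[nz[2]])
  expect_equal(sort(p$z[nz]), c(-1.9, 1.9), tolerance = p$bin_width)
})

test_that("solute number density matches the generating Boltzmann density", {
  dw <- double_well(a = 5, b = 1)
  pmf_used <- function(z) dw(pmin(pmax(z, -1.6), 1.6))
  nf <- 25
  spec <- small_spec(n_per_leaflet = 16, hydration = 30, n_solute = 100,
                     n_frames = nf, solute_pmf = pmf_used)
  ens <- build_bilayer_system(spec)
  p <- compute_density_profile(ens, "solute", "number", 0.2)
  n_draws <- 100 * nf
  half <- ground_truth(ens)$Lz / 2
  # oracle: exact bin probabilities by quadrature of the Boltzmann weight
  f <- function(x) exp(-pmf_used(x) / RT_330)
  Z <- integrate(f, -half, half, rel.tol = 1e-10)$value
  edges <- c(p$z - p$bin_width / 2, max(p$z) + p$bin_width / 2)
  pb <- vapply(seq_along(p$z), function(i)
    integrate(f, edges[i], edges[i + 1], rel.tol = 1e-10)$value / Z,
    numeric(1))
  expected <- n_draws * pb / (nf * p$bin_width * p$box_area)
  sd3 <- 3 * sqrt(n_draws * pb * (1 - pb)) / (nf * p$bin_width * p$box_area)
  expect_true(all(abs(p$value - expected) <= sd3 + 1e-9))
})

test_that("symmetrization is a reflection average, idempotent and conserving", {
  set.seed(31)
  g <- sym_grid(8, 0.1)
  vals <- runif(g$n)
  p <- density_profile(g$z, vals, g$h, "number", "solute", 1, 1, 8)
  s <- symmetrize_profile(p)
  expect_equal(s$value, (vals + rev(vals)) / 2)
  expect_equal(symmetrize_profile(s)$value, s$value) # idempotent, exactly
  expect_equal(sum(s$value), sum(vals), tolerance = 1e-12)
  # even input is a fixed point
  even <- density_profile(g$z, 1 + cos(g$z), g$h, "number", "s", 1, 1, 8)
  expect_equal(symmetrize_profile(even)$value, even$value)
  # a spike at +a reflects to half-height spikes at +/- a
  spike <- numeric(g$n); spike[g$n - 3] <- 10
  ps <- symmetrize_profile(density_profile(g$z, spike, g$h, "number", "s",
                                           1, 1, 8))
  expect_equal(ps$value[g$n - 3], 5)
  expect_equal(ps$value[4], 5)
})

test_that("profiles are invariant under a uniform z translation", {
  # keep the bilayer away from the periodic boundary: a generous aqueous
  # slab so the translated membrane never wraps
  ens <- build_bilayer_system(small_spec(hydration = 20))
  p0 <- compute_density_profile(ens, LIPID_SPECIES, "mass", 0.1)
  shifted <- ens
  shifted$frames <- lapply(ens$frames, function(x) {
    x[, 3] <- x[, 3] + 0.3
    x
  })
  shifted <- particle_ensemble(shifted$frames, shifted$box, shifted$particles)
  p1 <- compute_density_profile(shifted, LIPID_SPECIES, "mass", 0.1)
  expect_equal(p1$value, p0$value, tolerance = 1e-9)
})

test_that("bulk density estimation averages the far field", {
  g <- sym_grid(10, 0.1)
  flat <- density_profile(g$z, rep(3.2, g$n), g$h, "number", "s", 1, 1, 10)
  est <- estimate_bulk_density(flat, 2)
  expect_equal(est$rho0, 3.2)
  piece <- density_profile(g$z, ifelse(abs(g$z) > 2, 7, 0), g$h, "number",
                           "s", 1, 1, 10)
  expect_equal(estimate_bulk_density(piece, 2)$rho0, 7)
  expect_error(estimate_bulk_density(flat, 4.95), "no bulk region")
})

test_that("conservation holds for every weighting on a built ensemble", {
  ens <- build_bilayer_system(small_spec())
  for (wt in c("mass", "electron", "number")) {
    p <- compute_density_profile(ens, LIPID_SPECIES, wt, 0.15)
    sel <- ens$particles$species %in% LIPID_SPECIES
    total <- switch(wt, mass = sum(ens$particles$mass[sel]),
                    electron = sum(ens$particles$electron_count[sel]),
                    number = sum(sel))
    expect_equal(sum(p$value) * p$bin_width * p$box_area, total,
                 tolerance = 1e-6)
  }
  expect_error(compute_density_profile(ens, "cholesterol"), "empty selection")
})

test_that("profile CSV round trip preserves the profile", {
  ens <- build_bilayer_system(small_spec())
  p <- compute_density_profile(ens, "water", "mass", 0.1)
  path <- tempfile(fileext = ".csv")
  write_profile_csv(p, path)
  q <- read_profile_csv(path)
  expect_equal(q$value, p$value, tolerance = 1e-12)
  expect_equal(q$z, p$z, tolerance = 1e-12)
  expect_identical(q$weighting, p$weighting)
  expect_equal(q$z_box, p$z_box, tolerance = 1e-12)
})
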