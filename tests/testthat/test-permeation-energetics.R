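test_that("partition coefficient: homogeneous, ramped and Gaussian oracles", {
  # uniform density: P = 1, logP = 0
  p <- profile_from_function(function(z) rep(2, length(z)), 9.9, 0.1)
  res <- partition_coefficient(p, 4.0)
  expect_equal(res$logp, 0, tolerance = 1e-12)
  expect_equal(res$p_memb_bulk, 1, tolerance = 1e-12)
  expect_equal(res$membrane_integral + res$bulk_integral,
               sum(p$value) * p$bin_width, tolerance = 1e-9)

  # trapezoidal enrichment: 2c inside |z| <= 2.2, linear ramp to c by 2.4,
  # c beyond; breakpoints on grid nodes, cut points inside the flat region,
  # so the closed form is exact arithmetic.
  c0 <- 1.3
  ramp <- function(z) {
    az <- abs(z)
    c0 * ifelse(az <= 2.2, 2, ifelse(az <= 2.4, 2 - (az - 2.2) / 0.2, 1))
  }
  pr <- profile_from_function(ramp, 9.9, 0.02) # nodes hit 2.2 and 2.4 exactly
  # closed form for the piecewise-linear shape (constant edge extension):
  zedge <- 9.9 / 2
  total <- 2 * c0 * (2 * 2.2 + 1.5 * 0.2 + (zedge - 2.4))
  dhh <- 4.0
  memb <- 2 * c0 * dhh
  p_closed <- (memb / dhh) / ((total - memb) / (9.9 - dhh))
  res <- partition_coefficient(pr, dhh)
  expect_lt(abs(res$p_memb_bulk - p_closed) / p_closed, 1e-6)

  # Gaussian enrichment vs erf closed form
  A <- 3; sg <- 0.5; zbox <- 8
  gauss <- function(z) c0 * (1 + A * exp(-z^2 / (2 * sg^2)))
  pg <- profile_from_function(gauss, zbox, 0.001)
  dhh <- 3.0
  gint <- function(a, b) { # integral of the Gaussian bump
    A * c0 * sg * sqrt(2 * pi) * (pnorm(b / sg) - pnorm(a / sg))
  }
  memb <- c0 * dhh + gint(-dhh / 2, dhh / 2)
  total <- c0 * zbox + gint(-zbox / 2, zbox / 2)
  p_closed <- (memb / dhh) / ((total - memb) / (zbox - dhh))
  res <- partition_coefficient(pg, dhh)
  expect_lt(abs(res$p_memb_bulk - p_closed) / p_closed, 1e-6)

  # P is invariant under uniform scaling of the profile
  pg2 <- pg; pg2$value <- 17 * pg2$value
  expect_equal(partition_coefficient(pg2, dhh)$p_memb_bulk,
               res$p_memb_bulk, tolerance = 1e-12)

  # no solute in bulk is an error, not infinity
  inner <- profile_from_function(function(z) ifelse(abs(z) < 1, 1, 0), 8, 0.1)
  expect_error(partition_coefficient(inner, 4), "no solute in bulk")
})

test_that("logP contrasts are magnitude reductions, sign-blind", {
  expect_equal(logp_contrast(-0.3, -0.3), 0)
  expect_error(logp_contrast(0.5, 0), "nonzero")
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, -2, 2); b <- runif(1, 0.1, 2) * sample(c(-1, 1), 1)
    expect_equal(logp_contrast(a, b), logp_contrast(-a, -b))
  }
})

test_that("inverse Boltzmann inversion and its exact round trip", {
  g <- sym_grid(8, 0.1)
  rho0 <- 5
  # rho = rho0 everywhere -> PMF identically zero
  flat <- density_profile(g$z, rep(rho0, g$n), g$h, "number", "s", 1, 1, 8)
  pmf <- pmf_from_density(flat, rho0, 330)
  expect_true(all(abs(pmf$value) < 1e-12))
  expect_identical(pmf$reference, "bulk-zero")
  # a doubled bin at 330 K sits at -RT ln 2 = -1.902 kJ/mol
  vals <- rep(rho0, g$n); vals[g$n %/% 2] <- 2 * rho0
  one <- density_profile(g$z, vals, g$h, "number", "s", 1, 1, 8)
  pmf1 <- pmf_from_density(one, rho0, 330, z_bulk = NA)
  expect_equal(pmf1$value[g$n %/% 2], -RT_330 * log(2), tolerance = 1e-9)
  expect_equal(pmf1$value[g$n %/% 2], -1.902, tolerance = 1e-3)
  # zero bins are masked, never clamped
  vals2 <- rep(rho0, g$n); vals2[5] <- 0
  pmf2 <- pmf_from_density(density_profile(g$z, vals2, g$h, "number", "s",
                                           1, 1, 8), rho0, 330)
  expect_false(pmf2$valid[5])
  expect_true(is.na(pmf2$value[5]))
  # bulk-region mean is zero after referencing
  set.seed(42)
  noisy <- density_profile(g$z, rho0 * exp(runif(g$n, -0.5, 0.5)), g$h,
                           "number", "s", 1, 1, 8)
  pmf3 <- pmf_from_density(noisy, rho0, 330, z_bulk = 2.5)
  expect_lt(abs(mean(pmf3$value[abs(g$z) > 2.5])), 1e-9)
  # round trip: exp(-PMF/RT) * rho0 reproduces the density to 1e-12
  back <- density_from_pmf(pmf3, rho0)
  expect_equal(back, noisy$value, tolerance = 1e-12)
})

test_that("PMF symmetrization averages sides and propagates masks", {
  g <- sym_grid(6, 0.1)
  set.seed(43)
  v <- runif(g$n, -2, 5)
  pmf <- pmf_profile(g$z, v, temperature = 330)
  s <- symmetrize_pmf(pmf)
  expect_equal(s$value, (v + rev(v)) / 2)
  expect_equal(symmetrize_pmf(s)$value, s$value) # idempotent
  # even input unchanged
  even <- pmf_profile(g$z, g$z^2, temperature = 330)
  expect_equal(symmetrize_pmf(even)$value, even$value)
  # one-sided propagation: value +a valid at +z0 only
  v2 <- rep(NA_real_, g$n); v2[abs(g$z) > 2] <- 0
  v2[g$n - 5] <- 4.2; v2[6] <- NA
  pm <- pmf_profile(g$z, v2, valid = !is.na(v2), temperature = 330)
  sm <- symmetrize_pmf(pm)
  expect_equal(sm$value[g$n - 5], 4.2)
  expect_equal(sm$value[6], 4.2)
  expect_true(sm$one_sided[6] && sm$one_sided[g$n - 5])
})

test_that("density-level and PMF-level symmetrization agree on even data", {
  # the two operations do not commute in general (log of a mean differs from
  # a mean of logs); on even profiles both routes are the identity
  g <- sym_grid(8, 0.1)
  rho0 <- 2
  even_vals <- rho0 * exp(-cos(g$z))
  prof <- density_profile(g$z, even_vals, g$h, "number", "s", 1, 1, 8)
  route1 <- pmf_from_density(symmetrize_profile(prof), rho0, 330, z_bulk = NA)
  route2 <- symmetrize_pmf(pmf_from_density(prof, rho0, 330, z_bulk = NA))
  expect_equal(route1$value, route2$value, tolerance = 1e-9)
})

test_that("replica combination yields per-bin mean, sd and mask intersection", {
  g <- sym_grid(6, 0.1)
  base <- pmf_profile(g$z, g$z^2, temperature = 330)
  expect_equal(combine_replicas(list(base, base))$sd,
               rep(0, g$n))
  # two replicas differing by +delta at one bin
  delta <- 0.8
  v2 <- g$z^2; v2[10] <- v2[10] + delta
  comb <- combine_replicas(list(base, pmf_profile(g$z, v2, temperature = 330)))
  expect_equal(comb$value[10], g$z[10]^2 + delta / 2)
  expect_equal(comb$sd[10], delta / sqrt(2), tolerance = 1e-12)
  # mask intersection
  v3 <- g$z^2; v3[4] <- NA
  comb2 <- combine_replicas(list(base,
                                 pmf_profile(g$z, v3, valid = !is.na(v3),
                                             temperature = 330)))
  expect_false(comb2$valid[4])
  # grid mismatch rejected
  g2 <- sym_grid(6, 0.2)
  expect_error(combine_replicas(list(base, pmf_profile(g2$z, g2$z^2,
                                                       temperature = 330))),
               "grids")
})

test_that("replica scatter is consistent with multinomial propagation", {
  dw <- double_well(a = 5, b = 1)
  n <- 1e5
  draws <- lapply(1:2, function(s) {
    z <- sample_solute_positions(dw, c(-1.5, 1.5), n, 330, seed = 50 + s)
    profile_from_positions(z, 3.2, 0.05)
  })
  f <- function(x) exp(-dw(x) / RT_330)
  Z <- integrate(f, -1.6, 1.6, rel.tol = 1e-10)$value
  rho0 <- n / Z # 3-D density scale at U = 0 (unit lateral area)
  pmfs <- lapply(draws, pmf_from_density, rho0 = rho0, temperature = 330,
                 z_bulk = NA)
  comb <- combine_replicas(pmfs)
  counts <- draws[[1]]$value * draws[[1]]$bin_width # per-bin counts
  sel <- comb$valid & counts > 200
  predicted <- RT_330 / sqrt(counts[sel])
  ratio <- median(comb$sd[sel] / predicted)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("feature extraction reads the constructed W-profile exactly", {
  g <- sym_grid(6.58, 0.02) # includes 0 and +/-1.2 as grid nodes
  pmf <- pmf_profile(g$z, w_profile(g$z), temperature = 330,
                     reference = "bulk-zero")
  ft <- extract_features(pmf, dhh = 4.0, smoothing_window = 1)
  expect_equal(ft$central_barrier_vs_bulk, 2, tolerance = 1e-9)
  expect_equal(ft$central_barrier_vs_adjacent_min, 7, tolerance = 1e-9)
  expect_equal(ft$central_barrier_position, 0, tolerance = 1e-9)
  wells <- ft$minima[order(ft$minima$depth), ][1:2, ]
  expect_equal(sort(wells$position), c(-1.2, 1.2), tolerance = 1e-9)
  expect_equal(wells$depth, c(-5, -5), tolerance = 1e-9)
  # width at half height above the flanking minima: level -1.5 is crossed at
  # +/-0.6 for the cosine well, so the width is 1.2 nm
  expect_equal(ft$central_barrier_width, 1.2, tolerance = 1e-3)
  # flat zero profile: all features absent, not zero
  flat <- pmf_profile(g$z, rep(0, g$n), temperature = 330)
  ft0 <- extract_features(flat, dhh = 4.0)
  expect_true(is.na(ft0$central_barrier_vs_bulk))
  expect_true(is.na(ft0$outer_barrier))
  expect_identical(nrow(ft0$minima), 0L)
})

test_that("region assignment follows the crossover and headgroup edges", {
  g <- sym_grid(10, 0.02)
  # water rises through the lipid density exactly at |z| = 2.1
  lipid <- profile_from_function(function(z) 2 / (1 + exp((abs(z) - 2.1) / 0.1)),
                                 10, 0.02, species = "lipid")
  water <- profile_from_function(function(z) 2 - 2 / (1 + exp((abs(z) - 2.1) / 0.1)),
                                 10, 0.02, species = "water")
  head <- profile_from_function(function(z) exp(-(abs(z) - 1.9)^2 / (2 * 0.2^2)),
                                10, 0.02, species = "head")
  rg <- assign_regions(lipid, water, head, dhh = 3.8)
  expect_identical(rg$region, c("IV", "III", "II", "I"))
  expect_equal(rg$outer[rg$region == "II"], 2.1, tolerance = 0.02)
  expect_equal(rg$outer[rg$region == "IV"], 0.95, tolerance = 1e-9)
  # II/III at the inner 10% edge of the headgroup peak
  inner_edge <- 1.9 - sqrt(2 * log(10)) * 0.2
  expect_equal(rg$inner[rg$region == "II"], inner_edge, tolerance = 0.03)
  expect_equal(rg$outer[rg$region == "I"] - rg$inner[rg$region == "I"], 0.5)
  # boundaries are contiguous and ordered
  expect_true(all(diff(rg$inner) > 0) && all(rg$outer > rg$inner))
  # water-only system: no crossover
  expect_error(assign_regions(water, water, head, 3.8), "not resolved")
})

test_that("regions on a synthetic bilayer contain the headgroup peak", {
  ens <- build_bilayer_system(small_spec(n_per_leaflet = 32, hydration = 25,
                                         n_solute = 0, n_frames = 4))
  lipid <- compute_density_profile(ens, LIPID_SPECIES, "mass", 0.1)
  water <- compute_density_profile(ens, "water", "mass", 0.1)
  head <- compute_density_profile(ens, "lipid-head", "mass", 0.1)
  dhh <- ground_truth(ens)$dhh_target
  rg <- assign_regions(lipid, water, head, dhh)
  pk <- abs(head$z[which.max(symmetrize_profile(head)$value)])
  ii <- rg[rg$region == "II", ]
  expect_true(pk >= ii$inner && pk < ii$outer)
})
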