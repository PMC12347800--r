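# Shared fixtures: analytic potentials/profiles and small ensemble builders.

RT_330 <- memperm:::GAS_CONSTANT_KJ * 330

# Quartic double-well potential with barrier a * b^4 (kJ/mol).
double_well <- function(a = 10, b = 1) function(z) a * (z^2 - b^2)^2

# W-shaped permeation profile: central barrier +2 kJ/mol at z = 0, minima
# -5 kJ/mol at z = +/-1.2 nm, smoothly back to 0 by |z| = 2.4, flat beyond.
# Piecewise cosine, so extrema values/positions are exact.
w_profile <- function(z) {
  az <- abs(z)
  ifelse(az <= 1.2, -5 + 3.5 * (1 + cos(pi * z / 1.2)),
         ifelse(az <= 2.4, -5 + 2.5 * (1 - cos(pi * (az - 1.2) / 1.2)), 0))
}

# Uniform symmetric grid of odd length covering [-zbox/2, zbox/2].
sym_grid <- function(zbox, h) {
  n <- floor(zbox / h)
  if (n %% 2 == 0) n <- n - 1
  he <- zbox / n
  list(z = (seq_len(n) - (n + 1) / 2) * he, h = he, n = n)
}

# density_profile directly from values of a function on a symmetric grid.
profile_from_function <- function(f, zbox, h, weighting = "number",
                                  species = "solute", box_area = 1) {
  g <- sym_grid(zbox, h)
  density_profile(g$z, f(g$z), g$h, weighting, species, 1, box_area, zbox)
}

# Number-density profile from 1-D positions (for generator round trips):
# wraps them into a solute-only ensemble so the binning machinery is the
# code under test.
profile_from_positions <- function(z, zbox, bin_width, box_lateral = 1) {
  n <- length(z)
  particles <- data.frame(species = "solute", mass = 1, electron_count = 1,
                          residue = seq_len(n), leaflet = "none",
                          carbon_index = NA_integer_, parent = NA_integer_)
  ens <- particle_ensemble(list(cbind(0.5, 0.5, z + zbox / 2)),
                           c(box_lateral, box_lateral, zbox), particles)
  compute_density_profile(ens, "solute", "number", bin_width, recenter = FALSE)
}

# Normalized Boltzmann density of a potential by quadrature (oracle).
boltzmann_density <- function(pmf, z, temperature = 330) {
  f <- function(x) exp(-pmf(x) / (memperm:::GAS_CONSTANT_KJ * temperature))
  Z <- stats::integrate(f, min(z), max(z), rel.tol = 1e-10)$value
  f(z) / Z
}

# Minimal ensemble with one carbon per supplied C-H unit vector (for order
# parameter oracles).
ch_ensemble <- function(vectors, box = c(3, 3, 3)) {
  n <- nrow(vectors)
  particles <- data.frame(
    species = rep(c("lipid-tail-carbon", "tail-hydrogen"), n),
    mass = rep(c(12.011, 1.008), n),
    electron_count = rep(c(6, 1), n),
    residue = rep(seq_len(n), each = 2),
    leaflet = "upper",
    carbon_index = 1L,
    parent = as.integer(rbind(NA, seq(1, 2 * n, by = 2))),
    stringsAsFactors = FALSE)
  cpos <- cbind(1.5, 1.5, 1.5)[rep(1, n), , drop = FALSE]
  xyz <- matrix(0, 2 * n, 3)
  xyz[seq(1, 2 * n, 2), ] <- cpos
  xyz[seq(2, 2 * n, 2), ] <- cpos + 0.109 * vectors
  particle_ensemble(list(xyz), box, particles)
}

# Small, fast bilayer spec for plumbing tests.
small_spec <- function(...) {
  args <- list(n_per_leaflet = 8, hydration = 8, n_solute = 10,
               n_frames = 2, tail_carbons = 4, seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(bilayer_spec, args)
}
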