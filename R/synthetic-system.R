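#' Specification of a synthetic hydrated bilayer system
#'
#' Describes an idealized, single-lipid-species hydrated bilayer with a known
#' ground truth, used to validate the density, structure and energetics
#' estimators. Defaults correspond to the reference study conditions: 128
#' lipids per leaflet, 50 waters per lipid, 150 mM NaCl, 100 solute
#' molecules, palmitoyl-length (16-carbon) tails, and DPPC-like geometry at
#' 330 K.
#'
#' Lipids are coarse idealized stand-ins - one headgroup bead plus a chain of
#' tail carbons each carrying two explicit hydrogens - not force-field
#' molecules; they are sufficient because only the structural estimators and
#' the density/energetics machinery are under test.
#'
#' @param n_per_leaflet lipids per leaflet (>= 1).
#' @param hydration water molecules per lipid (>= 0).
#' @param apl_target area per lipid, nm^2 (> 0); sets the lateral box size.
#' @param dhh_target headgroup peak-to-peak thickness, nm (> 0).
#' @param headgroup_sigma Gaussian z-scatter of headgroup beads, nm.
#' @param scd_target deuterium order parameter target, in `[-0.5, 1.0]`.
#' @param tail_carbons carbons per acyl chain.
#' @param salt_conc salt concentration in the aqueous slabs, mol/L.
#' @param n_solute number of solute molecules.
#' @param solute_pmf `"none"` for a uniform solute distribution, or a
#'   vectorized function of z (nm, bilayer midplane at 0) returning kJ/mol;
#'   solute z positions are then Boltzmann-distributed accordingly.
#' @param temperature K (> 0).
#' @param n_frames number of independent frames to draw.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   ensembles.
#' @param headgroup_charge formal charge per headgroup (neutralizing sodium
#'   counterions are added when negative).
#' @return an object of class `bilayer_spec`.
#' @examples
#' spec <- bilayer_spec(n_per_leaflet = 8, hydration = 6, n_solute = 5,
#'                      n_frames = 2)
#' @export
bilayer_spec <- function(n_per_leaflet = 128,
                         hydration = 50,
                         apl_target = 0.618,
                         dhh_target = 3.732,
                         headgroup_sigma = 0.15,
                         scd_target = -0.2,
                         tail_carbons = 16,
                         salt_conc = 0.150,
                         n_solute = 100,
                         solute_pmf = "none",
                         temperature = 330,
                         n_frames = 10,
                         seed = 1L,
                         headgroup_charge = 0) {
  spec <- list(n_per_leaflet = as.integer(n_per_leaflet),
               hydration = hydration, apl_target = apl_target,
               dhh_target = dhh_target, headgroup_sigma = headgroup_sigma,
               scd_target = scd_target, tail_carbons = as.integer(tail_carbons),
               salt_conc = salt_conc, n_solute = as.integer(n_solute),
               solute_pmf = solute_pmf, temperature = temperature,
               n_frames = as.integer(n_frames), seed = as.integer(seed),
               headgroup_charge = headgroup_charge)
  validate_bilayer_spec(spec)
  structure(spec, class = "bilayer_spec")
}

validate_bilayer_spec <- function(spec) {
  with(spec, {
    if (n_per_leaflet < 1) stop("n_per_leaflet must be >= 1")
    if (hydration < 0) stop("hydration must be >= 0")
    if (apl_target <= 0) stop("apl_target must be > 0")
    if (dhh_target <= 0) stop("dhh_target must be > 0")
    if (headgroup_sigma <= 0) stop("headgroup_sigma must be > 0")
    if (scd_target < -0.5 || scd_target > 1.0)
      stop("scd_target must lie in [-0.5, 1.0]")
    if (tail_carbons < 1) stop("tail_carbons must be >= 1")
    if (salt_conc < 0) stop("salt_conc must be >= 0")
    if (n_solute < 0) stop("n_solute must be >= 0")
    if (temperature <= 0) stop("temperature must be > 0")
    if (n_frames < 1) stop("n_frames must be >= 1")
    if (!identical(solute_pmf, "none") && !is.function(solute_pmf))
      stop("solute_pmf must be \"none\" or a function of z")
  })
  invisible(spec)
}

# Bead properties of the idealized particles (amu, electrons).
BEAD_PROPS <- list(
  head     = list(mass = 163.2, electrons = 96),
  carbon   = list(mass = 12.011, electrons = 6),
  hydrogen = list(mass = 1.008, electrons = 1),
  water    = list(mass = 18.015, electrons = 10),
  sodium   = list(mass = 22.990, electrons = 10),
  chloride = list(mass = 35.453, electrons = 18),
  solute   = list(mass = 94.11, electrons = 50)
)

# C-H bond length (nm) and z-jitter (nm) applied to tail carbon rows so the
# chain does not produce delta-like density spikes.
CH_BOND_LENGTH <- 0.109
TAIL_Z_JITTER <- 0.10
LATERAL_JITTER <- 0.05

#' Build a synthetic hydrated bilayer + solute ensemble
#'
#' Places lipids on a per-leaflet square lattice in a box of lateral area
#' `n_per_leaflet * apl_target`, with headgroup beads Gaussian-scattered about
#' `+/- dhh_target/2`, tail carbons descending toward the midplane, and C-H
#' vectors drawn so the per-carbon order-parameter estimator has expectation
#' `scd_target`. Waters fill the two aqueous slabs uniformly; Na+/Cl- ion
#' counts follow the slab volume and `salt_conc`, plus counterions for any
#' declared headgroup charge; solute z positions are drawn from the Boltzmann
#' density of `solute_pmf` (uniform if `"none"`). Frames are independent
#' draws under the spec seed. The bilayer midplane sits at `Lz/2` in stored
#' (wrapped) coordinates; after the recentering performed by the density
#' machinery it is at z = 0.
#'
#' @param spec a [bilayer_spec()].
#' @return a [particle_ensemble()] with attributes `ground_truth` (the spec
#'   plus derived box dimensions and exact particle counts) available via
#'   [ground_truth()].
#' @examples
#' ens <- build_bilayer_system(bilayer_spec(n_per_leaflet = 4, hydration = 6,
#'                                          n_solute = 0, n_frames = 1))
#' species_counts(ens)
#' @export
build_bilayer_system <- function(spec) {
  validate_bilayer_spec(spec)
  n_lip_leaf <- spec$n_per_leaflet
  n_lipid <- 2L * n_lip_leaf
  n_water <- as.integer(round(spec$hydration * n_lipid))
  L <- sqrt(n_lip_leaf * spec$apl_target)
  area <- L * L

  # membrane extent and aqueous slab geometry (z measured from the midplane)
  z_mem <- spec$dhh_target / 2 + 3 * spec$headgroup_sigma
  water_thickness <- n_water * WATER_VOLUME_NM3 / area
  if (n_water > 0 && water_thickness / 2 < 2 * spec$headgroup_sigma)
    stop("no bulk region: aqueous slab thinner than 2 x headgroup_sigma")
  Lz <- 2 * z_mem + water_thickness
  half <- Lz / 2

  slab_volume <- water_thickness * area # nm^3, both slabs together
  n_ion_salt <- as.integer(round(spec$salt_conc * slab_volume * 1e-24 * AVOGADRO))
  n_counter <- as.integer(round(abs(spec$headgroup_charge) * n_lipid))
  n_na <- n_ion_salt + if (spec$headgroup_charge < 0) n_counter else 0L
  n_cl <- n_ion_salt + if (spec$headgroup_charge > 0) n_counter else 0L

  nc <- spec$tail_carbons
  atoms_per_lipid <- 1L + 3L * nc # head + carbons + 2 H per carbon

  particles <- build_particle_table(n_lip_leaf, nc, n_water, n_na, n_cl,
                                    spec$n_solute)
  n_part <- nrow(particles)

  # lattice sites per leaflet (fixed across frames)
  m <- ceiling(sqrt(n_lip_leaf))
  site <- (expand.grid(ix = seq_len(m), iy = seq_len(m)) - 0.5) / m * L
  site <- site[seq_len(n_lip_leaf), , drop = FALSE]

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  frames <- lapply(seq_len(spec$n_frames), function(f) {
    draw_frame(spec, particles, site, L, Lz, half, z_mem, water_thickness,
               n_lip_leaf, nc, n_water, n_na + n_cl)
  })

  box <- matrix(rep(c(L, L, Lz), each = spec$n_frames), ncol = 3)
  ens <- particle_ensemble(frames, box, particles)
  attr(ens, "ground_truth") <- c(unclass(spec),
    list(Lx = L, Ly = L, Lz = Lz, box_area = area,
         counts = c(lipid = n_lipid, water = n_water, sodium = n_na,
                    chloride = n_cl, solute = spec$n_solute),
         aqueous_concentration =
           if (n_water > 0) solute_concentration(spec$n_solute, n_water) else NA_real_))
  ens
}

#' Ground-truth parameters of a synthetic ensemble
#' @param ensemble an ensemble produced by [build_bilayer_system()].
#' @return list of generating parameters, derived box dimensions and counts.
#' @export
ground_truth <- function(ensemble) {
  gt <- attr(ensemble, "ground_truth")
  if (is.null(gt)) stop("ensemble carries no ground-truth attribute")
  gt
}

build_particle_table <- function(n_lip_leaf, nc, n_water, n_na, n_cl, n_solute) {
  lip_species <- c("lipid-head", rep(c("lipid-tail-carbon", "tail-hydrogen",
                                       "tail-hydrogen"), nc))
  lip_mass <- c(BEAD_PROPS$head$mass,
                rep(c(BEAD_PROPS$carbon$mass, BEAD_PROPS$hydrogen$mass,
                      BEAD_PROPS$hydrogen$mass), nc))
  lip_elec <- c(BEAD_PROPS$head$electrons,
                rep(c(BEAD_PROPS$carbon$electrons, BEAD_PROPS$hydrogen$electrons,
                      BEAD_PROPS$hydrogen$electrons), nc))
  lip_cidx <- c(NA_integer_, rep(seq_len(nc), each = 3))
  # parent (within-lipid offset): hydrogens point at the preceding carbon
  lip_parent <- rep(NA_integer_, length(lip_species))
  carbon_rows <- 1L + 3L * (seq_len(nc) - 1L) + 1L
  lip_parent[carbon_rows + 1L] <- carbon_rows
  lip_parent[carbon_rows + 2L] <- carbon_rows

  apl_atoms <- length(lip_species)
  n_lipid <- 2L * n_lip_leaf
  species <- c(rep(lip_species, n_lipid),
               rep("water", n_water), rep("ion", n_na + n_cl),
               rep("solute", n_solute))
  mass <- c(rep(lip_mass, n_lipid), rep(BEAD_PROPS$water$mass, n_water),
            rep(BEAD_PROPS$sodium$mass, n_na), rep(BEAD_PROPS$chloride$mass, n_cl),
            rep(BEAD_PROPS$solute$mass, n_solute))
  elec <- c(rep(lip_elec, n_lipid), rep(BEAD_PROPS$water$electrons, n_water),
            rep(BEAD_PROPS$sodium$electrons, n_na),
            rep(BEAD_PROPS$chloride$electrons, n_cl),
            rep(BEAD_PROPS$solute$electrons, n_solute))
  carbon_index <- c(rep(lip_cidx, n_lipid),
                    rep(NA_integer_, n_water + n_na + n_cl + n_solute))
  parent <- c(unlist(lapply(seq_len(n_lipid) - 1L,
                            function(k) lip_parent + k * apl_atoms)),
              rep(NA_integer_, n_water + n_na + n_cl + n_solute))
  leaflet <- c(rep(c("upper", "lower"), each = n_lip_leaf * apl_atoms),
               rep("none", n_water + n_na + n_cl + n_solute))
  n_mol <- c(rep(seq_len(n_lipid), each = apl_atoms),
             n_lipid + seq_len(n_water + n_na + n_cl + n_solute))
  data.frame(species = species, mass = mass, electron_count = elec,
             residue = n_mol, leaflet = leaflet, carbon_index = carbon_index,
             parent = parent, stringsAsFactors = FALSE)
}

# Draw one frame; z is generated about the midplane (0) and shifted to Lz/2
# on output. Consumes the active RNG stream.
draw_frame <- function(spec, particles, site, L, Lz, half, z_mem,
                       water_thickness, n_lip_leaf, nc, n_water, n_ion) {
  n_part <- nrow(particles)
  xyz <- matrix(0, n_part, 3)
  row <- 0L
  for (s in c(+1, -1)) {
    for (i in seq_len(n_lip_leaf)) {
      x0 <- site$ix[i] + stats::rnorm(1, 0, LATERAL_JITTER)
      y0 <- site$iy[i] + stats::rnorm(1, 0, LATERAL_JITTER)
      zj <- stats::rnorm(1, 0, TAIL_Z_JITTER)
      # headgroup bead
      row <- row + 1L
      xyz[row, ] <- c(x0, y0, s * spec$dhh_target / 2 +
                        stats::rnorm(1, 0, spec$headgroup_sigma))
      # tail: carbons descend toward the midplane, each with two hydrogens
      ch <- generate_orientation_sample(spec$scd_target, 2L * nc,
                                        seed = NULL)
      for (ci in seq_len(nc)) {
        zc <- s * (spec$dhh_target / 2) * (nc + 1 - ci) / (nc + 1) + zj
        row <- row + 1L
        xyz[row, ] <- c(x0, y0, zc)
        for (h in 1:2) {
          v <- ch[2L * (ci - 1L) + h, ]
          row <- row + 1L
          xyz[row, ] <- c(x0 + CH_BOND_LENGTH * v[1],
                          y0 + CH_BOND_LENGTH * v[2],
                          zc + CH_BOND_LENGTH * v[3])
        }
      }
    }
  }
  n_bulk <- n_water + n_ion
  if (n_bulk > 0) {
    side <- sample(c(-1, 1), n_bulk, replace = TRUE)
    zb <- side * stats::runif(n_bulk, z_mem, z_mem + water_thickness / 2)
    xyz[row + seq_len(n_bulk), ] <- cbind(stats::runif(n_bulk, 0, L),
                                          stats::runif(n_bulk, 0, L), zb)
    row <- row + n_bulk
  }
  if (spec$n_solute > 0) {
    if (identical(spec$solute_pmf, "none")) {
      zs <- stats::runif(spec$n_solute, -half, half)
    } else {
      zs <- sample_solute_positions(spec$solute_pmf, c(-half, half),
                                    spec$n_solute, spec$temperature,
                                    seed = NULL)
    }
    xyz[row + seq_len(spec$n_solute), ] <-
      cbind(stats::runif(spec$n_solute, 0, L),
            stats::runif(spec$n_solute, 0, L), zs)
  }
  xyz[, 3] <- xyz[, 3] + half
  xyz
}

#' Sample solute z positions from a potential of mean force
#'
#' Draws i.i.d. positions from the Boltzmann density
#' `p(z) ~ exp(-PMF(z)/RT)` on `z_range`, by inverse-CDF interpolation on a
#' fine grid (step <= 0.005 nm). Deterministic under a fixed seed.
#'
#' @param pmf vectorized function of z (nm) returning kJ/mol; must be finite
#'   on `z_range`.
#' @param z_range length-2 numeric interval (nm).
#' @param n number of draws (>= 1).
#' @param temperature K.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return numeric vector of n z values (nm).
#' @examples
#' z <- sample_solute_positions(function(z) 0 * z, c(-1, 1), 100, 330, seed = 7)
#' @export
sample_solute_positions <- function(pmf, z_range, n, temperature, seed = NULL) {
  stopifnot(is.function(pmf), length(z_range) == 2, n >= 1, temperature > 0)
  z_range <- sort(as.numeric(z_range))
  if (!is.null(seed)) set.seed(seed)
  m <- max(2L, ceiling(diff(z_range) / 0.005)) + 1L
  zg <- seq(z_range[1], z_range[2], length.out = m)
  u <- pmf(zg)
  if (!all(is.finite(u)))
    stop("pmf is non-finite on the requested range")
  w <- exp(-(u - min(u)) / (GAS_CONSTANT_KJ * temperature))
  # cumulative trapezoid -> CDF
  cdf <- c(0, cumsum((w[-1] + w[-m]) / 2 * diff(zg)))
  if (cdf[m] <= 0) stop("Boltzmann weight integrates to zero on the range")
  cdf <- cdf / cdf[m]
  # enforce strict monotonicity for interpolation in flat-weight stretches
  cdf <- cdf + seq(0, 1e-12, length.out = m)
  cdf <- cdf / cdf[m]
  stats::approx(cdf, zg, xout = stats::runif(n), rule = 2)$y
}

#' Draw unit C-H vectors with a prescribed order parameter
#'
#' Generates `n` unit vectors from an axially symmetric mixture whose
#' deuterium-order-parameter expectation `(1/2)<3 cos^2 Theta - 1>` equals
#' `scd_target` (Theta measured from the z axis). The mixture combines an
#' isotropic component with in-plane vectors (for negative targets) or
#' axis-parallel vectors (for positive targets); the mixture weight follows
#' from the analytic moment: `E = -w/2` for the perpendicular mixture and
#' `E = w` for the parallel one.
#'
#' @param scd_target target order parameter in `[-0.5, 1.0]`.
#' @param n number of vectors.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return n x 3 matrix of unit vectors.
#' @examples
#' v <- generate_orientation_sample(-0.5, 10, seed = 1)
#' all(abs(v[, 3]) < 1e-12)
#' @export
generate_orientation_sample <- function(scd_target, n, seed = NULL) {
  if (scd_target < -0.5 || scd_target > 1.0)
    stop("scd_target must lie in [-0.5, 1.0]")
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (scd_target >= 0) {
    w <- scd_target                      # parallel fraction
    comp <- stats::runif(n) < w
    u <- ifelse(comp, sample(c(-1, 1), n, replace = TRUE),
                stats::runif(n, -1, 1))
  } else {
    w <- -2 * scd_target                 # perpendicular fraction
    comp <- stats::runif(n) < w
    u <- ifelse(comp, 0, stats::runif(n, -1, 1))
  }
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - u^2))
  cbind(r * cos(phi), r * sin(phi), u)
}
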