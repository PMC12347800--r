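---
title: "Membrane permeation analysis: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane permeation analysis: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memperm)
```

This vignette documents the science implemented in `memperm`: the models
behind each estimator, the parameters that matter and their defaults, the
synthetic data the package validates itself against, and the numerical and
design choices made where more than one convention exists. Units are fixed
package-wide: lengths in nm, energies in kJ/mol, masses in amu,
temperatures in K, times in ps (so 1 amu nm² ps⁻² = 1 kJ/mol).

## 1. The problem

Small amphiphilic or polar solutes (industrial heterocycles such as
N-methyl-2-pyrrolidone, 1,4-dioxane, oxane or phenol are typical cases)
cross phospholipid bilayers passively. Two complementary observables
quantify this: the membrane/bulk partition coefficient, which integrates
the solute density profile inside and outside the membrane slab, and the
potential of mean force (PMF) along the membrane normal, whose central and
interfacial barriers set the kinetics of crossing. Both derive from
particle ensembles: frames of coordinates with per-particle species
metadata in an orthorhombic box. The package computes these observables,
the standard bilayer structural parameters that contextualize them, and
includes a desk-scale reimplementation of the adaptive-bias sampler used
to obtain PMFs in production simulations.

## 2. Density profiles

`compute_density_profile()` bins particle weight (mass, electron count, or
unity) along z. Conventions:

- **Recentering.** Each frame is shifted so the mass-weighted center of
  all lipid-tagged particles sits at z = 0, removing box drift. This
  matches the reaction-coordinate convention of measuring solute positions
  relative to the bilayer center of mass. The only unwrapping performed is
  this z-shift; the bilayer is assumed not to straddle the periodic
  boundary.
- **Grid.** The bin count is `floor(Lz / bin_width)` forced odd, and the
  effective width `Lz / n_bins` spans the box exactly. One bin is
  therefore centered on z = 0 and the mirror image of the grid is itself,
  so symmetrization needs no interpolation, and
  `sum(value) * bin_width * area` equals the total selected weight per
  frame to ~1e-9 relative (a tested invariant).
- **Default bin width 0.02 nm**, configurable. For headgroup-peak
  localization (thickness), a broader 0.1 nm default is used instead; see
  below.
- Electron weights come from explicit per-particle electron counts;
  coordinate files without them fall back to an element table.

`symmetrize_profile()` averages a profile with its mirror image. The
canonical symmetrization in this package happens at the PMF level (that is
what replica averaging operates on); the density-level variant exists for
profile figures. The two do **not** commute in general — the log of a mean
is not the mean of logs — and both are exposed deliberately; they agree
exactly on even profiles, which is what the tests pin down.

`estimate_bulk_density()` averages bins beyond `|z| = z_bulk`, where the
caller supplies `z_bulk = D_HH/2 + bulk_margin` (default margin 0.5 nm).
Fewer than 3 contributing bins is an error ("no bulk region"), never a
silent extrapolation.

## 3. Structural parameters

- **APL** — per frame, `2 Lx Ly / n_lipid`; exact given the box, so its
  uncertainty reflects only box fluctuations.
- **D_HH** — distance between the highest local maximum of the electron
  density profile on each side of the midplane, each refined by a
  quadratic fit through the peak bin and its two neighbours. Ties between
  equal-height maxima are broken toward larger |z| (headgroups are the
  outermost peaks). Fewer than one maximum per side raises "no headgroup
  peaks". The 0.1 nm default bin width trades sub-bin resolution (restored
  by the quadratic fit) for robustness of peak identification against shot
  noise.
- **VPL** — `D_HH × APL / 2`, with errors propagated in quadrature.
- **S_CD** — `½⟨3 cos²Θ − 1⟩` per chain carbon over all C–H bonds, lipids
  and frames; leaflet-agnostic because cos² is sign-free. Carbons without
  bonded hydrogens are skipped with a warning. Explicit hydrogens are
  assumed (the synthetic lipids carry them; united-atom reconstruction is
  out of scope).
- **Uncertainties** are block averages: frames are split into 5 equal
  contiguous blocks (fewer if there are fewer frames) and the standard
  error of the block means is reported. Five blocks is the customary
  compromise between bias (too few) and correlation (too many) for
  trajectory data.

## 4. Partition coefficient and PMF

`partition_coefficient()` evaluates the mean solute density inside the
membrane slab `|z| ≤ D_HH/2` against the mean density in the remaining
volume. Integration is composite trapezoid over the piecewise-linear
interpolant with explicit cut points inserted at ±D_HH/2, and the total
integral uses the conservation convention `sum(value) × bin_width`
(equivalent to constant extension over the outer half-bins). This makes
the result bin-width-robust: uniform profiles give exactly P = 1, and
analytic profiles match their closed forms to better than 1e-6 relative
(tested). A zero bulk integral is an error — P is undefined there, not
infinite. `logp_contrast()` reports `100 (|logP_b| − |logP_a|)/|logP_b|`,
the percent reduction in partitioning magnitude between two systems.

`pmf_from_density()` applies `PMF(z) = −RT ln(ρ(z)/ρ₀)`. Bins with zero
counts are masked invalid and stay masked through symmetrization and
replica combination; pseudo-counts are never added because they bias
barrier heights and no smoothing rule is prescribed for the inversion. The
profile is then referenced so the declared bulk region averages zero; the
subtracted offset is stored so the inversion round-trips to the input
density at 1e-12 relative (a tested invariant). Default temperature 330 K
(PC/PG-like systems), with 345 K the conventional choice for PE/PA-like
systems.

`extract_features()` works on a moving-average-smoothed copy (centered
window, default 5 bins; window 1 disables smoothing, and unsmoothed
features are always attached). Local extrema come from sign changes of the
discrete derivative, with zero slopes inheriting the previous sign so
plateaus yield one extremum. The central barrier (highest maximum in
`|z| < D_HH/4`) is reported both vs bulk and vs the mean of its flanking
minima, because single-number barrier heights in the literature rarely
state their reference; the full width at half height above the flanking
minima uses linear interpolation. The outer barrier is the highest maximum
in the headgroup band `D_HH/4 < |z| < D_HH/2 + 0.5`. Absent features are
`NA`, never zero.

`assign_regions()` implements the four-region decomposition (perturbed
interfacial water I, headgroups II, dense acyl chains III, bilayer center
IV): II/I at the outermost water–lipid density crossover (a zero-density
gap between the two is bridged by interpolation), II/III where the
headgroup density falls below 10% of its peak moving inward, III/IV at
`|z| = D_HH/4`, and region I extending one water-perturbation margin
(default 0.5 nm) beyond the crossover.

## 5. The synthetic system generator

`build_bilayer_system()` stands in for production trajectories. Its
defaults are the reference composition: 128 lipids per leaflet, 50 waters
per lipid (12,800 waters), 150 mM NaCl, 100 single-bead solutes, 16-carbon
tails, APL 0.618 nm², D_HH 3.732 nm, 330 K — so 100 solutes per 12,800
waters correspond to 0.432 M on the water-mole-ratio convention
(`n_solute/n_water × 55.35 M`), which is how the concentration is labeled
(`aqueous_concentration`); the per-box-volume molarity is also computable
via `solute_concentration(basis = "box")`. Ten frames are generated by
default; frames are independent draws, which makes block uncertainties
well-defined and is sufficient for estimator validation (no dynamics are
claimed).

What it emulates, and how:

- lipids are **idealized**: one headgroup bead (mass 163.2, 96 electrons,
  Gaussian z-scatter of width `headgroup_sigma = 0.15` nm about
  ±D_HH/2) plus a chain of carbons descending linearly toward the
  midplane, each with two explicit hydrogens at 0.109 nm;
- C–H orientations are drawn from an axially symmetric mixture whose
  order-parameter expectation equals `scd_target` exactly: isotropic plus
  in-plane vectors for negative targets (weight −2s), isotropic plus
  axis-parallel for positive targets (weight s);
- carbons carry a 0.1 nm z-jitter per lipid so the chain does not produce
  delta-like density spikes;
- waters (0.0304 nm³ each, setting the slab thickness) and ions fill the
  two aqueous slabs uniformly; ion counts follow the slab volume and salt
  concentration, with sodium counterions for any declared headgroup
  charge. Debye screening structure is deliberately ignored — ions are
  bookkeeping here;
- solute z positions are inverse-CDF draws (grid step ≤ 0.005 nm) from
  `exp(−PMF/RT)` for any supplied PMF, or uniform for `"none"`.

What it does **not** emulate: force fields, molecular water geometry,
equilibration dynamics, undulations, frame-to-frame correlation, membrane
response to solutes. Passing tests therefore demonstrate estimator
correctness against known ground truth, not fidelity to any particular
real bilayer.

Degenerate inputs are rejected up front: aqueous slabs thinner than
2×`headgroup_sigma` ("no bulk region"), order-parameter targets outside
[−0.5, 1], non-positive geometry. Identical spec + seed gives
bit-identical ensembles.

## 6. The adaptive-weight-histogram sampler

`awh_run()` is a didactic one-particle, one-dimensional reimplementation
of the accelerated-weight-histogram method, not the production MD-coupled
algorithm; its purpose is to validate the free-energy layer at desk scale
on potentials with known answers.

The extended state is (x, λ): x follows overdamped Langevin dynamics in
`U(x) + k/2 (x − λ)²`, integrated with the exact Ornstein–Uhlenbeck step
for the harmonic part (the external force is frozen across the step),
which is unconditionally stable — important because the default coupling
k = 12,800 kJ mol⁻¹ nm⁻² makes explicit Euler diverge at any practical
timestep. λ is Gibbs-resampled over the grid every step with weights
`exp(f_j − βk/2 (λ_j − x)²)`, f the current free-energy estimate in RT
units (flat target). Every `update_interval` (default 10) steps the
accumulated normalized λ-weights ΔW update the estimate:

```
f_j ← f_j − ln[(N/M + ΔW_j) / (N/M + u/M)]
```

with M grid points, u samples per update and N the reference
weight-histogram size. The initial size uses the heuristic
`N₀ = (RT/ε₀)² · t_cross / Δt_sample` with `t_cross = L²/(2D)` from the
diffusion estimate D — a smaller claimed initial error ε₀ or slower
diffusion both make early updates more cautious. In the initial stage N
doubles at each covering (every grid point visited since the last
covering); the final stage begins when the doubled N reaches the true
sample count, after which N grows linearly so the update size decays as
1/n. Defaults follow the reference setup: D = 2.5×10⁻⁴ nm² ps⁻¹,
ε₀ = 10 kJ/mol, k = 12,800 kJ mol⁻¹ nm⁻²; friction 1 ps⁻¹ at unit mass,
timestep 0.01 ps.

Numerical and design notes:

- **Grid spacing** defaults to 0.02 nm, comparable to the spring width
  `sqrt(RT/k) ≈ 0.015` nm. Much coarser grids Boltzmann-suppress λ hops
  (`exp(−βk h²/2)`) and slow mixing badly; this spacing is the single most
  important tuning choice of the sampler.
- The λ walk moves in spring-width steps, so mixing across a 4 nm grid
  takes ~10⁵ steps per crossing; the estimate's slowest (tilt) mode is
  correspondingly the last to converge. The flatness check in the
  acceptance suite runs 4×10⁷ steps (about 90 s of the compiled core) so
  that this mode's noise floor sits well inside the 0.5 kJ/mol bound;
  the double-well recovery uses 8×10⁶ steps and the harmonic check 5×10⁶.
- Gibbs weights are max-shifted before exponentiation; an all-zero weight
  vector aborts with a diagnostic rather than sampling garbage.
- `awh_estimate_pmf()` applies the stiff-spring deconvolution
  `U ≈ f − (RT/k)/2 · f″` (finite differences); at the default k the
  correction is a few thousandths of a kJ/mol and it vanishes as k → ∞
  (tested). Estimates from runs still in the initial stage carry a
  warning flag.
- Covering is defined as every grid point visited at least once since the
  last covering, counted on realized λ draws.
- `awh_convergence()` reports max-deviation-from-final per snapshot with a
  Mann–Kendall trend statistic. Visit-histogram flatness is assessed on
  the last half of sampling with a per-bin ±20% bound; a raw χ² test
  against uniform would assume independent draws, which autocorrelated
  visits are not.
- Exact reproducibility: the compiled core draws from R's RNG, so a seed
  fixes the full trace.

Out of scope by design: multiple walkers, multidimensional coordinates,
coupling to molecular systems.

## 7. Pipeline, I/O, CLI

`run_pipeline()` executes density → structure → partition → PMF →
features → regions, writing CSV/JSON artifacts plus a manifest (package
version, seeds, parameters, per-stage status and timings). Systems without
solutes skip the partition/PMF stages with warnings and succeed; any stage
error aborts with the stage name. Multiple seeds on synthetic input
produce replica PMFs combined into mean ± sd.

GRO files are read and written natively (fixed-column, nm, concatenated
frames; atom names encode the synthetic topology so species, chain indices
and hydrogen–carbon links round-trip); PDB and DCD go through bio3d with
Å→nm conversion. Triclinic boxes are rejected; XTC is not supported by the
available readers — convert to DCD or multi-frame GRO. CSV dialect is
comma-separated, dot-decimal, with required headers
(`z_nm, value, weighting, species, bin_width, n_frames` for profiles;
`z_nm, pmf_kJmol, sd_kJmol, valid` for PMFs). The CLI
(`inst/cli/memperm.R`) is a thin wrapper over these functions.

## 8. Validation strategy and problem sizes

The test suite validates every estimator against an independent oracle:
closed forms (partition integrals, order-parameter limits, VPL
arithmetic), quadrature of Boltzmann densities (position sampler, density
profiles, inverse-Boltzmann round trips), constructed profiles with exact
extrema (feature extraction, thickness), and analytic potentials (AWH).
Statistical checks run at sizes where the expected fluctuation is far from
the asserted bound: 10⁶ draws for sampler moments and PMF round trips
(multinomial noise ≈ 0.1 kJ/mol per well bin against 0.3 kJ/mol bounds),
10-frame default ensembles for structural recovery, and the sampler runs
listed above. The whole suite runs in roughly two minutes on one CPU.

## 9. Known limitations

- Single-frame independence in the generator means time-correlation
  effects on block errors are untested.
- Recentering assumes an intact, non-wrapped bilayer; heavily drifting
  trajectories should be pre-wrapped.
- The bulk region must exist: strongly undersized water slabs are rejected
  rather than analyzed.
- The AWH toy shares the estimator equations but not the engine's
  MD coupling, multi-walker support or target-distribution options; its
  convergence constants (N₀ heuristic) are documented here and tested only
  through convergence properties.
- Percent logP contrasts are sensitive to the printed rounding of their
  inputs; they are reported to one decimal at most.
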