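# memperm

Analysis toolkit for studying the **passive membrane permeation of small
solutes in phospholipid bilayers** from particle ensembles (molecular
dynamics trajectories or synthetic systems with known ground truth).

It is aimed at membrane biophysicists who have bilayer/solute coordinate
data and want, in one consistent unit system (nm, kJ/mol, amu, K, ps):

- **Density profiles** along the membrane normal — mass, electron or number
  weighted, with per-frame recentering on the lipid center of mass,
  optional symmetrization and aqueous bulk-density estimation.
- **Bilayer structural parameters** with block-averaged uncertainties:
  - area per lipid `APL = 2 Lx Ly / n_lipid`,
  - thickness `D_HH`, the distance between the headgroup peaks of the
    electron density profile (quadratic sub-bin peak refinement),
  - volume per lipid `VPL = D_HH × APL / 2`,
  - deuterium order parameters `S_CD(i) = ½⟨3 cos²Θ − 1⟩` per tail carbon,
    Θ the angle between a C–H bond and the bilayer normal.
- **Permeation energetics**:
  - the membrane/bulk partition coefficient

    ```
    P_memb/bulk = [∫_{-D/2}^{+D/2} ρ dz / D_HH] /
                  [(∫_{-Z/2}^{+Z/2} ρ dz − ∫_{-D/2}^{+D/2} ρ dz) / (Z_box − D_HH)]
    ```

  - potentials of mean force by inverse Boltzmann inversion,
    `PMF(z) = −RT ln(ρ(z)/ρ₀)`, with zero-count bins masked (never
    clamped), symmetrization, replica mean ± sd, barrier/minimum feature
    extraction, and the Marrink–Berendsen four-region decomposition.
- A **1-D accelerated-weight-histogram (AWH) sampler** on analytic
  potentials: overdamped Langevin dynamics harmonically coupled to a
  gridded reaction coordinate, Gibbs coordinate resampling, and the
  two-stage weight-histogram bias update (defaults: force constant
  12,800 kJ mol⁻¹ nm⁻², diffusion estimate 2.5×10⁻⁴ nm² ps⁻¹, initial
  error 10 kJ/mol). This validates the free-energy layer end to end
  against potentials whose answer is known.
- A **synthetic bilayer generator** (`bilayer_spec()` /
  `build_bilayer_system()`) whose defaults emulate the reference study
  composition — 128 lipids per leaflet, 50 waters per lipid, 150 mM NaCl,
  100 solute molecules — with controllable area per lipid, thickness, tail
  order, and solute distributions drawn from any prescribed PMF. Every
  estimator in the package is tested against this ground truth.
- I/O: GRO (read/write, multi-frame), PDB and DCD (via bio3d), profile and
  PMF CSVs, JSON results, YAML configs, plus a pipeline driver
  `run_pipeline()` and a thin CLI (`inst/cli/memperm.R`) with subcommands
  `build-synthetic`, `density`, `structure`, `partition`, `pmf`,
  `features`, `awh-toy`, `run-all`.

## Worked example

```r
library(memperm)

spec <- bilayer_spec(n_frames = 4)        # study-condition defaults
ens  <- build_bilayer_system(spec)
ens
#> <particle_ensemble> 4 frame(s), 25514 particles
#>   box (frame 1): 8.894 x 8.894 x 9.551 nm
#>   species: ion=70, lipid-head=256, lipid-tail-carbon=4096, solute=100,
#>            tail-hydrogen=8192, water=12800

ground_truth(ens)$aqueous_concentration   # 100 solutes / 12,800 waters
#> [1] 0.4324219                           # mol/L, the 0.432 M loading

structural_params(ens)
#> APL  = 0.6180 +/- 0.0000 nm^2
#> D_HH = 3.6806 +/- 0.0000 nm
#> VPL  = 1.1373 +/- 0.0000 nm^3
#> S_CD (chain average) = -0.1978

prof <- compute_density_profile(ens, "solute", "number", bin_width = 0.05)
partition_coefficient(prof, dhh = 3.68)
#> P_memb/bulk = 1.229 (logP = 0.0897), D_HH = 3.681 nm, Z = 9.551 nm

logp_contrast(-0.20, -0.55)               # DIOX, DPPG vs DPPE logP table
#> [1] 63.63636                            # percent reduction in |logP|
```

The APL is exact by construction (the builder sets the box from the
target), D_HH and S_CD recover their targets within the estimator
uncertainties, the uniform solute distribution gives P ≈ 1, and the logP
contrast reproduces the printed 63.7% within rounding of the table
entries.

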