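#' Physical constants and unit conventions
#'
#' All quantities in the package use a fixed unit system: lengths in nm,
#' energies in kJ/mol, masses in amu, temperatures in K, times in ps.
#' Note that 1 amu nm^2/ps^2 = 1 kJ/mol, so friction expressed as
#' mass x collision rate (amu/ps) is directly a molar friction
#' (kJ mol^-1 ps nm^-2).
#'
#' @name memperm-units
#' @keywords internal
NULL

#' Molar gas constant in kJ/(mol K).
#' @keywords internal
GAS_CONSTANT_KJ <- 8.314462618e-3

#' Avogadro constant (1/mol).
#' @keywords internal
AVOGADRO <- 6.02214076e23

# Molarity of pure liquid water (mol/L), used to convert a solute-per-water
# mole ratio into an aqueous-phase concentration.
WATER_MOLARITY <- 55.35

# Effective volume of one water molecule (nm^3) at simulation conditions;
# sets the aqueous slab thickness in the synthetic builder.
WATER_VOLUME_NM3 <- 0.0304

#' Aqueous-phase solute concentration from particle counts
#'
#' Converts a solute load into a molar concentration. Two conventions are
#' supported: `"aqueous"` (default) treats the solute/water mole ratio as a
#' dilute aqueous solution and multiplies by the molarity of pure water
#' (55.35 M); `"box"` divides the solute count by the total box volume.
#' The aqueous convention is the one under which 100 solutes per 12,800
#' waters corresponds to 0.432 M.
#'
#' @param n_solute number of solute molecules.
#' @param n_water number of water molecules (aqueous convention).
#' @param box_volume_nm3 box volume in nm^3 (box convention).
#' @param basis `"aqueous"` or `"box"`.
#' @return concentration in mol/L.
#' @examples
#' solute_concentration(100, n_water = 12800)
#' @export
solute_concentration <- function(n_solute, n_water = NULL, box_volume_nm3 = NULL,
                                 basis = c("aqueous", "box")) {
  basis <- match.arg(basis)
  stopifnot(is.numeric(n_solute), n_solute >= 0)
  if (basis == "aqueous") {
    if (is.null(n_water) || n_water <= 0)
      stop("aqueous basis requires a positive `n_water`")
    n_solute / n_water * WATER_MOLARITY
  } else {
    if (is.null(box_volume_nm3) || box_volume_nm3 <= 0)
      stop("box basis requires a positive `box_volume_nm3`")
    # molecules / (nm^3 -> L) / N_A
    n_solute / (box_volume_nm3 * 1e-24) / AVOGADRO
  }
}
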