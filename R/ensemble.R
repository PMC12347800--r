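#' Particle ensembles
#'
#' A `particle_ensemble` is the universal input container of the package:
#' one or more frames of 3-D coordinates (nm) in an orthorhombic box, plus
#' per-particle metadata shared by all frames.
#'
#' @details
#' The metadata data frame has one row per particle with columns:
#' \describe{
#'   \item{species}{one of `"lipid-head"`, `"lipid-tail-carbon"`,
#'     `"tail-hydrogen"`, `"water"`, `"ion"`, `"solute"`.}
#'   \item{mass}{amu.}
#'   \item{electron_count}{number of electrons carried by the particle.}
#'   \item{residue}{integer residue id.}
#'   \item{leaflet}{`"upper"`, `"lower"` or `"none"`.}
#'   \item{carbon_index}{position of a tail carbon along the acyl chain
#'     (1 = nearest the headgroup), `NA` otherwise.}
#'   \item{parent}{for tail hydrogens, the row index of the bonded carbon;
#'     `NA` otherwise.}
#' }
#' Coordinates are stored wrapped into `[0, L)` along each axis.
#'
#' @param frames list of N x 3 numeric matrices (nm).
#' @param box numeric matrix with one row per frame and columns
#'   `Lx`, `Ly`, `Lz` (nm).
#' @param particles metadata data frame as described above.
#' @return an object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(frames, box, particles) {
  if (!is.list(frames) || length(frames) == 0)
    stop("`frames` must be a non-empty list of coordinate matrices")
  if (is.null(dim(box))) box <- matrix(box, nrow = 1)
  box <- as.matrix(box)
  colnames(box) <- c("Lx", "Ly", "Lz")
  if (nrow(box) != length(frames))
    stop("`box` must have one row per frame")
  if (any(box <= 0)) stop("box lengths must be positive")
  required <- c("species", "mass", "electron_count", "residue", "leaflet",
                "carbon_index", "parent")
  if (!all(required %in% names(particles)))
    stop("particle metadata missing columns: ",
         paste(setdiff(required, names(particles)), collapse = ", "))
  n <- nrow(particles)
  frames <- lapply(seq_along(frames), function(i) {
    xyz <- frames[[i]]
    if (!is.matrix(xyz) || ncol(xyz) != 3)
      stop("each frame must be an N x 3 matrix")
    if (nrow(xyz) != n)
      stop("frame ", i, " has ", nrow(xyz), " particles; metadata has ", n)
    wrap_coords(xyz, box[i, ])
  })
  hyd <- which(particles$species == "tail-hydrogen")
  if (length(hyd)) {
    par <- particles$parent[hyd]
    if (anyNA(par) || any(particles$species[par] != "lipid-tail-carbon"))
      stop("every tail-hydrogen must reference a parent tail carbon")
  }
  structure(list(frames = frames, box = box, particles = particles),
            class = "particle_ensemble")
}

#' Wrap coordinates into the primary box image
#'
#' @param xyz N x 3 coordinate matrix (nm).
#' @param box length-3 vector of box lengths (nm).
#' @return wrapped N x 3 matrix with every coordinate in `[0, L)`.
#' @keywords internal
wrap_coords <- function(xyz, box) {
  for (k in 1:3) xyz[, k] <- xyz[, k] - floor(xyz[, k] / box[k]) * box[k]
  xyz
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cnt <- table(x$particles$species)
  cat("<particle_ensemble> ", length(x$frames), " frame(s), ",
      nrow(x$particles), " particles\n", sep = "")
  cat("  box (frame 1): ", paste(sprintf("%.3f", x$box[1, ]), collapse = " x "),
      " nm\n", sep = "")
  cat("  species:", paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `particle_ensemble`.
#' @return integer count.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Per-species particle counts
#'
#' Waters, ions and solutes are single-bead particles here, so the bead count
#' equals the molecule count for those species.
#'
#' @param ensemble a `particle_ensemble`.
#' @return named integer vector of counts by species tag.
#' @export
species_counts <- function(ensemble) {
  tab <- table(ensemble$particles$species)
  stats::setNames(as.integer(tab), names(tab))
}

#' Species tags considered part of the lipid
#'
#' Used for recentering and for lipid-wide density selections.
#' @export
LIPID_SPECIES <- c("lipid-head", "lipid-tail-carbon", "tail-hydrogen")

# Mass-weighted lipid center of mass along z for one frame (assumes the
# bilayer is not split across the periodic boundary).
lipid_com_z <- function(ensemble, frame) {
  sel <- ensemble$particles$species %in% LIPID_SPECIES
  if (!any(sel)) stop("ensemble contains no lipid-tagged particles")
  m <- ensemble$particles$mass[sel]
  sum(m * ensemble$frames[[frame]][sel, 3]) / sum(m)
}
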