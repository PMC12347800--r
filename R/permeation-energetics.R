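#' PMF profile objects
#'
#' A `pmf_profile` is a free-energy curve along the membrane normal on a
#' uniform symmetric grid, in kJ/mol, with a per-bin validity mask (bins
#' with zero sampled density carry no value and are never clamped).
#'
#' @param z bin centers (nm), symmetric about 0.
#' @param value kJ/mol; `NA` where invalid.
#' @param valid logical mask of valid bins.
#' @param temperature K.
#' @param sd optional per-bin standard deviation (kJ/mol).
#' @param one_sided logical mask marking bins whose value came from a single
#'   side during symmetrization.
#' @param reference referencing convention tag (`"bulk-zero"`, `"min-zero"`
#'   or `"none"`).
#' @return object of class `pmf_profile`.
#' @export
pmf_profile <- function(z, value, valid = is.finite(value), temperature = 330,
                        sd = NULL, one_sided = NULL, reference = "none") {
  stopifnot(length(z) == length(value), temperature > 0)
  if (max(abs(z + rev(z))) > 1e-9) stop("grid is not symmetric about zero")
  value[!valid] <- NA_real_
  if (any(!is.finite(value[valid]))) stop("valid bins must be finite")
  structure(list(z = as.numeric(z), value = as.numeric(value),
                 sd = sd, valid = as.logical(valid),
                 one_sided = if (is.null(one_sided))
                   rep(FALSE, length(z)) else one_sided,
                 temperature = temperature, reference = reference,
                 gas_constant = GAS_CONSTANT_KJ),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("<pmf_profile> ", length(x$z), " bins, ", sum(x$valid), " valid; T = ",
      x$temperature, " K; reference = ", x$reference, "\n", sep = "")
  rng <- range(x$value[x$valid])
  cat(sprintf("  range %.3f .. %.3f kJ/mol\n", rng[1], rng[2]))
  invisible(x)
}

# Trapezoidal integral of the piecewise-linear interpolant of (z, v) over
# [a, b], inserting interpolated cut points at a and b; constant extension
# beyond the outermost centers.
trapz_interval <- function(z, v, a, b) {
  f <- stats::approxfun(z, v, rule = 2)
  inside <- z[z > a & z < b]
  zz <- c(a, inside, b)
  vv <- f(zz)
  sum((vv[-1] + vv[-length(vv)]) / 2 * diff(zz))
}

#' Membrane/bulk partition coefficient from a solute density profile
#'
#' Computes
#' \deqn{P = \frac{\int_{-D/2}^{+D/2} \rho\,dz / D}
#'                {(\int_{-Z/2}^{+Z/2} \rho\,dz - \int_{-D/2}^{+D/2} \rho\,dz)
#'                 / (Z - D)}}
#' with D the headgroup peak-to-peak thickness and Z the box height: the mean
#' solute density inside the membrane slab over its mean density in the
#' remaining (bulk) region. Integration is composite trapezoid with explicit
#' interpolated cut points at +/- D/2, so the result is robust to the bin
#' width; the total integral uses the conservation convention
#' `sum(value) * bin_width` (each bin contributes its full width).
#'
#' @param profile solute [density_profile()].
#' @param dhh membrane thickness D_HH in nm, 0 < dhh < z_box.
#' @return list of class `partition_result`: `p_memb_bulk`, `logp` (log10),
#'   `dhh_used`, `z_box`, `membrane_integral`, `bulk_integral`.
#' @examples
#' z <- seq(-4.95, 4.95, by = 0.1)
#' prof <- density_profile(z, rep(2, length(z)), 0.1, "number", "solute",
#'                         1, 25, 9.9 + 0.1)
#' partition_coefficient(prof, 3.8)$logp # 0
#' @export
partition_coefficient <- function(profile, dhh) {
  stopifnot(inherits(profile, "density_profile"))
  zbox <- profile$z_box
  if (dhh <= 0 || dhh >= zbox) stop("need 0 < dhh < z_box")
  h <- profile$bin_width
  total <- sum(profile$value) * h
  memb <- trapz_interval(profile$z, profile$value, -dhh / 2, dhh / 2)
  bulk <- total - memb
  if (bulk <= 0) stop("no solute in bulk: partition coefficient undefined")
  if (memb <= 0) stop("no solute in the membrane slab")
  p <- (memb / dhh) / (bulk / (zbox - dhh))
  structure(list(p_memb_bulk = p, logp = log10(p), dhh_used = dhh,
                 z_box = zbox, membrane_integral = memb,
                 bulk_integral = bulk),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("P_memb/bulk = %.4g (logP = %.4f), D_HH = %.3f nm, Z = %.3f nm\n",
              x$p_memb_bulk, x$logp, x$dhh_used, x$z_box))
  invisible(x)
}

#' Percent contrast between two logP values
#'
#' `100 * (|logp_b| - |logp_a|) / |logp_b|`: the percent reduction in logP
#' magnitude going from system b to system a (e.g. from the least to the most
#' permeable membrane). Invariant under a joint sign flip.
#'
#' @param logp_a,logp_b log10 partition coefficients; `logp_b` nonzero.
#' @return percent reduction.
#' @examples
#' logp_contrast(-0.20, -0.55) # ~63.6
#' @export
logp_contrast <- function(logp_a, logp_b) {
  if (logp_b == 0) stop("logp_b must be nonzero")
  100 * (abs(logp_b) - abs(logp_a)) / abs(logp_b)
}

#' Potential of mean force by inverse Boltzmann inversion
#'
#' `PMF(z) = -R T ln(rho(z) / rho0)` on bins with positive density; zero
#' density bins are masked invalid rather than clamped (pseudo-counts would
#' bias barrier heights). The curve is then referenced so the mean over the
#' declared bulk region is zero.
#'
#' @param profile solute [density_profile()].
#' @param rho0 aqueous bulk reference density (> 0), e.g. from
#'   [estimate_bulk_density()].
#' @param temperature K.
#' @param z_bulk inner edge of the bulk region used for referencing (nm);
#'   default: outer quarter of the grid on each side. Use `NA` to skip
#'   referencing (pure inversion).
#' @return a [pmf_profile()]; the subtracted offset is stored as attribute
#'   `reference_shift` (kJ/mol) so the inversion can be undone exactly.
#' @export
pmf_from_density <- function(profile, rho0, temperature, z_bulk = NULL) {
  stopifnot(inherits(profile, "density_profile"), rho0 > 0, temperature > 0)
  valid <- profile$value > 0
  if (!any(valid)) stop("all bins have zero density")
  val <- rep(NA_real_, length(profile$z))
  val[valid] <- -GAS_CONSTANT_KJ * temperature *
    log(profile$value[valid] / rho0)
  shift <- 0
  ref <- "none"
  if (is.null(z_bulk)) z_bulk <- 0.75 * max(abs(profile$z))
  if (!is.na(z_bulk)) {
    sel <- valid & abs(profile$z) > z_bulk
    if (!any(sel)) stop("no valid bins in the bulk region |z| > ", z_bulk)
    shift <- mean(val[sel])
    val <- val - shift
    ref <- "bulk-zero"
  }
  out <- pmf_profile(profile$z, val, valid, temperature, reference = ref)
  attr(out, "reference_shift") <- shift
  out
}

#' Density implied by a PMF (inverse of [pmf_from_density()])
#'
#' @param pmf a [pmf_profile()] from [pmf_from_density()].
#' @param rho0 the reference density used in the inversion.
#' @return numeric density vector (NA on invalid bins).
#' @export
density_from_pmf <- function(pmf, rho0) {
  shift <- attr(pmf, "reference_shift")
  if (is.null(shift)) shift <- 0
  rho0 * exp(-(pmf$value + shift) / (GAS_CONSTANT_KJ * pmf$temperature))
}

#' Symmetrize a PMF about the midplane
#'
#' `out(z) = (in(z) + in(-z))/2` where both sides are valid; where only one
#' side is valid its value is used and the bin is flagged `one_sided`.
#' Idempotent.
#'
#' @param pmf a [pmf_profile()] on a symmetric grid.
#' @return symmetrized [pmf_profile()].
#' @export
symmetrize_pmf <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  v <- pmf$value; ok <- pmf$valid
  rv <- rev(v); rok <- rev(ok)
  out <- ifelse(ok & rok, (v + rv) / 2, ifelse(ok, v, rv))
  new_valid <- ok | rok
  one_sided <- xor(ok, rok)
  res <- pmf_profile(pmf$z, out, new_valid, pmf$temperature,
                     one_sided = one_sided, reference = pmf$reference)
  attr(res, "reference_shift") <- attr(pmf, "reference_shift")
  res
}

#' Combine replica PMFs
#'
#' Per-bin mean and sample standard deviation over replicas on identical
#' grids; the validity mask of the result is the intersection of the replica
#' masks.
#'
#' @param pmfs list of >= 2 [pmf_profile()]s, each already referenced.
#' @return a [pmf_profile()] with `sd` filled in.
#' @export
combine_replicas <- function(pmfs) {
  if (!is.list(pmfs) || length(pmfs) < 2)
    stop("need at least 2 replica PMFs")
  z <- pmfs[[1]]$z
  for (p in pmfs[-1])
    if (length(p$z) != length(z) || max(abs(p$z - z)) > 1e-9)
      stop("replica grids do not match")
  vals <- sapply(pmfs, function(p) p$value)
  valid <- Reduce(`&`, lapply(pmfs, function(p) p$valid))
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  m[!valid] <- NA_real_; s[!valid] <- NA_real_
  pmf_profile(z, m, valid, pmfs[[1]]$temperature, sd = s,
              reference = pmfs[[1]]$reference)
}

# Centered moving average with partial windows at the edges; NA-aware.
moving_average <- function(y, window) {
  if (window <= 1) return(y)
  half <- floor(window / 2)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(y[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

# Indices of interior local maxima/minima by sign changes of the discrete
# derivative (zero slopes inherit the previous sign, so plateaus report one
# extremum).
local_extrema <- function(y) {
  d <- sign(diff(y))
  for (i in seq_along(d)[-1]) if (d[i] == 0) d[i] <- d[i - 1]
  turn <- diff(d)
  list(maxima = which(turn < 0) + 1L, minima = which(turn > 0) + 1L)
}

# Half-height crossings around a peak via linear interpolation, scanning
# outward until the curve drops below `level`.
half_width <- function(z, y, jpeak, level) {
  cross <- function(dir) {
    j <- jpeak
    repeat {
      jn <- j + dir
      if (jn < 1 || jn > length(y) || is.na(y[jn])) return(NA_real_)
      if (y[jn] <= level) {
        frac <- (y[j] - level) / (y[j] - y[jn])
        return(z[j] + frac * (z[jn] - z[j]))
      }
      j <- jn
    }
  }
  zl <- cross(-1L); zr <- cross(+1L)
  if (is.na(zl) || is.na(zr)) return(list(width = NA_real_, left = zl, right = zr))
  list(width = zr - zl, left = zl, right = zr)
}

#' Barrier and minimum features of a permeation PMF
#'
#' On a moving-average-smoothed copy of the profile, local extrema are found
#' by sign changes of the discrete derivative. The central barrier is the
#' highest maximum in `|z| < dhh/4` and is reported both vs bulk (the value
#' itself, since bulk = 0) and vs the mean of its two flanking minima; its
#' width is the full width at half height above the flanking minima, by
#' linear interpolation. The outer barrier is the highest maximum in the
#' headgroup band `dhh/4 < |z| < dhh/2 + 0.5`. All local minima are listed
#' with positions and depths vs bulk. Absent features are reported as `NA`,
#' never as zero. Features from the unsmoothed curve are attached under
#' `$unsmoothed`.
#'
#' @param pmf a [pmf_profile()] referenced to bulk zero.
#' @param dhh membrane thickness (nm) defining the central/headgroup bands.
#' @param smoothing_window moving-average window in bins (default 5; 1
#'   disables smoothing).
#' @return list of class `pmf_features`.
#' @export
extract_features <- function(pmf, dhh, smoothing_window = 5) {
  stopifnot(inherits(pmf, "pmf_profile"), dhh > 0)
  features_of <- function(window) {
    z <- pmf$z
    y <- moving_average(pmf$value, window)
    y[!pmf$valid] <- NA_real_
    ex <- local_extrema(y)
    out <- list(central_barrier_vs_bulk = NA_real_,
                central_barrier_vs_adjacent_min = NA_real_,
                central_barrier_width = NA_real_,
                central_barrier_position = NA_real_,
                outer_barrier = NA_real_, outer_barrier_position = NA_real_,
                minima = data.frame(position = numeric(0), depth = numeric(0)))
    if (length(ex$minima))
      out$minima <- data.frame(position = z[ex$minima], depth = y[ex$minima])
    central <- ex$maxima[abs(z[ex$maxima]) < dhh / 4 & !is.na(y[ex$maxima])]
    if (length(central)) {
      j <- central[which.max(y[central])]
      out$central_barrier_vs_bulk <- y[j]
      out$central_barrier_position <- z[j]
      left_min <- ex$minima[ex$minima < j]
      right_min <- ex$minima[ex$minima > j]
      flank <- c(if (length(left_min)) y[max(left_min)],
                 if (length(right_min)) y[min(right_min)])
      if (length(flank)) {
        fm <- mean(flank)
        out$central_barrier_vs_adjacent_min <- y[j] - fm
        out$central_barrier_width <-
          half_width(z, y, j, (y[j] + fm) / 2)$width
      }
    }
    band <- ex$maxima[abs(z[ex$maxima]) > dhh / 4 &
                        abs(z[ex$maxima]) < dhh / 2 + 0.5 &
                        !is.na(y[ex$maxima])]
    if (length(band)) {
      j <- band[which.max(y[band])]
      out$outer_barrier <- y[j]
      out$outer_barrier_position <- z[j]
    }
    out
  }
  res <- features_of(smoothing_window)
  res$smoothing_window <- smoothing_window
  res$unsmoothed <- features_of(1L)
  class(res) <- "pmf_features"
  res
}

#' @export
print.pmf_features <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.3f", v)
  cat("central barrier: ", fmt(x$central_barrier_vs_bulk),
      " kJ/mol vs bulk, ", fmt(x$central_barrier_vs_adjacent_min),
      " vs adjacent minima, width ", fmt(x$central_barrier_width), " nm\n",
      sep = "")
  cat("outer barrier:   ", fmt(x$outer_barrier), " kJ/mol at ",
      fmt(x$outer_barrier_position), " nm\n", sep = "")
  if (nrow(x$minima))
    cat("minima: ", paste(sprintf("%.2f kJ/mol @ %.2f nm", x$minima$depth,
                                  x$minima$position), collapse = "; "), "\n")
  invisible(x)
}

#' Four-region decomposition of the bilayer
#'
#' Splits `|z|` into the Marrink-Berendsen regions: (I) perturbed interfacial
#' water, (II) charged headgroups, (III) dense acyl chains, (IV) bilayer
#' center. The II/I boundary is the outermost water-lipid density crossover;
#' the II/III boundary is the inner edge where the headgroup density falls
#' below 10% of its peak; III/IV sits at `|z| = dhh/4`; region I extends one
#' water-perturbation margin beyond the II/I crossover.
#'
#' @param lipid_profile,water_profile,headgroup_profile [density_profile()]s
#'   on a shared grid.
#' @param dhh membrane thickness (nm).
#' @param water_margin width of region I beyond the crossover (nm,
#'   default 0.5).
#' @return object of class `region_boundaries`: a data frame with columns
#'   `region`, `inner`, `outer` (nm, in `|z|`), ordered IV to I.
#' @export
assign_regions <- function(lipid_profile, water_profile, headgroup_profile,
                           dhh, water_margin = 0.5) {
  z <- lipid_profile$z
  for (p in list(water_profile, headgroup_profile))
    if (length(p$z) != length(z) || max(abs(p$z - z)) > 1e-9)
      stop("profiles must share one grid")
  # fold onto |z| by averaging the two sides
  fold <- function(v) {
    s <- (v + rev(v)) / 2
    s[z >= 0]
  }
  az <- z[z >= 0]
  lw <- fold(water_profile$value) - fold(lipid_profile$value)
  # outermost crossover: beyond it water dominates, inside it the lipid
  # does; a zero gap between the two (both densities vanishing) is bridged
  # by interpolating between the last lipid-dominated and the first
  # water-dominated bin
  j_neg <- suppressWarnings(max(which(lw < 0)))
  pos_after <- which(lw > 0 & seq_along(lw) > j_neg)
  if (!is.finite(j_neg) || !length(pos_after))
    stop("bilayer not resolved: no water-lipid crossover")
  j_pos <- min(pos_after)
  frac <- lw[j_neg] / (lw[j_neg] - lw[j_pos])
  b_II_I <- az[j_neg] + frac * (az[j_pos] - az[j_neg])
  hg <- fold(headgroup_profile$value)
  jpk <- which.max(hg)
  thr <- 0.1 * hg[jpk]
  below <- which(hg[seq_len(jpk)] < thr)
  b_II_III <- if (length(below)) {
    jb <- max(below) # innermost edge below threshold, moving out from center
    frac <- (thr - hg[jb]) / (hg[jb + 1] - hg[jb])
    az[jb] + frac * (az[jb + 1] - az[jb])
  } else dhh / 4
  b_III_IV <- dhh / 4
  b_II_III <- max(b_II_III, b_III_IV)
  if (b_II_I <= b_II_III)
    stop("bilayer not resolved: crossover inside the headgroup edge")
  out <- data.frame(
    region = c("IV", "III", "II", "I"),
    inner = c(0, b_III_IV, b_II_III, b_II_I),
    outer = c(b_III_IV, b_II_III, b_II_I, b_II_I + water_margin))
  class(out) <- c("region_boundaries", class(out))
  out
}

#' Write a PMF (with features) to CSV / JSON
#'
#' The PMF CSV has columns `z_nm, pmf_kJmol, sd_kJmol, valid`; features are
#' written as a JSON record.
#'
#' @param pmf a [pmf_profile()].
#' @param path CSV output path.
#' @param features optional `pmf_features`; `features_path` its JSON output.
#' @param features_path JSON output path for the features.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(pmf, path, features = NULL, features_path = NULL) {
  df <- data.frame(z_nm = pmf$z, pmf_kJmol = pmf$value,
                   sd_kJmol = if (is.null(pmf$sd)) NA_real_ else pmf$sd,
                   valid = pmf$valid)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(features) && !is.null(features_path)) {
    rec <- unclass(features)
    rec$unsmoothed <- unclass(rec$unsmoothed)
    jsonlite::write_json(rec, features_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}
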