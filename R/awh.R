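#' Parameters for the 1-D accelerated-weight-histogram sampler
#'
#' Configures the didactic one-particle AWH run: a uniform reaction
#' coordinate grid, the harmonic coupling between the particle and the
#' coordinate, the adaptive-bias bookkeeping constants, and the overdamped
#' Langevin dynamics. Defaults follow the reference free-energy setup: pull
#' force constant 12,800 kJ mol^-1 nm^-2, reaction-coordinate diffusion
#' estimate 2.5e-4 nm^2/ps, initial error estimate 10 kJ/mol. The particle
#' itself moves with friction `langevin_friction` (collision rate, 1/ps)
#' times `particle_mass` (amu); since 1 amu nm^2/ps^2 = 1 kJ/mol this product
#' is directly the molar friction zeta in kJ mol^-1 ps nm^-2.
#'
#' The initial reference weight-histogram size uses the heuristic
#' `N0 = (RT / initial_error)^2 * t_cross / dt_sample`, where
#' `t_cross = L^2 / (2 D)` is the diffusive grid-crossing time implied by
#' the diffusion estimate and `dt_sample = timestep * update_interval`:
#' smaller claimed initial errors or slower diffusion both make the initial
#' updates more cautious.
#'
#' @param grid uniform reaction-coordinate grid (nm), >= 10 points. The
#'   default spacing (0.02 nm) is comparable to the harmonic-coupling width
#'   `sqrt(RT/k)`; much coarser grids suppress coordinate hops and slow
#'   mixing.
#' @param force_constant harmonic coupling k, kJ/(mol nm^2).
#' @param diffusion_estimate D along the coordinate, nm^2/ps.
#' @param initial_error initial free-energy error estimate, kJ/mol.
#' @param temperature K.
#' @param langevin_friction collision rate, 1/ps.
#' @param particle_mass amu.
#' @param timestep ps.
#' @param n_steps total dynamics steps.
#' @param update_interval steps between estimate updates.
#' @param seed integer RNG seed.
#' @param target target distribution tag; only `"flat"` is implemented.
#' @return object of class `awh_params`.
#' @export
awh_params <- function(grid = seq(-2, 2, by = 0.02),
                       force_constant = 12800,
                       diffusion_estimate = 2.5e-4,
                       initial_error = 10,
                       temperature = 330,
                       langevin_friction = 1,
                       particle_mass = 1,
                       timestep = 0.01,
                       n_steps = 2e6,
                       update_interval = 10,
                       seed = 1L,
                       target = "flat") {
  if (length(grid) < 10) stop("grid needs at least 10 points")
  if (max(abs(diff(grid) - diff(grid)[1])) > 1e-9) stop("grid must be uniform")
  if (force_constant <= 0) stop("force_constant must be > 0")
  if (diffusion_estimate <= 0) stop("diffusion_estimate must be > 0")
  if (initial_error <= 0) stop("initial_error must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (!identical(target, "flat")) stop("only the flat target is implemented")
  structure(list(grid = as.numeric(grid), force_constant = force_constant,
                 diffusion_estimate = diffusion_estimate,
                 initial_error = initial_error, temperature = temperature,
                 langevin_friction = langevin_friction,
                 particle_mass = particle_mass, timestep = timestep,
                 n_steps = as.numeric(n_steps),
                 update_interval = as.integer(update_interval),
                 seed = as.integer(seed), target = target),
            class = "awh_params")
}

#' Run the toy AWH sampler on an analytic potential
#'
#' Alternates (a) overdamped Langevin steps of the particle under
#' `U(x) + k/2 (x - lambda)^2` (exact Ornstein-Uhlenbeck integration of the
#' harmonic part, stable at any timestep), (b) Gibbs resampling of the
#' reaction coordinate over the grid with weights
#' `exp(g_j - k/2 (lambda_j - x)^2 / RT)` where `g_j` is the current
#' free-energy estimate (flat target), and (c) periodic weight-histogram
#' updates of the estimate. The initial stage halves the update size at each
#' covering of the grid and hands over to the final stage, in which the
#' update size decays as 1/n_samples. Deterministic under the params seed.
#'
#' @param potential vectorized function of z (nm) returning kJ/mol, finite
#'   over the grid span.
#' @param params an [awh_params()].
#' @return object of class `awh_state` with elements `free_energy_estimate`
#'   (kJ/mol, min-referenced), `reference_weight_histogram`,
#'   `visit_histogram`, `visit_final` (visits accumulated in the final
#'   stage), `visit_last_half` (visits over the last half of sampling),
#'   `stage`, `covering_count`, `update_size`, `trace` (snapshot
#'   matrix, kJ/mol) and `params`.
#' @examples
#' st <- awh_run(function(z) 0 * z,
#'               awh_params(grid = seq(-1, 1, by = 0.1), n_steps = 2e4))
#' diff(range(st$free_energy_estimate)) # small: flat landscape
#' @export
awh_run <- function(potential, params) {
  stopifnot(is.function(potential), inherits(params, "awh_params"))
  g <- params$grid
  margin <- 0.3
  tab_step <- 0.001
  xtab <- seq(min(g) - margin, max(g) + margin, by = tab_step)
  u <- potential(xtab)
  if (!all(is.finite(u))) stop("potential is non-finite on the grid span")
  # central-difference force table
  ftab <- -c(u[2] - u[1], (u[-(1:2)] - u[-((length(u) - 1):length(u))]) / 2,
             u[length(u)] - u[length(u) - 1]) / tab_step
  RT <- GAS_CONSTANT_KJ * params$temperature
  zeta <- params$particle_mass * params$langevin_friction
  L <- diff(range(g))
  t_cross <- L^2 / (2 * params$diffusion_estimate)
  N0 <- max(length(g), (RT / params$initial_error)^2 * t_cross /
              (params$timestep * params$update_interval))
  set.seed(params$seed)
  raw <- awh_run_cpp(g, u, ftab, xtab[1], tab_step, params$force_constant,
                     RT, zeta, params$timestep, params$n_steps,
                     params$update_interval, N0,
                     trace_stride = max(1L, as.integer(
                       params$n_steps / params$update_interval / 200)))
  fe <- raw$free_energy
  structure(list(
    free_energy_estimate = fe - min(fe),
    reference_weight_histogram = rep(raw$histogram_size / length(g), length(g)),
    visit_histogram = raw$visit_hist,
    visit_final = raw$visit_final,
    visit_last_half = raw$visit_last_half,
    stage = raw$stage,
    covering_count = raw$covering_count,
    update_size = raw$update_size,
    trace = raw$trace,
    trace_updates = raw$trace_updates,
    grid = g, params = params), class = "awh_state")
}

#' @export
print.awh_state <- function(x, ...) {
  cat("<awh_state> ", length(x$grid), " grid points; stage = ", x$stage,
      "; coverings = ", x$covering_count, "\n", sep = "")
  cat(sprintf("  estimate range %.3f .. %.3f kJ/mol; update size %.3g\n",
              min(x$free_energy_estimate), max(x$free_energy_estimate),
              x$update_size))
  invisible(x)
}

#' PMF estimate from an AWH state
#'
#' The raw estimate converges to the free energy of the harmonically coupled
#' system, i.e. the true PMF convolved with the Gaussian spring distribution
#' of width `sqrt(RT/k)`. Under the stiff-spring approximation the
#' first-order deconvolution subtracts `(RT/k)/2` times the second
#' derivative of the estimate; for the default force constant the correction
#' is a few thousandths of a kJ/mol. The output is min-referenced on the
#' sampling grid.
#'
#' @param state an `awh_state` from [awh_run()].
#' @return a [pmf_profile()] on the sampling grid (reference `"min-zero"`);
#'   carries attribute `stage_warning = TRUE` if the run never left the
#'   initial stage.
#' @export
awh_estimate_pmf <- function(state) {
  stopifnot(inherits(state, "awh_state"))
  warn <- !identical(state$stage, "final")
  if (warn) warning("AWH run is still in the initial stage; estimate is rough")
  f <- state$free_energy_estimate
  h <- diff(state$grid)[1]
  n <- length(f)
  fpp <- c(0, (f[-(1:2)] - 2 * f[-c(1, n)] + f[-((n - 1):n)]) / h^2, 0)
  sigma2 <- GAS_CONSTANT_KJ * state$params$temperature /
    state$params$force_constant
  u <- f - sigma2 / 2 * fpp
  u <- u - min(u)
  out <- pmf_profile(state$grid, u, temperature = state$params$temperature,
                     reference = "min-zero")
  attr(out, "stage_warning") <- warn
  out
}

#' Convergence trace of an AWH run
#'
#' For each stored snapshot, the maximum absolute deviation of the estimate
#' from the final estimate, together with a Mann-Kendall monotone-trend
#' statistic of the series.
#'
#' @param state an `awh_state` (>= 2 snapshots in its trace).
#' @return data frame with columns `update` and `max_dev` (kJ/mol);
#'   attributes `mann_kendall_S` and `kendall_tau` carry the trend test.
#' @export
awh_convergence <- function(state) {
  stopifnot(inherits(state, "awh_state"))
  tr <- state$trace
  if (is.null(dim(tr)) || nrow(tr) < 2) stop("need at least 2 trace snapshots")
  fin <- state$free_energy_estimate
  dev <- apply(tr, 1, function(f) max(abs((f - min(f)) - fin)))
  out <- data.frame(update = state$trace_updates, max_dev = dev)
  d <- outer(dev, dev, `-`)
  # lower triangle holds dev_later - dev_earlier, so the sign sum is S
  S <- sum(sign(d[lower.tri(d)]))
  attr(out, "mann_kendall_S") <- S
  attr(out, "kendall_tau") <- suppressWarnings(
    stats::cor(seq_along(dev), dev, method = "kendall"))
  out
}
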