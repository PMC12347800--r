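#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation on a uniform table (clamped at the ends).
static inline double interp_table(const NumericVector &tab, double x0,
                                  double step, double x) {
  double t = (x - x0) / step;
  int n = tab.size();
  if (t <= 0.0) return tab[0];
  if (t >= n - 1) return tab[n - 1];
  int j = (int)t;
  double f = t - j;
  return tab[j] * (1.0 - f) + tab[j + 1] * f;
}

// Core loop of the 1-D accelerated-weight-histogram sampler.
//
// One particle x moves by overdamped Langevin dynamics in
// U(x) + k/2 (x - lambda)^2, integrated with the exact
// Ornstein-Uhlenbeck step for the harmonic part (the external force is
// frozen over the step), which is stable for any timestep. The reaction
// coordinate lambda is Gibbs-resampled over the grid each step with weights
// proportional to exp(f_j - beta k/2 (lambda_j - x)^2), f_j being the
// current free-energy estimate in units of RT (flat target distribution).
// Every `update_interval` steps the accumulated normalized lambda-weights
// are folded into the estimate:
//   f_j <- f_j - log( (N/M + dW_j) / (N/M + u/M) )
// where N is the reference weight-histogram size, M the number of grid
// points and u the samples per update. In the initial stage N doubles at
// each covering (every grid point visited since the last covering); the
// final stage is entered once the doubled N reaches the actual accumulated
// sample count, after which N grows linearly with samples so the update
// size decays as 1/n.
//
// U and its force are passed as tables on a uniform fine grid; energies in
// kJ/mol are converted to RT units internally. Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List awh_run_cpp(NumericVector grid, NumericVector u_tab, NumericVector f_tab,
                 double tab_x0, double tab_step, double k, double RT,
                 double zeta, double dt, double n_steps_d, int update_interval,
                 double N0, int trace_stride) {
  const int M = grid.size();
  const long long n_steps = (long long)n_steps_d;
  const double beta = 1.0 / RT;
  const double decay = std::exp(-k * dt / zeta);
  const double noise_sd = std::sqrt(RT / k * (1.0 - decay * decay));
  const double xmin = tab_x0;
  const double xmax = tab_x0 + tab_step * (u_tab.size() - 1);

  std::vector<double> f(M, 0.0);          // estimate, RT units
  std::vector<double> dW(M, 0.0);         // weight accumulation this interval
  std::vector<double> w(M, 0.0);
  std::vector<double> visits_since(M, 0.0);
  NumericVector visit_hist(M), visit_final(M), visit_last_half(M);

  double N = N0;                           // reference histogram size
  bool initial_stage = true;
  int covering_count = 0;
  long long n_samples = 0;
  const double u_per_update = (double)update_interval;
  long long n_updates_total = n_steps / update_interval;
  int n_trace = (int)(n_updates_total / trace_stride) + 1;
  NumericMatrix trace(n_trace, M);
  std::vector<double> trace_update_idx;
  int trace_row = 0;
  long long update_count = 0;

  double x = grid[M / 2];
  int lam = M / 2;

  GetRNGstate();
  for (long long step = 0; step < n_steps; ++step) {
    // (a) exact-OU Langevin step with the external force frozen
    double Fu = interp_table(f_tab, tab_x0, tab_step, x);
    double xm = grid[lam] + Fu / k;
    x = xm + (x - xm) * decay + noise_sd * norm_rand();
    if (x < xmin) x = 2.0 * xmin - x; // reflect at the table ends
    if (x > xmax) x = 2.0 * xmax - x;

    // (b) Gibbs resampling of lambda over the grid
    double emax = -1e300;
    for (int j = 0; j < M; ++j) {
      double d = grid[j] - x;
      double e = f[j] - 0.5 * beta * k * d * d;
      w[j] = e;
      if (e > emax) emax = e;
    }
    double wsum = 0.0;
    for (int j = 0; j < M; ++j) {
      w[j] = std::exp(w[j] - emax);
      wsum += w[j];
    }
    if (!(wsum > 0.0) || !std::isfinite(wsum)) {
      PutRNGstate();
      stop("zero or non-finite Gibbs weights at step %lld (x = %g)",
           step, x);
    }
    double u = unif_rand() * wsum, acc = 0.0;
    lam = M - 1;
    for (int j = 0; j < M; ++j) {
      acc += w[j];
      if (u <= acc) { lam = j; break; }
    }

    // (c) accumulate histograms
    for (int j = 0; j < M; ++j) dW[j] += w[j] / wsum;
    visits_since[lam] += 1.0;
    visit_hist[lam] += 1.0;
    if (!initial_stage) visit_final[lam] += 1.0;
    if (2 * (step + 1) > n_steps) visit_last_half[lam] += 1.0;
    ++n_samples;

    if ((step + 1) % update_interval == 0) {
      double ref = N / M;
      double tgt = u_per_update / M;
      for (int j = 0; j < M; ++j) {
        f[j] -= std::log((ref + dW[j]) / (ref + tgt));
        dW[j] = 0.0;
      }
      double fmin = *std::min_element(f.begin(), f.end());
      for (int j = 0; j < M; ++j) f[j] -= fmin;

      // covering check
      bool covered = true;
      for (int j = 0; j < M; ++j)
        if (visits_since[j] < 1.0) { covered = false; break; }
      if (covered) {
        ++covering_count;
        std::fill(visits_since.begin(), visits_since.end(), 0.0);
        if (initial_stage) {
          N *= 2.0;
          if (N >= (double)n_samples) {
            initial_stage = false;
            N = (double)n_samples;
          }
        }
      }
      if (!initial_stage) N += u_per_update;

      if (update_count % trace_stride == 0 && trace_row < n_trace) {
        for (int j = 0; j < M; ++j) trace(trace_row, j) = f[j] * RT;
        trace_update_idx.push_back((double)(update_count + 1));
        ++trace_row;
      }
      ++update_count;
    }
  }
  PutRNGstate();

  NumericVector fe(M);
  for (int j = 0; j < M; ++j) fe[j] = f[j] * RT;
  return List::create(
    _["free_energy"] = fe,
    _["visit_hist"] = visit_hist,
    _["visit_final"] = visit_final,
    _["visit_last_half"] = visit_last_half,
    _["stage"] = initial_stage ? "initial" : "final",
    _["covering_count"] = covering_count,
    _["histogram_size"] = N,
    _["update_size"] = u_per_update / N,
    _["n_updates"] = (double)update_count,
    _["trace"] = trace(Range(0, std::max(trace_row - 1, 0)), _),
    _["trace_updates"] = wrap(trace_update_idx));
}
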