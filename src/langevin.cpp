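#include <Rcpp.h>
using namespace Rcpp;

// dU/dz for the analytic potential forms; tabulated forms pass the derivative
// sampled on a uniform grid and interpolate linearly.
static inline double pot_deriv(double z, int form, const double* p,
                               const double* gz, const double* gf, int ng) {
  switch (form) {
  case 1: // harmonic: p = {k, center}
    return p[0] * (z - p[1]);
  case 2: { // double well: p = {h, a}
    double q = z / p[1];
    return 4.0 * p[0] * z * (q * q - 1.0) / (p[1] * p[1]);
  }
  case 3: { // translocation: p = {depth, interface_center, interface_width, plateau}
    double w = p[2];
    double t = (z - (p[1] - w)) / (2.0 * w);
    if (t <= 0.0 || t >= 1.0) return 0.0;
    return -p[0] * 6.0 * t * (1.0 - t) / (2.0 * w);
  }
  case 4: { // tabulated derivative on uniform grid, clamped at the ends
    if (ng < 2) return 0.0;
    double lo = gz[0], hi = gz[ng - 1];
    if (z <= lo) return gf[0];
    if (z >= hi) return gf[ng - 1];
    double h = (hi - lo) / (ng - 1);
    int i = (int)((z - lo) / h);
    if (i > ng - 2) i = ng - 2;
    double f = (z - (lo + i * h)) / h;
    return gf[i] * (1.0 - f) + gf[i + 1] * f;
  }
  }
  return 0.0;
}

// Overdamped Euler-Maruyama integrator:
//   z <- z - beta * D * U'(z) * dt + sqrt(2 D dt) * xi,  xi ~ N(0, 1)
// with U = potential + optional harmonic bias. Records every `stride`-th
// position after `burn_in` steps. Uses R's RNG, so set.seed() in R fixes the
// trajectory.
// [[Rcpp::export]]
NumericVector langevin_core(double z0, int n_steps, int burn_in, int stride,
                            double dt, double diffusion, double beta,
                            int form, NumericVector pars,
                            NumericVector grid_z, NumericVector grid_f,
                            double bias_center, double bias_k,
                            double lower, double upper) {
  if (n_steps <= 0) stop("n_steps must be positive");
  if (stride <= 0) stop("stride must be positive");
  if (burn_in < 0 || burn_in >= n_steps) stop("burn_in must lie in [0, n_steps)");
  const int n_out = (n_steps - burn_in) / stride;
  NumericVector out(n_out);
  const double drift = beta * diffusion * dt;
  const double noise = std::sqrt(2.0 * diffusion * dt);
  const double* p = pars.begin();
  const double* gz = grid_z.begin();
  const double* gf = grid_f.begin();
  const int ng = grid_z.size();

  RNGScope scope;
  double z = z0;
  int k = 0;
  for (int step = 1; step <= n_steps; ++step) {
    double f = pot_deriv(z, form, p, gz, gf, ng);
    if (bias_k > 0.0) f += bias_k * (z - bias_center);
    z += -drift * f + noise * norm_rand();
    if (!std::isfinite(z) || z < lower || z > upper) {
      stop("position %g escaped domain [%g, %g] at step %d", z, lower, upper, step);
    }
    if (step > burn_in && (step - burn_in) % stride == 0 && k < n_out) {
      out[k++] = z;
    }
  }
  return out;
}
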