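#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation on a uniform grid, clamped at the ends.
static inline double lin_interp(const double* y, double z0, double dz,
                                int n, double z) {
  double u = (z - z0) / dz;
  if (u <= 0.0) return y[0];
  if (u >= n - 1) return y[n - 1];
  int i = static_cast<int>(u);
  double w = u - i;
  return y[i] * (1.0 - w) + y[i + 1] * w;
}

// Euler-Maruyama integration of overdamped Langevin dynamics on a 1-D
// landscape under an optional harmonic umbrella bias:
//   dz = beta*D(z)*F(z)*dt + D'(z)*dt + sqrt(2*D(z)*dt)*dW
// F(z) = -dG/dz - kf*(z - center).  The D'(z) term is the spurious drift
// required with position-dependent diffusion so that the stationary
// density remains proportional to exp(-beta*G).
//
// grid_z must be uniformly spaced; f_land holds -dG/dz on that grid and
// dprime holds dD/dz.  Positions are recorded every save_every steps.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".simulate_overdamped_cpp")]]
NumericVector simulate_overdamped_cpp(double z0, double center, double kf,
                                      double beta, double dt, double n_steps_d,
                                      int save_every, NumericVector grid_z,
                                      NumericVector f_land, NumericVector dvals,
                                      NumericVector dprime, double z_lo,
                                      double z_hi, bool spurious_drift) {
  const int n = grid_z.size();
  const double g0 = grid_z[0];
  const double dzg = grid_z[1] - grid_z[0];
  const double* fl = f_land.begin();
  const double* dv = dvals.begin();
  const double* dp = dprime.begin();
  const R_xlen_t n_steps = static_cast<R_xlen_t>(n_steps_d);
  const R_xlen_t n_save = n_steps / save_every;
  NumericVector out(n_save);

  double z = z0;
  R_xlen_t k = 0;
  RNGScope scope;
  for (R_xlen_t s = 1; s <= n_steps; ++s) {
    const double D = lin_interp(dv, g0, dzg, n, z);
    const double F = lin_interp(fl, g0, dzg, n, z) - kf * (z - center);
    double drift = beta * D * F * dt;
    if (spurious_drift) drift += lin_interp(dp, g0, dzg, n, z) * dt;
    z += drift + std::sqrt(2.0 * D * dt) * norm_rand();
    if (z < z_lo - 1.0 || z > z_hi + 1.0)
      stop("trajectory left the landscape range (z = %.3f nm at step %td); "
           "decrease dt or check the landscape",
           z, s);
    if (s % save_every == 0) out[k++] = z;
  }
  return out;
}
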