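#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of a potential tabulated on a regular grid.
// Positions outside [zlo, zlo + (n-1)*dz] are treated as +infinity,
// i.e. proposals there are rejected (reflecting support boundaries).
static inline double interp_u(const NumericVector &u, double zlo, double dz,
                              double z, bool &ok) {
  double x = (z - zlo) / dz;
  if (x < 0.0 || x > u.size() - 1.0) { ok = false; return 0.0; }
  ok = true;
  int i = (int)x;
  if (i >= u.size() - 1) i = u.size() - 2;
  double f = x - i;
  return u[i] * (1.0 - f) + u[i + 1] * f;
}

// Random-walk Metropolis on the biased potential. Uses R's RNG so the
// chain is reproducible from set.seed() on the R side.
// [[Rcpp::export(rng = true)]]
NumericVector metropolis_chain(NumericVector u, double zlo, double dz,
                               double kT, double z0, int n_steps,
                               double proposal_sd) {
  NumericVector out(n_steps);
  double z = z0;
  bool ok = true;
  double uz = interp_u(u, zlo, dz, z, ok);
  if (!ok) stop("Initial position outside the tabulated support.");
  for (int s = 0; s < n_steps; ++s) {
    double zp = z + R::norm_rand() * proposal_sd;
    bool okp = true;
    double up = interp_u(u, zlo, dz, zp, okp);
    if (okp) {
      double dU = up - uz;
      if (dU <= 0.0 || R::unif_rand() < std::exp(-dU / kT)) {
        z = zp;
        uz = up;
      }
    }
    out[s] = z;
  }
  return out;
}

// Overdamped Langevin (Euler-Maruyama) on the same tabulated potential,
// force from central differences.  Returns the chain, or stops with a
// stability diagnostic when the drift per step exceeds drift_max.
// [[Rcpp::export(rng = true)]]
NumericVector langevin_chain(NumericVector u, double zlo, double dz,
                             double kT, double z0, int n_steps,
                             double D, double dt, double drift_max) {
  NumericVector out(n_steps);
  double z = z0;
  double noise_sd = std::sqrt(2.0 * D * dt);
  double zhi = zlo + dz * (u.size() - 1);
  for (int s = 0; s < n_steps; ++s) {
    bool ok1 = true, ok2 = true;
    double up = interp_u(u, zlo, dz, z + dz, ok1);
    double um = interp_u(u, zlo, dz, z - dz, ok2);
    double force;
    if (ok1 && ok2) force = -(up - um) / (2.0 * dz);
    else if (ok1) force = -(up - interp_u(u, zlo, dz, z, ok2)) / dz;
    else {
      bool okz = true;
      force = -(interp_u(u, zlo, dz, z, okz) - um) / dz;
    }
    double drift = D / kT * force * dt;
    if (std::fabs(drift) > drift_max) {
      stop("Langevin step unstable (|drift| = %.3g nm). Reduce dt to about %.3g.",
           std::fabs(drift), dt * drift_max / std::fabs(drift) * 0.5);
    }
    double zn = z + drift + noise_sd * R::norm_rand();
    if (zn < zlo) zn = 2.0 * zlo - zn;        // reflect at support edges
    if (zn > zhi) zn = 2.0 * zhi - zn;
    if (zn >= zlo && zn <= zhi) z = zn;
    out[s] = z;
  }
  return out;
}
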