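#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Brownian dynamics on a tabulated force field.
//
// Position update: z <- z + (D/kT) F(z) dt + N(0, sqrt(2 D dt)),
// with the energy tabulated in kT so (D/kT) F = D * f, f = -dG/dz in 1/nm.
// Force between grid points by linear interpolation, clamped at the ends.
// Lower boundary reflects; upper boundary absorbs (trajectory ends) or
// reflects. Uses R's RNG, so set.seed() gives bit-reproducible paths.
//
// [[Rcpp::export(name = ".bdCore")]]
List bdCore(NumericVector zgrid, NumericVector force, double z0,
            double D, double dt, double zmin, double zmax,
            bool absorbing, int nsteps, int thin) {
  const int ng = zgrid.size();
  const double g0 = zgrid[0], g1 = zgrid[ng - 1];
  const double dg = (g1 - g0) / (ng - 1);
  const double sd = std::sqrt(2.0 * D * dt);

  int nout = nsteps / thin + 1;
  NumericVector out(nout);
  double z = z0;
  out[0] = z;
  int nkept = 1;
  bool escaped = false;
  int steps_run = 0;

  for (int i = 1; i <= nsteps; ++i) {
    // linear interpolation of the force (uniform grid)
    double u = (z - g0) / dg;
    if (u < 0) u = 0;
    if (u > ng - 1) u = ng - 1;
    int k = (int)u;
    if (k > ng - 2) k = ng - 2;
    double w = u - k;
    double f = force[k] * (1.0 - w) + force[k + 1] * w;

    z += D * f * dt + R::rnorm(0.0, sd);

    if (z < zmin) z = 2.0 * zmin - z;           // reflect
    if (z > zmax) {
      if (absorbing) { escaped = true; steps_run = i; break; }
      z = 2.0 * zmax - z;
    }
    if (z < zmin) z = zmin;                     // double bounce guard
    if (z > zmax) z = zmax;

    if (i % thin == 0 && nkept < nout) out[nkept++] = z;
    steps_run = i;
  }

  return List::create(_["z"] = out[Range(0, nkept - 1)],
                      _["escaped"] = escaped,
                      _["steps"] = steps_run);
}
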