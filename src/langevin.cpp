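#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) on a cubic-gradient (quartic)
// potential, optionally with an adaptive kernel bias deposited on a grid.
// Kernel heights attenuate by the well-tempered factor
// exp(-V(x) * wt_fac), wt_fac = 1 / ((gamma - 1) kBT); wt_fac = 0 keeps
// heights constant (the standard-metadynamics limit). Walls at the grid
// edges are reflective. Uses R's RNG, so runs are reproducible under
// set.seed().

// [[Rcpp::export]]
List sim_langevin_cpp(double x0, double n_steps, double dt, double mu,
                      double kBT, NumericVector gcoef, int sample_stride,
                      bool use_bias, double wt_fac, double height0,
                      double bw, int dep_stride, double grid_min,
                      double grid_dx, NumericVector grid_v,
                      double reflect_min, double reflect_max) {
  const long ns = (long) n_steps;
  const int ng = grid_v.size();
  std::vector<double> v(grid_v.begin(), grid_v.end());
  std::vector<double> samples;
  samples.reserve(ns / sample_stride + 1);
  std::vector<double> centers, heights;
  const double noise = std::sqrt(2.0 * mu * kBT * dt);
  const double g0 = gcoef[0], g1 = gcoef[1], g2 = gcoef[2], g3 = gcoef[3];
  const double inv_2bw2 = 1.0 / (2.0 * bw * bw);
  double x = x0;
  bool diverged = false;

  for (long i = 1; i <= ns; ++i) {
    double force = -(g0 + x * (g1 + x * (g2 + x * g3)));
    if (use_bias) {
      double u = (x - grid_min) / grid_dx;
      int j = (int) u;
      if (j < 0) j = 0;
      if (j > ng - 2) j = ng - 2;
      force += -(v[j + 1] - v[j]) / grid_dx;
    }
    x += mu * force * dt + noise * norm_rand();
    if (!std::isfinite(x)) { diverged = true; break; }
    // reflective walls
    int guard = 0;
    while ((x < reflect_min || x > reflect_max) && guard++ < 64) {
      if (x < reflect_min) x = 2.0 * reflect_min - x;
      if (x > reflect_max) x = 2.0 * reflect_max - x;
    }
    if (guard >= 64) { diverged = true; break; }

    if (use_bias && (i % dep_stride == 0)) {
      double u = (x - grid_min) / grid_dx;
      int j = (int) u;
      if (j < 0) j = 0;
      if (j > ng - 2) j = ng - 2;
      double frac = u - j;
      double vx = v[j] * (1.0 - frac) + v[j + 1] * frac;
      double h = height0 * std::exp(-vx * wt_fac);
      for (int g = 0; g < ng; ++g) {
        double dxg = grid_min + g * grid_dx - x;
        v[g] += h * std::exp(-dxg * dxg * inv_2bw2);
      }
      centers.push_back(x);
      heights.push_back(h);
    }
    if (i % sample_stride == 0) samples.push_back(x);
  }
  return List::create(
    _["samples"] = NumericVector(samples.begin(), samples.end()),
    _["kernel_centers"] = NumericVector(centers.begin(), centers.end()),
    _["kernel_heights"] = NumericVector(heights.begin(), heights.end()),
    _["grid_v"] = NumericVector(v.begin(), v.end()),
    _["x_final"] = x,
    _["diverged"] = diverged);
}
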