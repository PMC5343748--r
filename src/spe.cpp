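#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// splitmix64: small, fast, platform-stable generator for reproducible
// embeddings independent of R's RNG state
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() {  // uniform in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return (int)(unif() * n); }
};

// Stochastic proximity embedding against interval distance constraints.
// Coordinates start uniformly random in a cube; for C cycles of S steps,
// each step draws n_updates random constraints and, when the current
// distance violates [lower, upper], moves both points along their
// difference vector by lambda/2 * (target - d)/(d + eps) toward the
// nearest violated bound. Lambda decays linearly across cycles
// (simulated-annealing-like schedule).
// [[Rcpp::export]]
NumericMatrix spe_embed_cpp(IntegerVector ci, IntegerVector cj,
                            NumericVector lower, NumericVector upper,
                            int n_atoms, int cycles, int steps,
                            int n_updates, double lambda_start,
                            double lambda_end, double box_side,
                            double seed) {
  const int nc = ci.size();
  if (nc == 0) stop("empty constraint set");
  SplitMix rng((uint64_t)seed);
  std::vector<double> x(3 * n_atoms);
  for (int i = 0; i < 3 * n_atoms; ++i)
    x[i] = (rng.unif() - 0.5) * box_side;
  // pack constraints for cache-friendly random access
  struct Con { int i3, j3; double lo, hi; };
  std::vector<Con> cons(nc);
  for (int k = 0; k < nc; ++k)
    cons[k] = Con{3 * ci[k], 3 * cj[k], lower[k], upper[k]};
  const double eps = 1e-9;
  double *px = x.data();
  const Con *pc = cons.data();
  for (int c = 0; c < cycles; ++c) {
    double lambda = lambda_start;
    if (cycles > 1)
      lambda += (lambda_end - lambda_start) * ((double)c / (cycles - 1));
    const long total = (long)steps * n_updates;
    for (long s = 0; s < total; ++s) {
      const Con &cn = pc[(size_t)(rng.unif() * nc)];
      double *xi = px + cn.i3, *xj = px + cn.j3;
      double dx = xi[0] - xj[0];
      double dy = xi[1] - xj[1];
      double dz = xi[2] - xj[2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 >= cn.lo * cn.lo && d2 <= cn.hi * cn.hi)
        continue;  // satisfied constraints are not touched
      double d = std::sqrt(d2);
      double target = (d < cn.lo) ? cn.lo : cn.hi;
      double f = lambda * 0.5 * (target - d) / (d + eps);
      xi[0] += f * dx; xi[1] += f * dy; xi[2] += f * dz;
      xj[0] -= f * dx; xj[1] -= f * dy; xj[2] -= f * dz;
    }
  }
  NumericMatrix out(n_atoms, 3);
  for (int i = 0; i < n_atoms; ++i) {
    out(i, 0) = x[3*i]; out(i, 1) = x[3*i+1]; out(i, 2) = x[3*i+2];
  }
  return out;
}

// Sum of squared constraint violations; zero iff every constraint holds.
// [[Rcpp::export]]
double error_score_cpp(NumericMatrix coords, IntegerVector ci,
                       IntegerVector cj, NumericVector lower,
                       NumericVector upper) {
  double s = 0;
  for (int k = 0; k < ci.size(); ++k) {
    int i = ci[k], j = cj[k];
    double dx = coords(i,0) - coords(j,0);
    double dy = coords(i,1) - coords(j,1);
    double dz = coords(i,2) - coords(j,2);
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    double v = 0;
    if (d < lower[k]) v = lower[k] - d;
    else if (d > upper[k]) v = d - upper[k];
    s += v * v;
  }
  return s;
}
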