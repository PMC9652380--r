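#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Deterministic, R-independent RNG (xorshift128+ seeded via splitmix64) so
// that the stochastic layout optimization is reproducible from an integer
// seed regardless of R's RNG state.
namespace {

struct Xorshift {
  uint64_t s0, s1;
  explicit Xorshift(uint64_t seed) {
    uint64_t z = seed;
    s0 = splitmix(z);
    s1 = splitmix(z);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }
  static uint64_t splitmix(uint64_t &z) {
    z += 0x9E3779B97F4A7C15ULL;
    uint64_t t = z;
    t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
    t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
    return t ^ (t >> 31);
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  int randint(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double clip4(double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

}  // namespace

// Stochastic gradient optimization of a 2-D layout under the smooth
// attractive/repulsive curve 1 / (1 + a * d^(2b)), with negative sampling.
// Edges are undirected; both endpoints are moved on attraction.
// [[Rcpp::export(name = ".umap_optimize_layout")]]
NumericMatrix umap_optimize_layout(NumericMatrix init,
                                   IntegerVector head,
                                   IntegerVector tail,
                                   NumericVector epochs_per_sample,
                                   double a, double b, double gamma,
                                   double initial_alpha,
                                   int negative_sample_rate,
                                   int n_epochs,
                                   double seed) {
  NumericMatrix emb = clone(init);
  const int n = emb.nrow();
  const int n_edges = head.size();

  std::vector<double> next_sample(epochs_per_sample.begin(), epochs_per_sample.end());
  std::vector<double> eps_neg(n_edges), next_neg(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    eps_neg[e] = epochs_per_sample[e] / negative_sample_rate;
    next_neg[e] = eps_neg[e];
  }

  Xorshift rng(static_cast<uint64_t>(seed));

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double alpha = initial_alpha * (1.0 - (epoch - 1.0) / n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (next_sample[e] > epoch) continue;
      const int i = head[e], j = tail[e];

      double dx = emb(i, 0) - emb(j, 0);
      double dy = emb(i, 1) - emb(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 > 0.0) {
        double gc = (-2.0 * a * b * std::pow(d2, b - 1.0)) /
                    (a * std::pow(d2, b) + 1.0);
        double gx = clip4(gc * dx), gy = clip4(gc * dy);
        emb(i, 0) += alpha * gx;
        emb(i, 1) += alpha * gy;
        emb(j, 0) -= alpha * gx;
        emb(j, 1) -= alpha * gy;
      }
      next_sample[e] += epochs_per_sample[e];

      int n_neg = static_cast<int>((epoch - next_neg[e]) / eps_neg[e]);
      for (int p = 0; p < n_neg; ++p) {
        const int k = rng.randint(n);
        if (k == i) continue;
        double ndx = emb(i, 0) - emb(k, 0);
        double ndy = emb(i, 1) - emb(k, 1);
        double nd2 = ndx * ndx + ndy * ndy;
        if (nd2 <= 0.0) {
          emb(i, 0) += alpha * 4.0;  // coincident points: push apart
          continue;
        }
        double gc = (2.0 * gamma * b) /
                    ((0.001 + nd2) * (a * std::pow(nd2, b) + 1.0));
        emb(i, 0) += alpha * clip4(gc * ndx);
        emb(i, 1) += alpha * clip4(gc * ndy);
      }
      next_neg[e] += n_neg * eps_neg[e];
    }
  }
  return emb;
}
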