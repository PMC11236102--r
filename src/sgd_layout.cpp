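// Stochastic gradient layout of the fuzzy graph: edge sampling proportional
// to weight, uniform non-neighbor negative sampling, linearly decaying
// learning rate, per-component gradient clipping at +/-4.  A self-contained
// xorshift RNG keeps results deterministic for a given integer seed.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xorshift128p {
  uint64_t s0, s1;
  explicit Xorshift128p(uint64_t seed) {
    // splitmix64 seeding
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto next = [&z]() {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      return x ^ (x >> 31);
    };
    s0 = next();
    s1 = next();
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform integer in [0, n)
  int uniform_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double clip4(double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

inline bool is_neighbor(const IntegerVector& ptr, const IntegerVector& idx,
                        int i, int j) {
  int lo = ptr[i], hi = ptr[i + 1] - 1;
  while (lo <= hi) {  // idx is sorted within each row
    int mid = (lo + hi) / 2;
    if (idx[mid] == j) return true;
    if (idx[mid] < j) lo = mid + 1; else hi = mid - 1;
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sgd_layout(NumericMatrix init, IntegerVector head,
                         IntegerVector tail, NumericVector epochs_per_sample,
                         IntegerVector nbr_ptr, IntegerVector nbr_idx,
                         double a, double b, double alpha, int n_epochs,
                         int negative_samples, double gamma, int seed) {
  const int n = init.nrow();
  const int d = init.ncol();
  const int n_edges = head.size();
  NumericMatrix coords = clone(init);
  Xorshift128p rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> next_sample(n_edges);
  for (int e = 0; e < n_edges; ++e) next_sample[e] = epochs_per_sample[e];

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double lr = alpha * (1.0 - static_cast<double>(epoch - 1) / n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (next_sample[e] > epoch) continue;
      const int i = head[e];
      const int j = tail[e];

      // attractive update along the sampled edge; both endpoints move
      double d2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = coords(i, c) - coords(j, c);
        d2 += diff * diff;
      }
      if (d2 > 0.0) {
        const double pd = std::pow(d2, b - 1.0);
        const double grad_coeff = (-2.0 * a * b * pd) / (a * pd * d2 + 1.0);
        for (int c = 0; c < d; ++c) {
          const double g = clip4(grad_coeff * (coords(i, c) - coords(j, c)));
          coords(i, c) += lr * g;
          coords(j, c) -= lr * g;
        }
      }

      // repulsive updates against uniform non-neighbors of i
      for (int s = 0; s < negative_samples; ++s) {
        int v = -1;
        for (int attempt = 0; attempt < 8; ++attempt) {
          const int cand = rng.uniform_int(n);
          if (cand == i) continue;
          if (is_neighbor(nbr_ptr, nbr_idx, i, cand)) continue;
          v = cand;
          break;
        }
        if (v < 0) continue;
        double r2 = 0.0;
        for (int c = 0; c < d; ++c) {
          const double diff = coords(i, c) - coords(v, c);
          r2 += diff * diff;
        }
        if (r2 > 0.0) {
          const double grad_coeff =
              (2.0 * gamma * b) / ((0.001 + r2) * (a * std::pow(r2, b) + 1.0));
          for (int c = 0; c < d; ++c) {
            coords(i, c) += lr * clip4(grad_coeff * (coords(i, c) - coords(v, c)));
          }
        } else {
          // coincident points: push apart by the clip bound
          coords(i, 0) += lr * 4.0;
        }
      }
      next_sample[e] += epochs_per_sample[e];
    }
  }
  return coords;
}
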