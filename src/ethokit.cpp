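#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic xorshift64* stream, independent of R's RNG so that the
// embedding is reproducible from an explicit integer seed alone.
static inline uint64_t xorshift_next(uint64_t &s) {
  s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
  return s * 2685821657736338717ULL;
}
static inline double unif01(uint64_t &s) {
  return (xorshift_next(s) >> 11) * (1.0 / 9007199254740992.0);
}
static inline int unif_int(uint64_t &s, int n) {
  int k = (int)(unif01(s) * n);
  return k >= n ? n - 1 : k;
}

// Exact k-nearest neighbours of each row of `query` among rows of `ref`
// (euclidean). If skip_self, query and ref are the same set and the match
// with identical row index is excluded. Returns 1-based indices and
// distances, each row sorted by increasing distance.
// [[Rcpp::export]]
List knn_exact_cpp(NumericMatrix query, NumericMatrix ref, int k, bool skip_self) {
  const int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("dimension mismatch between query and reference");
  if (k < 1) stop("k must be >= 1");
  const int kk = std::min(k, skip_self ? nr - 1 : nr);
  IntegerMatrix idx(nq, kk);
  NumericMatrix dist(nq, kk);
  // contiguous row-major copies so the inner distance loop streams memory
  std::vector<double> Q((size_t)nq * d), R((size_t)nr * d);
  for (int i = 0; i < nq; ++i)
    for (int c = 0; c < d; ++c) Q[(size_t)i * d + c] = query(i, c);
  for (int j = 0; j < nr; ++j)
    for (int c = 0; c < d; ++c) R[(size_t)j * d + c] = ref(j, c);
  for (int i = 0; i < nq; ++i) {
    const double *q = &Q[(size_t)i * d];
    // max-heap of (distance, index) keeping the kk smallest
    std::priority_queue<std::pair<double, int> > heap;
    double worst = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nr; ++j) {
      if (skip_self && j == i) continue;
      const double *r = &R[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) { double t = r[c] - q[c]; s += t * t; }
      if ((int)heap.size() < kk) {
        heap.push(std::make_pair(s, j));
        if ((int)heap.size() == kk) worst = heap.top().first;
      } else if (s < worst) {
        heap.pop(); heap.push(std::make_pair(s, j));
        worst = heap.top().first;
      }
    }
    for (int m = (int)heap.size() - 1; m >= 0; --m) {
      idx(i, m) = heap.top().second + 1;
      dist(i, m) = std::sqrt(heap.top().first);
      heap.pop();
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Per-row calibration of the local kernel widths used to convert kNN
// distances into membership weights: rho_i is the distance to the nearest
// neighbour and sigma_i solves sum_j exp(-(d_ij - rho_i)+ / sigma_i) = target
// by bisection. Returns the weight matrix.
// [[Rcpp::export]]
NumericMatrix smooth_knn_cpp(NumericMatrix dist, double target) {
  const int n = dist.nrow(), k = dist.ncol();
  NumericMatrix w(n, k);
  for (int i = 0; i < n; ++i) {
    double rho = dist(i, 0);
    double lo = 0.0, hi = std::numeric_limits<double>::infinity(), mid = 1.0;
    for (int it = 0; it < 64; ++it) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        double x = dist(i, j) - rho;
        s += x <= 0 ? 1.0 : std::exp(-x / mid);
      }
      if (std::fabs(s - target) < 1e-5) break;
      if (s > target) { hi = mid; mid = (lo + hi) / 2.0; }
      else { lo = mid; mid = std::isinf(hi) ? mid * 2.0 : (lo + hi) / 2.0; }
    }
    for (int j = 0; j < k; ++j) {
      double x = dist(i, j) - rho;
      w(i, j) = x <= 0 ? 1.0 : std::exp(-x / mid);
    }
  }
  return w;
}

static inline double clip4(double x) {
  return x > 4.0 ? 4.0 : (x < -4.0 ? -4.0 : x);
}

// Stochastic gradient layout of the fuzzy neighbourhood graph in 2-D,
// with edge sampling proportional to membership weight and uniform negative
// sampling. head/tail are 0-based endpoint indices; epochs_per_sample is
// max(w)/w per edge. Modifies a copy of `init` and returns it.
// [[Rcpp::export]]
NumericMatrix layout_sgd_cpp(NumericMatrix init, IntegerVector head, IntegerVector tail,
                             NumericVector epochs_per_sample, int n_epochs,
                             double a, double b, double gamma, double alpha0,
                             int negative_rate, double seed) {
  NumericMatrix emb = clone(init);
  const int n = emb.nrow();
  const int ne = head.size();
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  xorshift_next(rng);
  std::vector<double> next_sample(ne), next_neg(ne), eps_neg(ne);
  for (int e = 0; e < ne; ++e) {
    next_sample[e] = epochs_per_sample[e];
    eps_neg[e] = epochs_per_sample[e] / negative_rate;
    next_neg[e] = eps_neg[e];
  }
  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    double alpha = alpha0 * (1.0 - (double)(epoch - 1) / n_epochs);
    for (int e = 0; e < ne; ++e) {
      if (next_sample[e] > epoch) continue;
      int i = head[e], j = tail[e];
      double dx = emb(i, 0) - emb(j, 0), dy = emb(i, 1) - emb(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 > 0.0) {
        double coef = (-2.0 * a * b * std::pow(d2, b - 1.0)) / (a * std::pow(d2, b) + 1.0);
        double gx = clip4(coef * dx), gy = clip4(coef * dy);
        emb(i, 0) += alpha * gx; emb(i, 1) += alpha * gy;
        emb(j, 0) -= alpha * gx; emb(j, 1) -= alpha * gy;
      }
      next_sample[e] += epochs_per_sample[e];
      int n_neg = (int)((epoch - next_neg[e]) / eps_neg[e]) + 1;
      for (int p = 0; p < n_neg; ++p) {
        int m = unif_int(rng, n);
        if (m == i) continue;
        double ddx = emb(i, 0) - emb(m, 0), ddy = emb(i, 1) - emb(m, 1);
        double dd2 = ddx * ddx + ddy * ddy;
        double coef;
        if (dd2 > 0.0) coef = (2.0 * gamma * b) / ((0.001 + dd2) * (a * std::pow(dd2, b) + 1.0));
        else continue;
        emb(i, 0) += alpha * clip4(coef * ddx);
        emb(i, 1) += alpha * clip4(coef * ddy);
      }
      next_neg[e] += n_neg * eps_neg[e];
    }
  }
  return emb;
}
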