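// Co-occurrence accumulation and AdaGrad log-bilinear training.
//
// Determinism: all randomness (vector initialization, per-epoch entry
// shuffling) comes from a self-contained splitmix64 stream seeded from R,
// so identical seeds give bitwise-identical models on a given platform.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

}  // namespace

// Accumulate symmetric window co-occurrences over documents.
// docs: list of integer vectors of 0-based token ids (-1 = skip).
// Returns triplets with 1-based i <= j, sorted by (i, j).
// [[Rcpp::export(name = ".cpp_build_cooccurrence")]]
List cpp_build_cooccurrence(List docs, int window, bool inverse_distance) {
  if (window < 1) stop("window must be >= 1");
  std::unordered_map<uint64_t, double> acc;
  acc.reserve(1 << 16);
  for (R_xlen_t d = 0; d < docs.size(); ++d) {
    IntegerVector ids = docs[d];
    int n = ids.size();
    for (int a = 0; a < n; ++a) {
      if (ids[a] < 0) continue;
      int bmax = std::min(n - 1, a + window);
      for (int b = a + 1; b <= bmax; ++b) {
        if (ids[b] < 0) continue;
        double w = inverse_distance ? 1.0 / (b - a) : 1.0;
        uint64_t lo = std::min(ids[a], ids[b]);
        uint64_t hi = std::max(ids[a], ids[b]);
        acc[(lo << 32) | hi] += w;
      }
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(acc.size());
  for (auto& kv : acc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  R_xlen_t m = keys.size();
  IntegerVector out_i(m), out_j(m);
  NumericVector out_x(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    out_i[k] = static_cast<int>(keys[k] >> 32) + 1;
    out_j[k] = static_cast<int>(keys[k] & 0xffffffffULL) + 1;
    out_x[k] = acc[keys[k]];
  }
  return List::create(_["i"] = out_i, _["j"] = out_j, _["x"] = out_x);
}

// Train GloVe vectors with AdaGrad over shuffled nonzero entries.
// ti, tj: 1-based indices of every nonzero entry of the FULL symmetric
// matrix (both orders for off-diagonal entries); tx: weights.
// Returns main/context vectors (n_vocab x dim), biases, per-epoch loss.
// [[Rcpp::export(name = ".cpp_train_glove")]]
List cpp_train_glove(IntegerVector ti, IntegerVector tj, NumericVector tx,
                     int n_vocab, int dim, int epochs, double x_max,
                     double alpha, double eta, double seed) {
  if (dim < 1) stop("dim must be >= 1");
  if (epochs < 0) stop("epochs must be >= 0");
  R_xlen_t nnz = ti.size();

  SplitMix64 rng(static_cast<uint64_t>(seed));
  double init_scale = 0.5 / dim;

  NumericMatrix W(n_vocab, dim), C(n_vocab, dim);
  NumericVector b(n_vocab), bc(n_vocab);
  for (int v = 0; v < n_vocab; ++v) {
    for (int k = 0; k < dim; ++k) {
      W(v, k) = (rng.unif() - 0.5) * 2.0 * init_scale;
      C(v, k) = (rng.unif() - 0.5) * 2.0 * init_scale;
    }
    b[v] = (rng.unif() - 0.5) * 2.0 * init_scale;
    bc[v] = (rng.unif() - 0.5) * 2.0 * init_scale;
  }

  NumericMatrix gW(n_vocab, dim), gC(n_vocab, dim);
  NumericVector gb(n_vocab), gbc(n_vocab);
  std::fill(gW.begin(), gW.end(), 1.0);
  std::fill(gC.begin(), gC.end(), 1.0);
  std::fill(gb.begin(), gb.end(), 1.0);
  std::fill(gbc.begin(), gbc.end(), 1.0);

  std::vector<R_xlen_t> order(nnz);
  for (R_xlen_t k = 0; k < nnz; ++k) order[k] = k;

  NumericVector epoch_loss(epochs);
  std::vector<double> logx(nnz), fw(nnz);
  for (R_xlen_t k = 0; k < nnz; ++k) {
    logx[k] = std::log(tx[k]);
    fw[k] = tx[k] < x_max ? std::pow(tx[k] / x_max, alpha) : 1.0;
  }

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from the seeded stream
    for (R_xlen_t k = nnz - 1; k > 0; --k) {
      R_xlen_t r = static_cast<R_xlen_t>(rng.below(k + 1));
      std::swap(order[k], order[r]);
    }
    double total = 0.0;
    for (R_xlen_t q = 0; q < nnz; ++q) {
      R_xlen_t k = order[q];
      int i = ti[k] - 1, j = tj[k] - 1;
      double diff = b[i] + bc[j] - logx[k];
      for (int d = 0; d < dim; ++d) diff += W(i, d) * C(j, d);
      double fdiff = fw[k] * diff;
      total += 0.5 * fdiff * diff;
      for (int d = 0; d < dim; ++d) {
        double t1 = fdiff * C(j, d);
        double t2 = fdiff * W(i, d);
        W(i, d) -= eta * t1 / std::sqrt(gW(i, d));
        C(j, d) -= eta * t2 / std::sqrt(gC(j, d));
        gW(i, d) += t1 * t1;
        gC(j, d) += t2 * t2;
      }
      b[i] -= eta * fdiff / std::sqrt(gb[i]);
      bc[j] -= eta * fdiff / std::sqrt(gbc[j]);
      gb[i] += fdiff * fdiff;
      gbc[j] += fdiff * fdiff;
    }
    epoch_loss[ep] = nnz > 0 ? total / nnz : 0.0;
  }

  return List::create(_["W"] = W, _["C"] = C, _["b"] = b, _["b_ctx"] = bc,
                      _["epoch_loss"] = epoch_loss);
}
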