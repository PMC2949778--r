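#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// Self-contained splitmix64 stream so that training is bit-reproducible for a
// given seed regardless of R's RNG state.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint32_t seed) : s(seed ? seed : 0x9e3779b9u) {}
  uint64_t next() {
    s += 0x9e3779b97f4a7c15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

} // namespace

// Online (per-pattern) back-propagation of squared error with momentum for a
// single-hidden-layer perceptron with logistic activations on both layers.
// Weight init is uniform(-0.5, 0.5) from the seeded stream; pattern order is
// reshuffled every epoch when `shuffle` is true. Training stops early when the
// epoch-mean squared error drops below `tol` (tol <= 0 disables the stop).
// [[Rcpp::export]]
List cpp_train_mlp(const NumericMatrix& X, const IntegerVector& y, int hidden,
                   double lr, double momentum, int max_epochs, bool shuffle,
                   int seed, double tol) {
  const int n = X.nrow(), d = X.ncol(), h = hidden;
  SplitMix rng(static_cast<uint32_t>(seed));

  std::vector<double> W1(static_cast<size_t>(h) * d), b1(h), W2(h);
  double b2;
  for (int j = 0; j < h; ++j)
    for (int k = 0; k < d; ++k) W1[static_cast<size_t>(j) * d + k] = rng.unif() - 0.5;
  for (int j = 0; j < h; ++j) b1[j] = rng.unif() - 0.5;
  for (int j = 0; j < h; ++j) W2[j] = rng.unif() - 0.5;
  b2 = rng.unif() - 0.5;

  std::vector<double> vW1(W1.size(), 0.0), vb1(h, 0.0), vW2(h, 0.0);
  double vb2 = 0.0;
  std::vector<double> a1(h), dh(h);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> epoch_mse;
  epoch_mse.reserve(max_epochs);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    if (shuffle) {
      for (int i = n - 1; i > 0; --i) {
        int j = rng.below(i + 1);
        std::swap(order[i], order[j]);
      }
    }
    double sse = 0.0;
    for (int ii = 0; ii < n; ++ii) {
      const int i = order[ii];
      // forward
      for (int j = 0; j < h; ++j) {
        double z = b1[j];
        const double* w = &W1[static_cast<size_t>(j) * d];
        for (int k = 0; k < d; ++k) z += w[k] * X(i, k);
        a1[j] = sigmoid(z);
      }
      double zo = b2;
      for (int j = 0; j < h; ++j) zo += W2[j] * a1[j];
      const double out = sigmoid(zo);
      const double e = out - static_cast<double>(y[i]);
      sse += e * e;
      // backward
      const double dout = e * out * (1.0 - out);
      for (int j = 0; j < h; ++j) dh[j] = dout * W2[j] * a1[j] * (1.0 - a1[j]);
      // momentum updates
      vb2 = -lr * dout + momentum * vb2;
      b2 += vb2;
      for (int j = 0; j < h; ++j) {
        vW2[j] = -lr * dout * a1[j] + momentum * vW2[j];
        W2[j] += vW2[j];
        vb1[j] = -lr * dh[j] + momentum * vb1[j];
        b1[j] += vb1[j];
        double* w = &W1[static_cast<size_t>(j) * d];
        double* vw = &vW1[static_cast<size_t>(j) * d];
        for (int k = 0; k < d; ++k) {
          vw[k] = -lr * dh[j] * X(i, k) + momentum * vw[k];
          w[k] += vw[k];
        }
      }
    }
    epoch_mse.push_back(sse / n);
    if (tol > 0.0 && epoch_mse.back() < tol) break;
  }

  NumericMatrix W1out(h, d);
  for (int j = 0; j < h; ++j)
    for (int k = 0; k < d; ++k) W1out(j, k) = W1[static_cast<size_t>(j) * d + k];
  return List::create(_["W1"] = W1out, _["b1"] = NumericVector(b1.begin(), b1.end()),
                      _["W2"] = NumericVector(W2.begin(), W2.end()), _["b2"] = b2,
                      _["epoch_mse"] = NumericVector(epoch_mse.begin(), epoch_mse.end()));
}

// Forward pass returning sigmoid output scores in (0, 1).
// [[Rcpp::export]]
NumericVector cpp_mlp_scores(const NumericMatrix& X, const NumericMatrix& W1,
                             const NumericVector& b1, const NumericVector& W2,
                             double b2) {
  const int n = X.nrow(), d = X.ncol(), h = W1.nrow();
  NumericVector out(n);
  std::vector<double> a1(h);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < h; ++j) {
      double z = b1[j];
      for (int k = 0; k < d; ++k) z += W1(j, k) * X(i, k);
      a1[j] = sigmoid(z);
    }
    double zo = b2;
    for (int j = 0; j < h; ++j) zo += W2[j] * a1[j];
    out[i] = sigmoid(zo);
  }
  return out;
}
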