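#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Auto-Contractive Map training. For each record the input signal is
// contracted twice: once through the mono-connections v (input -> hidden) and
// once through the pairwise matrix W (hidden -> output). Weights grow with
// co-activation and are kept below the contraction constant C by the
// (1 - w/C) factors. Deterministic: zero initialization, fixed record order.
//
//   m_s(i)   = m_in(i) * (1 - v(i)/C)
//   Net(i)   = sum_j m_s(j) * (1 - W(j,i)/C)
//   m_out(i) = m_s(i) * (1 - Net(i)/C)
//   dv(i)    = alpha * (m_in(i) - m_s(i)) * (1 - v(i)/C)
//   dW(j,i)  = alpha * (m_s(i) - m_out(i)) * (1 - W(j,i)/C) * m_s(j)
//
// Training stops when the epoch-mean absolute weight change falls below tol.
// [[Rcpp::export]]
List cpp_train_autocm(const NumericMatrix& X, double C, double alpha,
                      double tol, int max_epochs) {
  const int n = X.nrow(), N = X.ncol();
  std::vector<double> v(N, 0.0);
  std::vector<double> W(static_cast<size_t>(N) * N, 0.0); // W[j*N + i] = W(j,i)
  std::vector<double> ms(N), net(N), mout(N);

  int epochs_run = 0;
  bool converged = false;
  const double n_params = static_cast<double>(N) + static_cast<double>(N) * N;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double total_change = 0.0;
    for (int r = 0; r < n; ++r) {
      for (int i = 0; i < N; ++i) ms[i] = X(r, i) * (1.0 - v[i] / C);
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int j = 0; j < N; ++j) s += ms[j] * (1.0 - W[static_cast<size_t>(j) * N + i] / C);
        net[i] = s;
        mout[i] = ms[i] * (1.0 - s / C);
      }
      for (int i = 0; i < N; ++i) {
        const double dv = alpha * (X(r, i) - ms[i]) * (1.0 - v[i] / C);
        v[i] += dv;
        total_change += std::fabs(dv);
      }
      for (int i = 0; i < N; ++i) {
        const double gi = alpha * (ms[i] - mout[i]);
        for (int j = 0; j < N; ++j) {
          double& w = W[static_cast<size_t>(j) * N + i];
          const double dw = gi * (1.0 - w / C) * ms[j];
          w += dw;
          total_change += std::fabs(dw);
        }
      }
    }
    ++epochs_run;
    if (total_change / (n * n_params) < tol) {
      converged = true;
      break;
    }
  }

  NumericMatrix Wout(N, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) Wout(j, i) = W[static_cast<size_t>(j) * N + i];
  return List::create(_["v"] = NumericVector(v.begin(), v.end()), _["W"] = Wout,
                      _["epochs_run"] = epochs_run, _["converged"] = converged);
}
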