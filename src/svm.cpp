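#include <Rcpp.h>
using namespace Rcpp;

// Linear L1-loss SVM trained by dual coordinate descent (Hsieh et al. 2008).
// A constant bias feature is appended by the caller, so X is n x d with the
// last column equal to 1. y must be +/-1. Deterministic cyclic sweeps keep
// refits reproducible without a random permutation.
// [[Rcpp::export(name = ".svm_dcd")]]
NumericVector svm_dcd(NumericMatrix X, NumericVector y, double C,
                      int max_epochs, double tol) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> alpha(n, 0.0), w(d, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0) continue;
      double g = -1.0;
      for (int j = 0; j < d; ++j) g += y[i] * X(i, j) * w[j];
      // projected gradient for box constraint 0 <= alpha <= C
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        double old = alpha[i];
        double a = std::min(std::max(old - g / qii[i], 0.0), C);
        alpha[i] = a;
        double delta = (a - old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
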