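// Greedy forward feature selection for a binary RBF-kernel SVM, scored by
// internal cross-validated accuracy. The inner solver is a compact SMO
// (maximal-violating-pair working-set selection, as in libsvm's C-SVC)
// because the greedy wrapper evaluates hundreds of candidate feature sets
// per model and fold; the final per-model SVMs are fit in R with e1071.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SmoResult {
  std::vector<double> alpha;
  double rho;
};

// Solve the C-SVC dual on the training subset. K is the full n x n kernel,
// tr the training row indices, yy labels +-1.
SmoResult smo_solve(const std::vector<double>& K, int n,
                    const std::vector<int>& tr,
                    const std::vector<double>& yy, double C) {
  const int m = tr.size();
  const double eps = 1e-3;
  std::vector<double> alpha(m, 0.0), G(m, -1.0);
  std::vector<double> y(m);
  for (int a = 0; a < m; ++a) y[a] = yy[tr[a]];
  auto Kat = [&](int a, int b) { return K[tr[a] + (size_t)n * tr[b]]; };

  const int max_iter = 10000;
  for (int it = 0; it < max_iter; ++it) {
    // working set: i = argmax_{I_up} -y G, j = argmin_{I_low} -y G
    int i = -1, j = -1;
    double Gmax = -1e30, Gmin = 1e30;
    for (int t = 0; t < m; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    double quad = Kat(i, i) + Kat(j, j) - 2.0 * y[i] * y[j] * Kat(i, j);
    if (quad <= 0) quad = 1e-12;
    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double dai = y[i] * (alpha[i] - old_ai), daj = y[j] * (alpha[j] - old_aj);
    for (int t = 0; t < m; ++t)
      G[t] += y[t] * (Kat(t, i) * dai + Kat(t, j) * daj);
  }

  // rho from free support vectors; fall back to the violation midpoint
  double r = 0; int nfree = 0;
  double ub = 1e30, lb = -1e30;
  for (int t = 0; t < m; ++t) {
    double yg = y[t] * G[t];
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { r += yg; ++nfree; }
    if (up) ub = std::min(ub, -yg);
    if (low) lb = std::max(lb, -yg);
  }
  SmoResult res;
  res.rho = nfree > 0 ? r / nfree : -(ub + lb) / 2.0;
  res.alpha.assign(m, 0.0);
  for (int a = 0; a < m; ++a) res.alpha[a] = alpha[a] * y[a];
  return res;
}

// Internal-CV accuracy of the RBF SVM on kernel K with fold assignment.
double cv_accuracy(const std::vector<double>& K, int n,
                   const std::vector<double>& y,
                   const IntegerVector& fold, int nfold, double C) {
  int correct = 0;
  std::vector<int> tr; tr.reserve(n);
  for (int f = 1; f <= nfold; ++f) {
    tr.clear();
    std::vector<int> te;
    for (int t = 0; t < n; ++t) (fold[t] == f ? te : tr).push_back(t);
    if (te.empty() || tr.empty()) continue;
    SmoResult fit = smo_solve(K, n, tr, y, C);
    for (int u : te) {
      double dec = -fit.rho;
      for (size_t a = 0; a < tr.size(); ++a)
        dec += fit.alpha[a] * K[u + (size_t)n * tr[a]];
      if ((dec >= 0 ? 1.0 : -1.0) == y[u]) ++correct;
    }
  }
  return (double)correct / n;
}

}  // namespace

List forward_select_smo(NumericMatrix X, IntegerVector y01, IntegerVector fold,
                        int n_features, double cost) {
  const int n = X.nrow(), p = X.ncol();
  if (n_features > p) stop("fewer candidate features than requested");
  int nfold = 0;
  for (int t = 0; t < n; ++t) nfold = std::max(nfold, fold[t]);
  std::vector<double> y(n);
  for (int t = 0; t < n; ++t) y[t] = y01[t] ? 1.0 : -1.0;

  // per-feature squared-difference matrices
  std::vector<std::vector<double> > D(p, std::vector<double>((size_t)n * n));
  for (int f = 0; f < p; ++f) {
    const double* col = &X(0, f);
    for (int b = 0; b < n; ++b)
      for (int a = 0; a < n; ++a) {
        double d = col[a] - col[b];
        D[f][a + (size_t)n * b] = d * d;
      }
  }

  std::vector<double> Dsel((size_t)n * n, 0.0), K((size_t)n * n);
  std::vector<bool> used(p, false);
  IntegerVector selected(n_features);
  NumericVector scores(n_features);

  for (int step = 0; step < n_features; ++step) {
    double gamma = 1.0 / (step + 1);
    int best = -1; double best_acc = -1.0;
    for (int f = 0; f < p; ++f) {
      if (used[f]) continue;
      for (size_t t = 0; t < K.size(); ++t)
        K[t] = std::exp(-gamma * (Dsel[t] + D[f][t]));
      double acc = cv_accuracy(K, n, y, fold, nfold, cost);
      if (acc > best_acc) { best_acc = acc; best = f; }
    }
    used[best] = true;
    selected[step] = best + 1;  // 1-based
    scores[step] = best_acc;
    for (size_t t = 0; t < Dsel.size(); ++t) Dsel[t] += D[best][t];
  }
  return List::create(_["selected"] = selected, _["scores"] = scores);
}
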