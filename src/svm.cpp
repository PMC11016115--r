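#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic SMO solver for the C-SVC dual with linear kernel
// (standard formulation with unregularized bias via the equality
// constraint, so libsvm/e1071 is a direct cross-check). Most-violating
// pair selection; first index wins ties, so runs are reproducible.
//
// Problem sizes here are tiny (one training fold is 2*(n_subjects-1)
// samples with <= 4 features); the point of the C++ path is the
// permutation loop, which refits the classifier millions of times.

namespace {

struct SvmModel {
  std::vector<double> w;
  double b;
};

// X: n x d row-major, y in {-1, +1}
SvmModel svmTrainLinear(const std::vector<double> &X, int n, int d,
                        const std::vector<double> &y, double C) {
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; i++)
    for (int j = i; j < n; j++) {
      double s = 0.0;
      for (int k = 0; k < d; k++)
        s += X[(size_t)i * d + k] * X[(size_t)j * d + k];
      K[(size_t)i * n + j] = s;
      K[(size_t)j * n + i] = s;
    }
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  const double eps = 1e-6;
  const int maxIter = 100000;
  double Gmax = 0.0, Gmin = 0.0;
  for (int iter = 0; iter < maxIter; iter++) {
    int i = -1, j = -1;
    Gmax = -1e300;
    Gmin = 1e300;
    for (int t = 0; t < n; t++) {
      const double v = -y[t] * grad[t];
      const bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool dn = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (dn && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;
    double a = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
               2.0 * K[(size_t)i * n + j];
    if (a <= 0.0) a = 1e-12;
    double t = (Gmax - Gmin) / a;
    // box constraints along the feasible direction
    // (alpha_i += y_i * t, alpha_j -= y_j * t)
    t = std::min(t, (y[i] > 0) ? (C - alpha[i]) : alpha[i]);
    t = std::min(t, (y[j] > 0) ? alpha[j] : (C - alpha[j]));
    if (t <= 0.0) break;
    alpha[i] += y[i] * t;
    alpha[j] -= y[j] * t;
    for (int k = 0; k < n; k++)
      grad[k] += y[k] * t * (K[(size_t)k * n + i] - K[(size_t)k * n + j]);
  }
  SvmModel m;
  m.w.assign(d, 0.0);
  for (int i = 0; i < n; i++) {
    const double c = alpha[i] * y[i];
    if (c != 0.0)
      for (int k = 0; k < d; k++) m.w[k] += c * X[(size_t)i * d + k];
  }
  // bias from free support vectors (KKT: -y*grad = y - w'x = b)
  double bsum = 0.0;
  int bn = 0;
  for (int i = 0; i < n; i++)
    if (alpha[i] > 1e-8 && alpha[i] < C - 1e-8) {
      bsum += -y[i] * grad[i];
      bn++;
    }
  m.b = bn ? bsum / bn : (Gmax + Gmin) / 2.0;
  return m;
}

// LOSO accuracy per time bin. X: n x d x nb (R array flattening:
// X[i + n*(k + d*b)]). Features standardized by training-fold mean/SD.
// Decision ties (exactly 0) predict +1, the first label.
void losoAccuracy(const double *X, int n, int d, int nb,
                  const std::vector<double> &y,
                  const std::vector<int> &subj, double C, double *acc) {
  int nsubj = 0;
  for (int i = 0; i < n; i++) nsubj = std::max(nsubj, subj[i] + 1);
  std::vector<double> Xtr((size_t)n * d), ytr(n), mu(d), sdv(d);
  std::vector<int> trainIdx(n), testIdx(n);
  for (int b = 0; b < nb; b++) {
    int correct = 0, total = 0;
    for (int held = 0; held < nsubj; held++) {
      int ntr = 0, nte = 0;
      for (int i = 0; i < n; i++)
        (subj[i] == held ? testIdx[nte++] : trainIdx[ntr++]) = i;
      if (nte == 0) continue;
      for (int k = 0; k < d; k++) {
        double s = 0.0;
        for (int t = 0; t < ntr; t++)
          s += X[trainIdx[t] + (size_t)n * (k + (size_t)d * b)];
        mu[k] = s / ntr;
        double v = 0.0;
        for (int t = 0; t < ntr; t++) {
          const double z =
              X[trainIdx[t] + (size_t)n * (k + (size_t)d * b)] - mu[k];
          v += z * z;
        }
        sdv[k] = (ntr > 1) ? std::sqrt(v / (ntr - 1)) : 0.0;
        if (sdv[k] < 1e-12) sdv[k] = 1.0;
      }
      for (int t = 0; t < ntr; t++) {
        ytr[t] = y[trainIdx[t]];
        for (int k = 0; k < d; k++)
          Xtr[(size_t)t * d + k] =
              (X[trainIdx[t] + (size_t)n * (k + (size_t)d * b)] - mu[k]) /
              sdv[k];
      }
      SvmModel m = svmTrainLinear(Xtr, ntr, d, ytr, C);
      for (int t = 0; t < nte; t++) {
        double f = m.b;
        for (int k = 0; k < d; k++)
          f += m.w[k] *
               ((X[testIdx[t] + (size_t)n * (k + (size_t)d * b)] - mu[k]) /
                sdv[k]);
        const double pred = (f < 0.0) ? -1.0 : 1.0;  // tie -> +1
        if (pred == y[testIdx[t]]) correct++;
        total++;
      }
    }
    acc[b] = total ? (double)correct / total : NA_REAL;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_svm_train(NumericMatrix X, NumericVector y, double C) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> Xr((size_t)n * d), yv(n);
  for (int i = 0; i < n; i++) {
    yv[i] = y[i];
    for (int k = 0; k < d; k++) Xr[(size_t)i * d + k] = X(i, k);
  }
  SvmModel m = svmTrainLinear(Xr, n, d, yv, C);
  return List::create(_["w"] = NumericVector(m.w.begin(), m.w.end()),
                      _["b"] = m.b);
}

// [[Rcpp::export]]
NumericVector cpp_loso_accuracy(NumericVector X, NumericVector y,
                                IntegerVector subj0, double C) {
  IntegerVector dims = X.attr("dim");
  const int n = dims[0], d = dims[1], nb = dims[2];
  std::vector<double> yv(y.begin(), y.end());
  std::vector<int> sv(subj0.begin(), subj0.end());
  NumericVector acc(nb);
  losoAccuracy(REAL(X), n, d, nb, yv, sv, C, REAL(acc));
  return acc;
}

// flips: nperm x nsubj 0/1 matrix; permutation p flips the label pair of
// subject s iff flips(p, s) == 1 (paired-design shuffle)
// [[Rcpp::export]]
NumericMatrix cpp_loso_perm(NumericVector X, NumericVector y,
                            IntegerVector subj0, IntegerMatrix flips,
                            double C) {
  IntegerVector dims = X.attr("dim");
  const int n = dims[0], d = dims[1], nb = dims[2];
  const int nperm = flips.nrow();
  std::vector<double> yv(n);
  std::vector<int> sv(subj0.begin(), subj0.end());
  NumericMatrix out(nperm, nb);
  std::vector<double> acc(nb);
  for (int p = 0; p < nperm; p++) {
    for (int i = 0; i < n; i++)
      yv[i] = flips(p, sv[i]) ? -y[i] : y[i];
    losoAccuracy(REAL(X), n, d, nb, yv, sv, C, acc.data());
    for (int b = 0; b < nb; b++) out(p, b) = acc[b];
  }
  return out;
}
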