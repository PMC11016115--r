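#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Complex Morlet power sampled at stepped bin centers.
//
// data: trials x channels x samples array (flattened, R order)
// sigmas: Gaussian envelope SD (s) per frequency; wavelets are truncated
//   at +/- 3 sigma and gain-normalized (coefficients divided by the
//   envelope sum), so a unit-amplitude sinusoid at the wavelet frequency
//   yields power ~ 1/4 independent of frequency.
// centers0: 0-based sample indices of the bin centers.
// Bins whose wavelet support overruns the epoch stay NA.
// [[Rcpp::export]]
NumericVector cpp_morlet_power(NumericVector data, double fs,
                               NumericVector freqs, NumericVector sigmas,
                               IntegerVector centers0) {
  IntegerVector dims = data.attr("dim");
  const int ntr = dims[0], nch = dims[1], ns = dims[2];
  const int nf = freqs.size(), nb = centers0.size();

  std::vector< std::vector<double> > wc(nf), ws(nf);
  std::vector<int> halfL(nf);
  for (int fi = 0; fi < nf; fi++) {
    int h = (int)std::lround(3.0 * sigmas[fi] * fs);
    if (h < 1) h = 1;
    halfL[fi] = h;
    const int L = 2 * h + 1;
    wc[fi].resize(L);
    ws[fi].resize(L);
    double esum = 0.0;
    for (int k = -h; k <= h; k++) {
      const double tt = k / fs;
      const double env =
          std::exp(-0.5 * tt * tt / (sigmas[fi] * sigmas[fi]));
      const double ph = 2.0 * M_PI * freqs[fi] * tt;
      wc[fi][k + h] = env * std::cos(ph);
      ws[fi][k + h] = -env * std::sin(ph);
      esum += env;
    }
    for (int k = 0; k < L; k++) {
      wc[fi][k] /= esum;
      ws[fi][k] /= esum;
    }
  }

  NumericVector out((R_xlen_t)ntr * nch * nf * nb, NA_REAL);
  std::vector<double> x(ns);
  for (int tr = 0; tr < ntr; tr++) {
    for (int ch = 0; ch < nch; ch++) {
      for (int s = 0; s < ns; s++)
        x[s] = data[tr + (R_xlen_t)ntr * (ch + (R_xlen_t)nch * s)];
      for (int fi = 0; fi < nf; fi++) {
        const int h = halfL[fi];
        const int L = 2 * h + 1;
        const double *pc = wc[fi].data();
        const double *ps = ws[fi].data();
        for (int b = 0; b < nb; b++) {
          const int c = centers0[b];
          if (c - h < 0 || c + h >= ns) continue;
          const double *px = x.data() + (c - h);
          double re = 0.0, im = 0.0;
          for (int k = 0; k < L; k++) {
            re += px[k] * pc[k];
            im += px[k] * ps[k];
          }
          out[tr + (R_xlen_t)ntr *
                       (ch + (R_xlen_t)nch * (fi + (R_xlen_t)nf * b))] =
              re * re + im * im;
        }
      }
    }
  }
  out.attr("dim") =
      IntegerVector::create(ntr, nch, nf, nb);
  return out;
}
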