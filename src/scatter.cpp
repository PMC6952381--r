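#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scattering kernels: per-configuration-group phase sums
// S_g(q) = sum_{j in g} exp(i q . R_j) and orientation-averaged Debye
// sums D_{gg'}(q) = sum_{j in g, k in g'} sinc(q r_jk).

// [[Rcpp::export]]
ComplexMatrix cpp_phase_sum(NumericMatrix pos, IntegerVector group,
                            int n_groups, NumericMatrix qmat) {
  int N = pos.nrow(), nq = qmat.nrow();
  ComplexMatrix S(nq, n_groups);
  std::vector<double> re(nq * n_groups, 0.0), im(nq * n_groups, 0.0);
  for (int j = 0; j < N; ++j) {
    int g = group[j] - 1;
    double x = pos(j, 0), y = pos(j, 1), z = pos(j, 2);
    for (int k = 0; k < nq; ++k) {
      double ph = qmat(k, 0) * x + qmat(k, 1) * y + qmat(k, 2) * z;
      re[g * nq + k] += std::cos(ph);
      im[g * nq + k] += std::sin(ph);
    }
  }
  for (int g = 0; g < n_groups; ++g) {
    for (int k = 0; k < nq; ++k) {
      S(k, g) = Rcomplex{re[g * nq + k], im[g * nq + k]};
    }
  }
  return S;
}

// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix pos, IntegerVector group,
                        int n_groups, NumericVector qs) {
  int N = pos.nrow(), nq = qs.size();
  // output: nq x n_groups x n_groups (flattened, symmetric in (g,g'))
  NumericVector D(nq * n_groups * n_groups);
  for (int j = 0; j < N; ++j) {
    int gj = group[j] - 1;
    // self term: sinc(0) = 1
    for (int k = 0; k < nq; ++k) D[k + nq * (gj + n_groups * gj)] += 1.0;
    for (int l = j + 1; l < N; ++l) {
      int gl = group[l] - 1;
      double dx = pos(j, 0) - pos(l, 0);
      double dy = pos(j, 1) - pos(l, 1);
      double dz = pos(j, 2) - pos(l, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) {
        double x = qs[k] * r;
        double s = (x < 1e-8) ? 1.0 : std::sin(x) / x;
        D[k + nq * (gj + n_groups * gl)] += s;
        if (gj != gl) D[k + nq * (gl + n_groups * gj)] += s;
        else D[k + nq * (gj + n_groups * gj)] += s;
      }
    }
  }
  return D;
}
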