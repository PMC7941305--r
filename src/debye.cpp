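#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Debye sum over atom pairs with per-element complex effective form factors.
//
// I(s) = sum_j sum_k Re[f_j conj(f_k)] w_j w_k sinc(s r_jk)
//
// coords: n x 3 matrix (Angstrom); occ: length-n occupancy weights;
// elem: 0-based index of each atom into the columns of fre/fim;
// fre/fim: ns x nelem real and imaginary parts of f(s) per element.
// [[Rcpp::export(name = ".debye_sum")]]
NumericVector debye_sum(NumericMatrix coords, NumericVector occ,
                        IntegerVector elem, NumericMatrix fre,
                        NumericMatrix fim, NumericVector s) {
  const int n = coords.nrow();
  const int ns = s.size();
  const int ne = fre.ncol();
  NumericVector out(ns);

  // Self terms: sum_j w_j^2 |f_j|^2
  std::vector<double> wsum2(ne, 0.0); // sum of w^2 per element
  for (int j = 0; j < n; ++j) wsum2[elem[j]] += occ[j] * occ[j];
  for (int is = 0; is < ns; ++is) {
    double acc = 0.0;
    for (int e = 0; e < ne; ++e) {
      double re = fre(is, e), im = fim(is, e);
      acc += wsum2[e] * (re * re + im * im);
    }
    out[is] = acc;
  }

  // Cross terms, accumulated per (element pair, s) via Re[f_a conj(f_b)].
  // Loop pairs once; inner loop over s on the sinc kernel.
  std::vector<double> sv(s.begin(), s.end());
  for (int j = 0; j < n; ++j) {
    const double xj = coords(j, 0), yj = coords(j, 1), zj = coords(j, 2);
    const double wj = occ[j];
    const int ej = elem[j];
    for (int k = j + 1; k < n; ++k) {
      const double dx = xj - coords(k, 0);
      const double dy = yj - coords(k, 1);
      const double dz = zj - coords(k, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double w2 = 2.0 * wj * occ[k];
      const int ek = elem[k];
      for (int is = 0; is < ns; ++is) {
        const double rej = fre(is, ej), imj = fim(is, ej);
        const double rek = fre(is, ek), imk = fim(is, ek);
        const double ff = rej * rek + imj * imk; // Re[f_j conj(f_k)]
        const double x = sv[is] * r;
        const double sinc = (x < 1e-8) ? 1.0 : std::sin(x) / x;
        out[is] += w2 * ff * sinc;
      }
    }
  }
  return out;
}
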