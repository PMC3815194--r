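#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static double median_inplace(std::vector<double> &v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Tukey median polish: alternate row and column median sweeps (rows first)
// until the largest absolute sweep drops below tol or max_iter is reached.
// [[Rcpp::export(name = ".median_polish_cpp")]]
List median_polish_cpp(NumericMatrix x, double tol, int max_iter) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix z = clone(x);
  NumericVector row_eff(nr), col_eff(nc);
  double overall = 0.0;
  bool converged = false;
  int iter = 0;
  std::vector<double> buf;

  for (iter = 1; iter <= max_iter; ++iter) {
    double max_delta = 0.0;

    for (int i = 0; i < nr; ++i) {
      buf.assign(nc, 0.0);
      for (int j = 0; j < nc; ++j) buf[j] = z(i, j);
      double m = median_inplace(buf);
      for (int j = 0; j < nc; ++j) z(i, j) -= m;
      row_eff[i] += m;
      if (std::abs(m) > max_delta) max_delta = std::abs(m);
    }
    {
      buf.assign(col_eff.begin(), col_eff.end());
      double m = median_inplace(buf);
      for (int j = 0; j < nc; ++j) col_eff[j] -= m;
      overall += m;
    }

    for (int j = 0; j < nc; ++j) {
      buf.assign(nr, 0.0);
      for (int i = 0; i < nr; ++i) buf[i] = z(i, j);
      double m = median_inplace(buf);
      for (int i = 0; i < nr; ++i) z(i, j) -= m;
      col_eff[j] += m;
      if (std::abs(m) > max_delta) max_delta = std::abs(m);
    }
    {
      buf.assign(row_eff.begin(), row_eff.end());
      double m = median_inplace(buf);
      for (int i = 0; i < nr; ++i) row_eff[i] -= m;
      overall += m;
    }

    if (max_delta < tol) {
      converged = true;
      break;
    }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["overall"] = overall, _["row"] = row_eff,
                      _["col"] = col_eff, _["residuals"] = z,
                      _["iterations"] = iter, _["converged"] = converged);
}
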