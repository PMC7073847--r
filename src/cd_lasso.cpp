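#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the gram-form lasso
//   min_b  0.5 * b' G b  -  g' b  +  lambda * ||b||_1
// over a decreasing lambda path with warm starts. G is the gram submatrix
// with the target column removed; it need not be positive semi-definite
// (the adjusted-Spearman matrix is only approximately so), hence the hard
// iteration cap with a convergence flag rather than an error.
// [[Rcpp::export]]
List cd_lasso_path_cpp(const NumericMatrix& G, const NumericVector& g,
                       const NumericVector& lambdas, double tol, int maxit) {
  const int m = g.size();
  const int L = lambdas.size();
  NumericMatrix beta(m, L);
  IntegerVector iters(L);
  LogicalVector converged(L);
  std::vector<double> b(m, 0.0);

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int it = 0;
    bool ok = false;
    for (; it < maxit; ++it) {
      double maxdiff = 0.0;
      for (int i = 0; i < m; ++i) {
        double z = g[i];
        for (int k = 0; k < m; ++k)
          if (k != i) z -= G(i, k) * b[k];
        double bi;
        if (z > lam)       bi = (z - lam) / G(i, i);
        else if (z < -lam) bi = (z + lam) / G(i, i);
        else               bi = 0.0;
        const double d = std::abs(bi - b[i]);
        if (d > maxdiff) maxdiff = d;
        b[i] = bi;
      }
      if (maxdiff < tol) { ok = true; ++it; break; }
    }
    for (int i = 0; i < m; ++i) beta(i, l) = b[i];
    iters[l] = it;
    converged[l] = ok;
  }
  return List::create(_["beta"] = beta, _["iters"] = iters,
                      _["converged"] = converged);
}
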