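#include <Rcpp.h>
using namespace Rcpp;

// Conjugate gradient for (2*L + r1*I) x = b with L a symmetric sparse
// dgCMatrix given by its CSC slots.  Warm-started from x0.  Returns the
// iterate and the iteration count; stops at relative residual <= tol.
// [[Rcpp::export(name = ".cg_graph_solve")]]
List cg_graph_solve(IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                    NumericVector b, NumericVector x0,
                    double r1, double tol, int maxiter) {
  const int n = b.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> r(n), p(n), Ap(n);

  // L is symmetric, so the gather product over CSC columns (rows of L')
  // equals L*v and avoids the scatter's write contention
  const int* pp = INTEGER(Lp);
  const int* pi = INTEGER(Li);
  const double* px = REAL(Lx);
  auto apply = [&](const std::vector<double>& v, std::vector<double>& out) {
    for (int col = 0; col < n; ++col) {
      double acc = 0.0;
      for (int k = pp[col]; k < pp[col + 1]; ++k)
        acc += px[k] * v[pi[k]];
      out[col] = 2.0 * acc + r1 * v[col];
    }
  };

  apply(x, Ap);
  double bnorm2 = 0.0, rs = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - Ap[i];
    p[i] = r[i];
    rs += r[i] * r[i];
    bnorm2 += b[i] * b[i];
  }
  const double stop2 = tol * tol * std::max(bnorm2, 1e-300);
  int it = 0;
  while (rs > stop2 && it < maxiter) {
    apply(p, Ap);
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break;  // should not happen: system is SPD
    const double alpha = rs / pAp;
    double rs2 = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rs2 += r[i] * r[i];
    }
    const double beta = rs2 / rs;
    for (int i = 0; i < n; ++i) p[i] = r[i] + beta * p[i];
    rs = rs2;
    ++it;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it,
                      _["converged"] = (rs <= stop2));
}
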