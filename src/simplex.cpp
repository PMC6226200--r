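#include <Rcpp.h>
using namespace Rcpp;

// Dense tableau simplex core used by solve_lp(). The tableau `Tm` holds the
// constraint rows with the right-hand side in the last column; `basis` is the
// 1-based column index of each basic variable. Pricing is Dantzig (most
// negative reduced cost) with smallest-index tie-breaking in the ratio test;
// after `bland_after` iterations it falls back to Bland's rule, which
// guarantees termination on degenerate problems.
//
// Returns a list with the final tableau, basis, iteration count and a status
// code: 0 = optimal, 1 = unbounded, 2 = iteration limit.
// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericMatrix Tm_in, IntegerVector basis_in,
                  NumericVector cost, LogicalVector allowed,
                  double tol, int bland_after, int max_iter) {
  NumericMatrix Tm = clone(Tm_in);
  IntegerVector basis = clone(basis_in);
  int m = Tm.nrow();
  int ncols = Tm.ncol() - 1;

  // reduced costs: red_j = c_B' B^-1 A_j - c_j, maintained incrementally
  std::vector<double> red(ncols);
  for (int j = 0; j < ncols; ++j) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += cost[basis[i] - 1] * Tm(i, j);
    red[j] = s - cost[j];
  }

  int it = 0, status = 2;
  while (it < max_iter) {
    ++it;
    int q = -1;
    if (it <= bland_after) {
      double best = -tol;
      for (int j = 0; j < ncols; ++j)
        if (allowed[j] && red[j] < best) { best = red[j]; q = j; }
    } else {
      for (int j = 0; j < ncols; ++j)
        if (allowed[j] && red[j] < -tol) { q = j; break; }
    }
    if (q < 0) { status = 0; break; }

    // Harris-style two-pass ratio test: first find the minimum ratio with
    // a small feasibility relaxation, then among rows within it choose the
    // numerically largest pivot element (Bland mode: smallest basis index,
    // which guarantees termination on exact ties)
    bool bland = it > bland_after;
    const double relax = 1e-9;
    int p = -1;
    double rmin = R_PosInf;
    for (int i = 0; i < m; ++i) {
      double a = Tm(i, q);
      if (a > tol) {
        double r = (Tm(i, ncols) + relax) / a;
        if (r < rmin) rmin = r;
      }
    }
    if (!R_finite(rmin)) { status = 1; break; }  // unbounded
    double best_a = -1.0;
    for (int i = 0; i < m; ++i) {
      double a = Tm(i, q);
      if (a > tol) {
        double r = Tm(i, ncols) / a;
        if (r <= rmin) {
          if (bland ? (p < 0 || basis[i] < basis[p])
                    : (a > best_a)) { p = i; best_a = a; }
        }
      }
    }
    if (p < 0) { status = 1; break; }  // unbounded (defensive)

    double piv = Tm(p, q);
    for (int j = 0; j <= ncols; ++j) Tm(p, j) /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == p) continue;
      double f = Tm(i, q);
      if (f != 0.0) {
        for (int j = 0; j <= ncols; ++j) Tm(i, j) -= f * Tm(p, j);
        Tm(i, q) = 0.0;
      }
    }
    double rq = red[q];
    if (rq != 0.0)
      for (int j = 0; j < ncols; ++j) red[j] -= rq * Tm(p, j);
    red[q] = 0.0;
    basis[p] = q + 1;

    // periodic full refresh of reduced costs to curb numerical drift
    if (it % 128 == 0) {
      for (int j = 0; j < ncols; ++j) {
        double s = 0.0;
        for (int i = 0; i < m; ++i) s += cost[basis[i] - 1] * Tm(i, j);
        red[j] = s - cost[j];
      }
    }
  }

  return List::create(_["Tm"] = Tm, _["basis"] = basis,
                      _["status"] = status, _["iters"] = it);
}
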