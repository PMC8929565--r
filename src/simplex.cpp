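#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex for
//     min c'x  s.t.  A x = b,  x >= 0
// Bland's anti-cycling rule throughout; sized for the small LPs that arise in
// envelopment-form DEA (a handful of constraints, up to a few hundred
// variables), where a dense tableau is both fast and numerically transparent.
//
// Returns list(status, x, objective):
//   status 0 = optimal, 1 = infeasible, 2 = unbounded, 3 = iteration limit.

static const double PIV_TOL = 1e-9;   // minimum pivot magnitude
static const double COST_TOL = 1e-9;  // reduced-cost optimality tolerance

namespace {

struct Tableau {
  int m, n;                   // constraints, structural variables
  std::vector<double> T;      // (m + 1) x (n_total + 1), row-major; last row = cost
  std::vector<int> basis;     // basic variable per row
  int n_total;                // structural + artificial columns

  double& at(int i, int j) { return T[i * (n_total + 1) + j]; }

  void pivot(int pr, int pc) {
    double pv = at(pr, pc);
    int w = n_total + 1;
    for (int j = 0; j < w; ++j) at(pr, j) /= pv;
    for (int i = 0; i <= m; ++i) {
      if (i == pr) continue;
      double f = at(i, pc);
      if (std::fabs(f) < PIV_TOL) { at(i, pc) = 0.0; continue; }
      for (int j = 0; j < w; ++j) at(i, j) -= f * at(pr, j);
      at(i, pc) = 0.0;
    }
    basis[pr] = pc;
  }

  // Bland: entering = lowest-index column (< limit) with reduced cost < -tol;
  // leaving = min ratio, ties broken by lowest basic variable index.
  int iterate(int col_limit, int max_iter) {
    for (int it = 0; it < max_iter; ++it) {
      int pc = -1;
      for (int j = 0; j < col_limit; ++j) {
        if (at(m, j) < -COST_TOL) { pc = j; break; }
      }
      if (pc < 0) return 0;  // optimal
      int pr = -1;
      double best = 0.0;
      for (int i = 0; i < m; ++i) {
        double a = at(i, pc);
        if (a > PIV_TOL) {
          double ratio = at(i, n_total) / a;
          if (pr < 0 || ratio < best - PIV_TOL ||
              (ratio < best + PIV_TOL && basis[i] < basis[pr])) {
            pr = i; best = ratio;
          }
        }
      }
      if (pr < 0) return 2;  // unbounded
      pivot(pr, pc);
    }
    return 3;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_simplex")]]
List cpp_simplex(NumericVector c, NumericMatrix A, NumericVector b,
                 int max_iter = 10000) {
  int m = A.nrow(), n = A.ncol();
  if (c.size() != n || b.size() != m) stop("dimension mismatch in LP");

  Tableau tb;
  tb.m = m; tb.n = n; tb.n_total = n + m;
  tb.T.assign((m + 1) * (tb.n_total + 1), 0.0);
  tb.basis.assign(m, 0);

  // rows with b < 0 are negated so artificials start feasible
  for (int i = 0; i < m; ++i) {
    double s = (b[i] < 0.0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) tb.at(i, j) = s * A(i, j);
    tb.at(i, n + i) = 1.0;
    tb.at(i, tb.n_total) = s * b[i];
    tb.basis[i] = n + i;
  }

  // phase 1: min sum of artificials -> cost row = -(sum of constraint rows)
  for (int j = 0; j <= tb.n_total; ++j) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += tb.at(i, j);
    tb.at(m, j) = -s;
  }
  for (int i = 0; i < m; ++i) tb.at(m, n + i) = 0.0;

  int st = tb.iterate(n, max_iter);  // artificials may not re-enter
  if (st == 3) return List::create(_["status"] = 3);
  double phase1 = -tb.at(m, tb.n_total);
  if (phase1 > 1e-7)
    return List::create(_["status"] = 1, _["infeasibility"] = phase1);

  // drive artificials out of the basis (or drop redundant rows by leaving
  // them basic at zero -- they are excluded from phase-2 pricing anyway)
  for (int i = 0; i < m; ++i) {
    if (tb.basis[i] >= n) {
      int pc = -1;
      for (int j = 0; j < n; ++j)
        if (std::fabs(tb.at(i, j)) > 1e-7) { pc = j; break; }
      if (pc >= 0) tb.pivot(i, pc);
    }
  }

  // phase 2: rebuild cost row for c, priced against the current basis
  for (int j = 0; j <= tb.n_total; ++j) tb.at(m, j) = 0.0;
  for (int j = 0; j < n; ++j) tb.at(m, j) = c[j];
  for (int i = 0; i < m; ++i) {
    int bi = tb.basis[i];
    double cb = (bi < n) ? c[bi] : 0.0;
    if (cb != 0.0)
      for (int j = 0; j <= tb.n_total; ++j) tb.at(m, j) -= cb * tb.at(i, j);
  }

  st = tb.iterate(n, max_iter);
  if (st != 0) return List::create(_["status"] = st);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] < n) x[tb.basis[i]] = tb.at(i, tb.n_total);
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += c[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["objective"] = obj);
}
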