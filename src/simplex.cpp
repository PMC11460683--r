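// Dense two-phase primal simplex core: min c'x s.t. Ax = b, x >= 0.
// Dantzig pricing with a Bland anti-cycling fallback on stall.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tableau {
  int m, n;                 // rows, structural+artificial columns
  std::vector<double> t;    // m x (n+1), row-major; last col = rhs
  std::vector<double> redc; // n+1; last = -objective
  std::vector<int> basis;

  double &at(int r, int c) { return t[(size_t)r * (n + 1) + c]; }

  void pivot(int pr, int pc) {
    double pv = at(pr, pc);
    double *prow = &t[(size_t)pr * (n + 1)];
    for (int c = 0; c <= n; ++c) prow[c] /= pv;
    for (int r = 0; r < m; ++r) {
      if (r == pr) continue;
      double f = at(r, pc);
      if (f == 0.0) continue;
      double *row = &t[(size_t)r * (n + 1)];
      for (int c = 0; c <= n; ++c) row[c] -= f * prow[c];
      row[pc] = 0.0;
    }
    double f = redc[pc];
    if (f != 0.0) {
      for (int c = 0; c <= n; ++c) redc[c] -= f * prow[c];
      redc[pc] = 0.0;
    }
    basis[pr] = pc;
  }
};

// status: 0 optimal, 1 infeasible, 2 unbounded, 3 maxit
int runPhase(Tableau &tb, const std::vector<bool> &allowed, double tol,
             long maxit) {
  long it = 0, stall = 0;
  bool bland = false;
  double lastObj = tb.redc[tb.n];
  for (;;) {
    if (++it > maxit) return 3;
    int pc = -1;
    double best = -tol;
    if (bland) {
      for (int c = 0; c < tb.n; ++c)
        if (allowed[c] && tb.redc[c] < -tol) { pc = c; break; }
    } else {
      for (int c = 0; c < tb.n; ++c)
        if (allowed[c] && tb.redc[c] < best) { best = tb.redc[c]; pc = c; }
    }
    if (pc < 0) return 0;
    int pr = -1;
    double bestRatio = 0.0, bestPiv = 0.0;
    for (int r = 0; r < tb.m; ++r) {
      double a = tb.at(r, pc);
      if (a > tol) {
        double ratio = tb.at(r, tb.n) / a;
        if (pr < 0 || ratio < bestRatio - tol ||
            (ratio <= bestRatio + tol &&
             (bland ? tb.basis[r] < tb.basis[pr] : a > bestPiv))) {
          pr = r; bestRatio = ratio; bestPiv = a;
        }
      }
    }
    if (pr < 0) return 2;
    tb.pivot(pr, pc);
    double obj = tb.redc[tb.n];
    if (std::fabs(obj - lastObj) < tol) ++stall; else stall = 0;
    lastObj = obj;
    if (stall > 2L * (tb.m + tb.n)) bland = true;
  }
}

} // namespace

// [[Rcpp::export(name = ".simplexCore")]]
List simplexCore(NumericVector cvec, NumericMatrix A, NumericVector b,
                 double tol = 1e-9, double maxitFactor = 50.0) {
  int m = A.nrow(), n = A.ncol();
  long maxit = std::max(2000L, (long)(maxitFactor * (m + n)));
  if (m == 0) {
    for (int j = 0; j < n; ++j)
      if (cvec[j] < -tol) return List::create(_["status"] = "unbounded");
    return List::create(_["status"] = "optimal",
                        _["x"] = NumericVector(n), _["objval"] = 0.0);
  }
  Tableau tb;
  tb.m = m; tb.n = n + m;
  tb.t.assign((size_t)m * (tb.n + 1), 0.0);
  tb.redc.assign(tb.n + 1, 0.0);
  tb.basis.resize(m);
  for (int r = 0; r < m; ++r) {
    double sgn = (b[r] < 0) ? -1.0 : 1.0;
    for (int c = 0; c < n; ++c) tb.at(r, c) = sgn * A(r, c);
    tb.at(r, n + r) = 1.0;
    tb.at(r, tb.n) = sgn * b[r];
    tb.basis[r] = n + r;
  }
  // phase-1 reduced costs: c_j - z_j with cost 1 on artificials
  for (int c = 0; c < n; ++c) {
    double s = 0.0;
    for (int r = 0; r < m; ++r) s += tb.at(r, c);
    tb.redc[c] = -s;
  }
  {
    double s = 0.0;
    for (int r = 0; r < m; ++r) s += tb.at(r, tb.n);
    tb.redc[tb.n] = -s;
  }
  std::vector<bool> allowed(tb.n, true);
  int st = runPhase(tb, allowed, tol, maxit);
  if (st != 0) return List::create(_["status"] =
      st == 2 ? "unbounded" : "maxit");
  if (-tb.redc[tb.n] > 1e-7) return List::create(_["status"] = "infeasible");

  // drive artificials out of the basis; drop redundant rows
  std::vector<bool> keep(m, true);
  for (int r = 0; r < m; ++r) {
    if (tb.basis[r] >= n) {
      int pc = -1;
      for (int c = 0; c < n; ++c)
        if (std::fabs(tb.at(r, c)) > tol) { pc = c; break; }
      if (pc >= 0) tb.pivot(r, pc); else keep[r] = false;
    }
  }
  // compact rows if needed
  if (std::find(keep.begin(), keep.end(), false) != keep.end()) {
    int rr = 0;
    std::vector<int> nb;
    std::vector<double> nt;
    nt.reserve(tb.t.size());
    for (int r = 0; r < m; ++r) {
      if (!keep[r]) continue;
      for (int c = 0; c <= tb.n; ++c) nt.push_back(tb.at(r, c));
      nb.push_back(tb.basis[r]);
      ++rr;
    }
    tb.m = rr; tb.t.swap(nt); tb.basis.swap(nb);
    m = rr;
  }
  // phase 2: true objective, artificial columns barred
  for (int c = 0; c < tb.n; ++c) allowed[c] = (c < n);
  {
    std::vector<double> cB(m);
    for (int r = 0; r < m; ++r) cB[r] = cvec[tb.basis[r]]; // basis all < n here
    for (int c = 0; c <= tb.n; ++c) {
      double z = 0.0;
      for (int r = 0; r < m; ++r) z += cB[r] * tb.at(r, c);
      tb.redc[c] = (c < n ? cvec[c] : 0.0) - z;
    }
    // last entry currently holds -(z for rhs) ... fix sign convention
    double z = 0.0;
    for (int r = 0; r < m; ++r) z += cB[r] * tb.at(r, tb.n);
    tb.redc[tb.n] = -z;
  }
  st = runPhase(tb, allowed, tol, maxit);
  if (st != 0) return List::create(_["status"] =
      st == 2 ? "unbounded" : "maxit");
  NumericVector x(n);
  for (int r = 0; r < m; ++r)
    if (tb.basis[r] < n) x[tb.basis[r]] = tb.at(r, tb.n);
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += cvec[j] * x[j];
  return List::create(_["status"] = "optimal", _["x"] = x,
                      _["objval"] = obj);
}
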