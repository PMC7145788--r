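// Dense primal simplex inner loop. The tableau is carried in column-major
// R storage; one call runs a full phase (to optimality, unboundedness or the
// iteration limit) for the given cost vector starting from a feasible basis.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TOL = 1e-9;

// [[Rcpp::export(name = ".simplex_phase_cpp")]]
List simplex_phase_cpp(NumericMatrix Tab, IntegerVector basis0,
                       NumericVector cvec, int max_iter, int bland_from_start) {
  int m = Tab.nrow();
  int ntot = Tab.ncol() - 1;  // last column is the rhs
  std::vector<int> basis(basis0.begin(), basis0.end());  // 1-based ids
  std::vector<double> red(ntot);
  // switch to Bland's rule early: degenerate flux LPs (many zero rhs rows)
  // can cycle under the Dantzig rule
  int bland_after = 500 + 2 * (m + ntot);
  if (bland_after > max_iter) bland_after = (int)(0.6 * max_iter);
  if (bland_from_start) bland_after = -1;

  for (int iter = 0; iter < max_iter; ++iter) {
    bool bland = iter > bland_after;
    // reduced costs: c_j - c_B' (B^-1 A)_j
    int enter = -1;
    double best = -TOL;
    std::vector<double> cb(m);
    for (int i = 0; i < m; ++i) cb[i] = cvec[basis[i] - 1];
    for (int j = 0; j < ntot; ++j) {
      double dot = 0.0;
      const double* col = &Tab[(size_t)j * m];
      for (int i = 0; i < m; ++i) dot += col[i] * cb[i];
      red[j] = cvec[j] - dot;
    }
    for (int i = 0; i < m; ++i) red[basis[i] - 1] = 0.0;
    if (bland) {
      for (int j = 0; j < ntot; ++j)
        if (red[j] < -TOL) { enter = j; break; }
    } else {
      for (int j = 0; j < ntot; ++j)
        if (red[j] < best) { best = red[j]; enter = j; }
    }
    if (enter < 0) {
      double obj = 0.0, minrhs = 0.0;
      for (int i = 0; i < m; ++i) {
        obj += cvec[basis[i] - 1] * Tab[(size_t)ntot * m + i];
        if (Tab[(size_t)ntot * m + i] < minrhs) minrhs = Tab[(size_t)ntot * m + i];
      }
      return List::create(_["Tab"] = Tab,
                          _["basis"] = IntegerVector(basis.begin(), basis.end()),
                          _["status"] = "optimal", _["objval"] = obj,
                          _["minrhs"] = minrhs);
    }
    // Harris two-pass ratio test: pass 1 computes the step limit allowing a
    // delta-bounded constraint violation, pass 2 picks the largest pivot
    // element among rows whose exact ratio respects that limit. This lets a
    // well-conditioned pivot win over a tiny one at an essentially equal
    // ratio; the small infeasibility drift is cleaned up by the caller's
    // periodic refactorization.
    const double DELTA = 1e-8;
    const double* col = &Tab[(size_t)enter * m];
    const double* rhs = &Tab[(size_t)ntot * m];
    double rlimit = R_PosInf;
    for (int i = 0; i < m; ++i)
      if (col[i] > TOL) {
        double r = (rhs[i] + DELTA) / col[i];
        if (r < rlimit) rlimit = r;
      }
    if (!R_FINITE(rlimit))
      return List::create(_["Tab"] = Tab,
                          _["basis"] = IntegerVector(basis.begin(), basis.end()),
                          _["status"] = "unbounded", _["objval"] = R_NegInf);
    int leave = -1;
    int leave_basis = INT_MAX;
    if (bland) {
      // Bland: smallest basis index among eligible rows
      for (int i = 0; i < m; ++i)
        if (col[i] > TOL) {
          double r = rhs[i] / col[i];
          if (r <= rlimit && basis[i] < leave_basis) {
            leave = i; leave_basis = basis[i];
          }
        }
    } else {
      double best_piv = 0.0;
      for (int i = 0; i < m; ++i)
        if (col[i] > TOL) {
          double r = rhs[i] / col[i];
          if (r <= rlimit &&
              (col[i] > best_piv * (1.0 + 1e-9) ||
               (col[i] > best_piv * (1.0 - 1e-9) && basis[i] < leave_basis))) {
            leave = i; best_piv = col[i]; leave_basis = basis[i];
          }
        }
    }
    if (leave < 0) {
      // numerical corner: fall back to the exact minimal ratio row
      double rmin = R_PosInf;
      for (int i = 0; i < m; ++i)
        if (col[i] > TOL) {
          double r = rhs[i] / col[i];
          if (r < rmin) { rmin = r; leave = i; }
        }
    }
    // pivot on (leave, enter)
    double piv = Tab[(size_t)enter * m + leave];
    for (int j = 0; j <= ntot; ++j) Tab[(size_t)j * m + leave] /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = Tab[(size_t)enter * m + i];
      if (f == 0.0) continue;
      for (int j = 0; j <= ntot; ++j)
        Tab[(size_t)j * m + i] -= f * Tab[(size_t)j * m + leave];
    }
    for (int i = 0; i < m; ++i) Tab[(size_t)enter * m + i] = 0.0;
    Tab[(size_t)enter * m + leave] = 1.0;
    basis[leave] = enter + 1;
  }
  // iteration budget exhausted: hand control back (the caller refactors the
  // tableau from original data and continues)
  double obj = 0.0, minrhs = 0.0;
  for (int i = 0; i < m; ++i) {
    obj += cvec[basis[i] - 1] * Tab[(size_t)ntot * m + i];
    if (Tab[(size_t)ntot * m + i] < minrhs) minrhs = Tab[(size_t)ntot * m + i];
  }
  return List::create(_["Tab"] = Tab,
                      _["basis"] = IntegerVector(basis.begin(), basis.end()),
                      _["status"] = "maxiter", _["objval"] = obj,
                      _["minrhs"] = minrhs);
}
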