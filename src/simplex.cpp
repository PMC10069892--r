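#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Dense two-phase primal simplex with Bland's anti-cycling rule and
// periodic refactorization. Solves: min c'x s.t. A x = b (b >= 0, enforced
// by the R wrapper), x >= 0. Bland's rule is deterministic and guarantees
// finite termination in exact arithmetic; refactorization (rebuilding the
// tableau from the basis by a fresh linear solve) bounds the roundoff that
// plain tableau updates accumulate over hundreds of pivots.

static const double PIV_TOL = 1e-9;

// T: (m+1) x (ncols+1) tableau; row m = reduced costs, col ncols = rhs.
// basis[i] = column basic in row i. n_enter limits entering columns (phase 2
// must not re-enter artificials). Returns 0 optimal, 2 unbounded, 3 iter cap.
// Entering rule: Dantzig (most negative reduced cost, ties by index) for
// speed; pure Bland after `bland_after` iterations to guarantee termination.
// Leaving rule: standard ratio test; among rows within a small relative band
// of the minimum ratio, prefer the largest pivot magnitude (numerical
// stability), Bland index as the final tie-break.
static int simplex_iterate(arma::mat& T, std::vector<int>& basis,
                           int m, int ncols, int n_enter, int max_iter,
                           int bland_after = 2000) {
  for (int iter = 0; iter < max_iter; ++iter) {
    bool bland = iter >= bland_after;
    int enter = -1;
    double most_neg = -PIV_TOL;
    for (int j = 0; j < n_enter; ++j) {
      double rc = T(m, j);
      if (rc < most_neg) {
        enter = j;
        if (bland) break;
        most_neg = rc;
      }
    }
    if (enter < 0) return 0;

    double theta = -1.0;
    for (int i = 0; i < m; ++i) {
      double a = T(i, enter);
      if (a > PIV_TOL) {
        double ratio = T(i, ncols) / a;
        if (ratio < 0.0) ratio = 0.0;  // degenerate negative roundoff
        if (theta < 0.0 || ratio < theta) theta = ratio;
      }
    }
    if (theta < 0.0) return 2;
    int leave = -1;
    double best_piv = 0.0;
    double band = 1e-9 * (1.0 + theta);
    for (int i = 0; i < m; ++i) {
      double a = T(i, enter);
      if (a > PIV_TOL) {
        double ratio = T(i, ncols) / a;
        if (ratio < 0.0) ratio = 0.0;
        if (ratio <= theta + band) {
          if (bland) {
            if (leave < 0 || basis[i] < basis[leave]) leave = i;
          } else if (a > best_piv + 1e-12 ||
                     (std::abs(a - best_piv) <= 1e-12 && leave >= 0 &&
                      basis[i] < basis[leave])) {
            leave = i;
            best_piv = a;
          }
        }
      }
    }
    double piv = T(leave, enter);
    T.row(leave) /= piv;
    for (int i = 0; i <= m; ++i) {
      if (i == leave) continue;
      double f = T(i, enter);
      if (f != 0.0) T.row(i) -= f * T.row(leave);
    }
    basis[leave] = enter;
  }
  return 3;
}

// Rebuild the tableau exactly from the current basis: T = B^-1 [A | b],
// reduced-cost row from the given objective. Returns false if the basis
// matrix is numerically singular.
static bool refresh_tableau(const arma::mat& A, const arma::vec& b,
                            const arma::vec& cost, arma::mat& T,
                            const std::vector<int>& basis, int m, int ncols) {
  arma::mat B(m, m);
  for (int i = 0; i < m; ++i) B.col(i) = A.col(basis[i]);
  arma::mat rhs(m, ncols + 1);
  rhs.cols(0, ncols - 1) = A;
  rhs.col(ncols) = b;
  arma::mat X;
  if (!arma::solve(X, B, rhs, arma::solve_opts::no_approx)) return false;
  T.rows(0, m - 1) = X;
  arma::rowvec cr(ncols + 1, arma::fill::zeros);
  for (int j = 0; j < ncols; ++j) cr(j) = cost(j);
  for (int i = 0; i < m; ++i) {
    double cb = cost(basis[i]);
    if (cb != 0.0) cr -= cb * X.row(i);
  }
  T.row(m) = cr;
  return true;
}

// Iterate to claimed optimality, then refactorize and re-check; repeat until
// the refreshed tableau confirms optimality (or resource limits hit).
static int solve_phase(const arma::mat& A, const arma::vec& b,
                       const arma::vec& cost, arma::mat& T,
                       std::vector<int>& basis, int m, int ncols,
                       int n_enter, int max_iter) {
  // refactorize every `chunk` pivots to cap drift, and whenever the update
  // path claims optimality, confirm it against a freshly solved tableau
  const int chunk = 250;
  int done = 0;
  int stalled_rounds = 0;
  while (done < max_iter) {
    int st = simplex_iterate(T, basis, m, ncols, n_enter, chunk,
                             stalled_rounds >= 3 ? 0 : 2000);
    if (st == 2) return 2;
    if (!refresh_tableau(A, b, cost, T, basis, m, ncols)) return st == 0 ? 0 : 3;
    bool still_optimal = true;
    for (int j = 0; j < n_enter; ++j) {
      if (T(m, j) < -PIV_TOL) { still_optimal = false; break; }
    }
    if (st == 0) {
      if (still_optimal) return 0;
      ++stalled_rounds;          // claimed optimal but refresh disagrees
      if (stalled_rounds > 40) return 0;
    }
    done += chunk;
  }
  return 3;
}

// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(const arma::mat& A_in, const arma::vec& b, const arma::vec& c,
                  int max_iter = 200000) {
  const int m = A_in.n_rows;
  const int n = A_in.n_cols;
  const int ncols = n + m;  // original + artificial columns

  arma::mat A(m, ncols, arma::fill::zeros);
  A.cols(0, n - 1) = A_in;
  for (int i = 0; i < m; ++i) A(i, n + i) = 1.0;

  arma::mat T(m + 1, ncols + 1, arma::fill::zeros);
  T.cols(0, ncols - 1).rows(0, m - 1) = A;
  for (int i = 0; i < m; ++i) T(i, ncols) = b(i);

  // Phase 1: minimize the sum of artificials.
  arma::vec cost1(ncols, arma::fill::zeros);
  for (int j = n; j < ncols; ++j) cost1(j) = 1.0;
  std::vector<int> basis(m);
  for (int i = 0; i < m; ++i) basis[i] = n + i;
  for (int j = 0; j < n; ++j) T(m, j) = -arma::accu(A_in.col(j));
  T(m, ncols) = -arma::accu(b);

  int st = solve_phase(A, b, cost1, T, basis, m, ncols, n, max_iter);
  if (st == 3) return List::create(_["status"] = 3);
  double phase1 = 0.0;
  for (int i = 0; i < m; ++i) {
    if (basis[i] >= n) phase1 += T(i, ncols);
  }
  if (phase1 > 1e-7) {
    return List::create(_["status"] = 1, _["phase1"] = phase1);
  }

  // Drive basic artificials out where a non-artificial pivot exists; rows
  // where none exists are redundant and their artificial stays basic at 0
  // (harmless: artificials never re-enter in phase 2).
  for (int i = 0; i < m; ++i) {
    if (basis[i] >= n) {
      int piv_col = -1;
      for (int j = 0; j < n; ++j) {
        if (std::abs(T(i, j)) > 1e-7) { piv_col = j; break; }
      }
      if (piv_col >= 0) {
        double piv = T(i, piv_col);
        T.row(i) /= piv;
        for (int k = 0; k <= m; ++k) {
          if (k == i) continue;
          double f = T(k, piv_col);
          if (f != 0.0) T.row(k) -= f * T.row(i);
        }
        basis[i] = piv_col;
      }
    }
  }

  // Phase 2 on the true objective.
  arma::vec cost2(ncols, arma::fill::zeros);
  for (int j = 0; j < n; ++j) cost2(j) = c(j);
  if (!refresh_tableau(A, b, cost2, T, basis, m, ncols)) {
    return List::create(_["status"] = 3);
  }
  st = solve_phase(A, b, cost2, T, basis, m, ncols, n, max_iter);
  if (st != 0) return List::create(_["status"] = st);

  arma::vec x(n, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    if (basis[i] < n && T(i, ncols) > 0) x(basis[i]) = T(i, ncols);
  }
  return List::create(_["status"] = 0,
                      _["x"] = x,
                      _["objective"] = arma::dot(c, x));
}
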