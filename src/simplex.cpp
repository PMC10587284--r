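#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex with Bland's rule (anti-cycling).
// Solves: max c'x  s.t.  A x {<=,=} b,  x >= 0.
// DEA programs are tiny (a handful of rows, tens of columns) and frequently
// degenerate (zero right-hand sides), so robustness matters more than pivot
// heuristics here.

static const double EPS = 1e-9;

struct LpResult {
  int status; // 0 optimal, 1 infeasible, 2 unbounded
  double obj;
  std::vector<double> x;
};

// tableau: rows = m constraints + 1 objective row (last),
// cols = n structural + slacks + artificials + 1 rhs (last)
static LpResult simplex_core(const std::vector<double>& c,
                             const std::vector<std::vector<double>>& A,
                             const std::vector<double>& b,
                             const std::vector<int>& is_eq) {
  const int m = (int)A.size();
  const int n = m ? (int)A[0].size() : 0;
  LpResult out; out.status = 0; out.obj = 0.0; out.x.assign(n, 0.0);

  // count slacks (one per inequality) and artificials (eq rows, and ineq rows
  // whose rhs is negative after sign normalisation)
  std::vector<double> bb = b;
  std::vector<std::vector<double>> AA = A;
  std::vector<int> eq = is_eq;
  for (int i = 0; i < m; ++i) {
    if (bb[i] < 0) { // flip row so rhs >= 0
      bb[i] = -bb[i];
      for (int j = 0; j < n; ++j) AA[i][j] = -AA[i][j];
      if (!eq[i]) eq[i] = -1; // '<=' becomes '>='
    }
  }
  int n_slack = 0;
  for (int i = 0; i < m; ++i) if (eq[i] != 1) ++n_slack;
  // artificials: eq rows always; '>=' rows always (surplus slack is -1)
  int n_art = 0;
  for (int i = 0; i < m; ++i) if (eq[i] == 1 || eq[i] == -1) ++n_art;

  const int ncol = n + n_slack + n_art;
  std::vector<std::vector<double>> T(m + 1, std::vector<double>(ncol + 1, 0.0));
  std::vector<int> basis(m, -1);

  int sl = 0, ar = 0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[i][j] = AA[i][j];
    T[i][ncol] = bb[i];
    if (eq[i] == 0) {            // <= : slack enters basis
      T[i][n + sl] = 1.0; basis[i] = n + sl; ++sl;
    } else if (eq[i] == -1) {    // >= : surplus + artificial
      T[i][n + sl] = -1.0; ++sl;
      T[i][n + n_slack + ar] = 1.0; basis[i] = n + n_slack + ar; ++ar;
    } else {                     // = : artificial
      T[i][n + n_slack + ar] = 1.0; basis[i] = n + n_slack + ar; ++ar;
    }
  }

  auto pivot = [&](int pr, int pc) {
    double pv = T[pr][pc];
    for (int j = 0; j <= ncol; ++j) T[pr][j] /= pv;
    for (int i = 0; i <= m; ++i) {
      if (i == pr) continue;
      double f = T[i][pc];
      if (std::fabs(f) < 1e-14) continue;
      for (int j = 0; j <= ncol; ++j) T[i][j] -= f * T[pr][j];
    }
    basis[pr] = pc;
  };

  // Bland's rule iteration over objective row T[m][.] (maximisation:
  // enter on coefficient > EPS of the reduced-cost row written as z_j - c_j
  // convention below: we keep the row as negative reduced costs, enter on < -EPS)
  auto iterate = [&](int limit_cols) -> int {
    for (int iter = 0; iter < 50000; ++iter) {
      int pc = -1;
      for (int j = 0; j < limit_cols; ++j)
        if (T[m][j] < -EPS) { pc = j; break; } // Bland: smallest index
      if (pc < 0) return 0; // optimal
      int pr = -1; double best = 0.0;
      for (int i = 0; i < m; ++i) {
        if (T[i][pc] > EPS) {
          double ratio = T[i][ncol] / T[i][pc];
          if (pr < 0 || ratio < best - EPS ||
              (ratio < best + EPS && basis[i] < basis[pr])) { // Bland tie-break
            pr = i; best = ratio;
          }
        }
      }
      if (pr < 0) return 2; // unbounded
      pivot(pr, pc);
    }
    return 3; // iteration limit — treated as failure upstream
  };

  if (n_art > 0) {
    // Phase 1: minimise sum of artificials => maximise -sum
    // objective row = sum of artificial rows (so artificial basics price out)
    for (int j = 0; j <= ncol; ++j) T[m][j] = 0.0;
    for (int i = 0; i < m; ++i)
      if (basis[i] >= n + n_slack)
        for (int j = 0; j <= ncol; ++j) T[m][j] -= T[i][j];
    // basic (artificial) columns must price out to zero
    for (int j = n + n_slack; j < ncol; ++j) T[m][j] = 0.0;
    int st = iterate(ncol);
    if (st != 0) { out.status = (st == 2) ? 1 : st; return out; }
    if (T[m][ncol] < -1e-7) { out.status = 1; return out; } // infeasible
    // drive any artificial still basic out of the basis (degenerate)
    for (int i = 0; i < m; ++i) {
      if (basis[i] >= n + n_slack) {
        int pc = -1;
        for (int j = 0; j < n + n_slack; ++j)
          if (std::fabs(T[i][j]) > EPS) { pc = j; break; }
        if (pc >= 0) pivot(i, pc);
        // else row is redundant; harmless to leave
      }
    }
  }

  // Phase 2 objective: maximise c'x  -> row holds c_B B^-1 A - c;
  // entering is restricted to structural + slack columns, so artificials
  // (possibly still basic on redundant rows) can never re-enter.
  for (int j = 0; j <= ncol; ++j) T[m][j] = 0.0;
  for (int j = 0; j < n; ++j) T[m][j] = -c[j];
  for (int i = 0; i < m; ++i) {
    int bj = basis[i];
    if (bj < n && c[bj] != 0.0)
      for (int j = 0; j <= ncol; ++j) T[m][j] += c[bj] * T[i][j];
  }
  int st = iterate(n + n_slack);
  if (st != 0) { out.status = st; return out; }

  for (int i = 0; i < m; ++i)
    if (basis[i] < n) out.x[basis[i]] = T[i][ncol];
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += c[j] * out.x[j];
  out.obj = obj;
  out.status = 0;
  return out;
}

// [[Rcpp::export(name = ".lp_solve_cpp")]]
List lp_solve_cpp(NumericVector cvec, NumericMatrix Amat, NumericVector bvec,
                  IntegerVector eqvec) {
  const int m = Amat.nrow(), n = Amat.ncol();
  std::vector<double> c(cvec.begin(), cvec.end());
  std::vector<double> b(bvec.begin(), bvec.end());
  std::vector<int> eq(eqvec.begin(), eqvec.end());
  std::vector<std::vector<double>> A(m, std::vector<double>(n));
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) A[i][j] = Amat(i, j);
  LpResult r = simplex_core(c, A, b, eq);
  return List::create(_["status"] = r.status, _["objval"] = r.obj,
                      _["x"] = NumericVector(r.x.begin(), r.x.end()));
}

// Batched DEA output-oriented VRS distance programs.
//
// Frontier: J reference DMUs with inputs X (J x N), outputs Y (J x M).
// Scored observations: X0 (K x N), Y0 (K x M) — usually the same matrix
// (own-period scores) but possibly another period's observations (cross-
// period Malmquist distances).
//
// mode 0 (technical efficiency): all input columns constrained.
// mode 1 (capacity): only columns in fixed_idx constrained; variable-input
//   rows are dropped (their lambda multipliers are free above zero, so the
//   constraints can never bind — reported post hoc in R).
//
// Returns theta (K), status (K), and the z weight matrix (K x J).
// [[Rcpp::export(name = ".dea_solve_batch_cpp")]]
List dea_solve_batch_cpp(NumericMatrix X, NumericMatrix Y,
                         NumericMatrix X0, NumericMatrix Y0,
                         IntegerVector constrained_idx) {
  const int J = X.nrow(), N = X.ncol(), M = Y.ncol(), K = X0.nrow();
  const int nc = constrained_idx.size();
  NumericVector theta(K);
  IntegerVector status(K);
  NumericMatrix Z(K, J);

  // variables: (theta, z_1..z_J); rows: M output, nc input, 1 convexity
  std::vector<double> c(1 + J, 0.0); c[0] = 1.0;
  std::vector<std::vector<double>> A(M + nc + 1, std::vector<double>(1 + J, 0.0));
  std::vector<double> b(M + nc + 1, 0.0);
  std::vector<int> eq(M + nc + 1, 0);
  for (int j = 0; j < J; ++j) {
    for (int mm = 0; mm < M; ++mm) A[mm][1 + j] = -Y(j, mm);
    for (int ii = 0; ii < nc; ++ii) A[M + ii][1 + j] = X(j, constrained_idx[ii] - 1);
    A[M + nc][1 + j] = 1.0;
  }
  eq[M + nc] = 1; b[M + nc] = 1.0;

  for (int k = 0; k < K; ++k) {
    bool any_pos = false;
    for (int mm = 0; mm < M; ++mm) {
      A[mm][0] = Y0(k, mm);
      if (Y0(k, mm) > 0) any_pos = true;
    }
    for (int ii = 0; ii < nc; ++ii) b[M + ii] = X0(k, constrained_idx[ii] - 1);
    if (!any_pos) { theta[k] = NA_REAL; status[k] = 2; continue; } // unbounded
    LpResult r = simplex_core(c, A, b, eq);
    status[k] = r.status;
    if (r.status == 0) {
      theta[k] = r.obj;
      for (int j = 0; j < J; ++j) Z(k, j) = r.x[1 + j];
    } else {
      theta[k] = NA_REAL;
    }
  }
  return List::create(_["theta"] = theta, _["status"] = status, _["z"] = Z);
}
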