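// Bounded-variable two-phase primal simplex for the small dense LPs that
// arise in flux balance analysis:
//
//     min c'x   s.t.  A x = b,   l <= x <= u   (entries of l/u may be +-Inf)
//
// Bland's smallest-index rule is used throughout, so the method terminates
// on degenerate problems (FBA LPs are routinely degenerate). Bases are
// refactorised from scratch every iteration with a dense solve; problem
// sizes here are tens of variables, so clarity wins over sparse updates.
//
// Status: 0 = optimal, 1 = infeasible, 2 = unbounded, 3 = iteration limit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

enum VarState { AT_LB, AT_UB, FREE0, BASIC };

struct Problem {
  mat A;            // m x n (including artificials)
  vec c, l, u;
  int m, n;
};

// One primal simplex run from the current basis/state. Mutates basis, state
// and x. Returns 0 optimal, 2 unbounded, 3 iteration cap.
int primal_simplex(const Problem& P, std::vector<int>& basis,
                   std::vector<VarState>& state, vec& x,
                   double tol, int maxit) {
  const int m = P.m, n = P.n;
  for (int iter = 0; iter < maxit; ++iter) {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = P.A.col(basis[i]);
    vec cB(m);
    for (int i = 0; i < m; ++i) cB(i) = P.c(basis[i]);
    vec y;
    if (!solve(y, B.t(), cB)) return 3;  // singular basis: bail out

    // Bland entering rule: smallest index with a profitable direction.
    int enter = -1, dir = 0;
    for (int j = 0; j < n; ++j) {
      if (state[j] == BASIC) continue;
      double d = P.c(j) - dot(y, P.A.col(j));
      if ((state[j] == AT_LB || state[j] == FREE0) && d < -tol) {
        enter = j; dir = +1; break;
      }
      if ((state[j] == AT_UB || state[j] == FREE0) && d > tol) {
        enter = j; dir = -1; break;
      }
    }
    if (enter < 0) return 0;  // optimal

    vec w;
    if (!solve(w, B, P.A.col(enter))) return 3;

    // Ratio test: entering moves by t*dir, basics by -t*dir*w.
    double tmax = datum::inf;
    int leave = -1;          // index into basis; -1 => entering bound flip
    double xj = x(enter);
    double own = (dir > 0) ? (P.u(enter) - xj) : (xj - P.l(enter));
    if (own < tmax) { tmax = own; leave = -1; }
    for (int i = 0; i < m; ++i) {
      double delta = -dir * w(i);  // d x_Bi / d t
      double lim = datum::inf;
      if (delta > tol)       lim = (P.u(basis[i]) - x(basis[i])) / delta;
      else if (delta < -tol) lim = (x(basis[i]) - P.l(basis[i])) / (-delta);
      if (lim < tmax - 1e-12 || (lim < tmax + 1e-12 && leave >= 0 &&
                                 basis[i] < basis[leave])) {
        tmax = lim; leave = i;
      }
    }
    if (!std::isfinite(tmax)) return 2;  // unbounded ray
    if (tmax < 0) tmax = 0;              // numerical guard

    x(enter) = xj + dir * tmax;
    for (int i = 0; i < m; ++i) x(basis[i]) -= dir * tmax * w(i);

    if (leave < 0) {
      // entering variable ran to its opposite bound: state flip only
      state[enter] = (dir > 0) ? AT_UB : AT_LB;
    } else {
      int out = basis[leave];
      double delta = -dir * w(leave);
      // leaving variable lands on the bound it was driven into
      if (delta > 0) { x(out) = P.u(out); state[out] = AT_UB; }
      else           { x(out) = P.l(out); state[out] = AT_LB; }
      if (!std::isfinite(x(out))) x(out) = 0;  // free var leaving (rare)
      basis[leave] = enter;
      state[enter] = BASIC;
    }
  }
  return 3;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::vec& cost, const arma::mat& A,
                         const arma::vec& b, const arma::vec& lb,
                         const arma::vec& ub, double tol = 1e-9,
                         int maxit = 0) {
  const int m = A.n_rows, n = A.n_cols;
  if (maxit <= 0) maxit = 50 * (m + n) + 200;

  Problem P;
  P.m = m; P.n = n + m;
  P.A = join_rows(A, eye(m, m));  // artificial columns
  P.l = join_cols(lb, zeros<vec>(m));
  P.u = join_cols(ub, vec(m, fill::value(datum::inf)));

  // start: structural vars at a finite bound (prefer the smaller magnitude),
  // free vars at 0; artificials pick up the residual.
  vec x(P.n, fill::zeros);
  std::vector<VarState> state(P.n, AT_LB);
  for (int j = 0; j < n; ++j) {
    bool lf = std::isfinite(lb(j)), uf = std::isfinite(ub(j));
    if (lf && uf) {
      if (std::fabs(lb(j)) <= std::fabs(ub(j))) { x(j) = lb(j); state[j] = AT_LB; }
      else { x(j) = ub(j); state[j] = AT_UB; }
    } else if (lf) { x(j) = lb(j); state[j] = AT_LB; }
    else if (uf)   { x(j) = ub(j); state[j] = AT_UB; }
    else           { x(j) = 0;     state[j] = FREE0; }
  }
  vec r = b - A * x.head(n);
  std::vector<int> basis(m);
  for (int i = 0; i < m; ++i) {
    basis[i] = n + i;
    state[n + i] = BASIC;
    if (r(i) >= 0) { P.A(i, n + i) = 1;  x(n + i) = r(i); }
    else           { P.A(i, n + i) = -1; x(n + i) = -r(i); }
  }

  // Phase 1: drive artificials to zero.
  P.c = join_cols(zeros<vec>(n), ones<vec>(m));
  int st = primal_simplex(P, basis, state, x, tol, maxit);
  double phase1 = accu(x.tail(m));
  double scale = 1.0 + std::fabs(accu(abs(b)));
  if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
  if (phase1 > tol * scale * 1e3)
    return Rcpp::List::create(Rcpp::Named("status") = 1);

  // Pin artificials to zero; pivot basic artificials out where possible.
  for (int i = 0; i < m; ++i) { P.l(n + i) = 0; P.u(n + i) = 0; }
  for (int i = 0; i < m; ++i) {
    if (basis[i] < n) continue;
    mat B(m, m);
    for (int k = 0; k < m; ++k) B.col(k) = P.A.col(basis[k]);
    vec e(m, fill::zeros); e(i) = 1;
    vec rho;
    if (!solve(rho, B.t(), e)) continue;
    for (int j = 0; j < n; ++j) {
      if (state[j] == BASIC) continue;
      double a = dot(rho, P.A.col(j));
      if (std::fabs(a) > 1e-7) {
        int out = basis[i];
        state[out] = AT_LB; x(out) = 0;
        basis[i] = j; state[j] = BASIC;  // x(j) unchanged (degenerate pivot)
        break;
      }
    }
    // if no pivot found the row is redundant; artificial stays basic at 0
  }

  // Phase 2: original objective.
  P.c = join_cols(cost, zeros<vec>(m));
  st = primal_simplex(P, basis, state, x, tol, maxit);
  if (st == 2) return Rcpp::List::create(Rcpp::Named("status") = 2);
  if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);

  vec xout = x.head(n);
  return Rcpp::List::create(
      Rcpp::Named("status") = 0,
      Rcpp::Named("x") = xout,
      Rcpp::Named("objective") = dot(cost, xout));
}
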