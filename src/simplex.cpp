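// Bounded-variable two-phase primal simplex.
//
// Solves   min c'x   s.t.  A x = b,  lb <= x <= ub
// with possibly infinite bounds. Dense linear algebra; intended for the
// small/medium LPs arising from toy and synthetic metabolic networks
// (tens to a few hundred variables), not for genome-scale models with a
// commercial solver's scale.
//
// Basic values are recomputed from the factorized basis every iteration
// (no product-form updates): numerically clean and cheap at this size.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const int AT_LB = 0, AT_UB = 1, BASIC = 2, FREE_NB = 3;

// [[Rcpp::export(name = ".simplex_cpp")]]
Rcpp::List simplex_cpp(const arma::mat& A,
                       const arma::vec& b,
                       const arma::vec& c,
                       const arma::vec& lb,
                       const arma::vec& ub,
                       double tol = 1e-9,
                       int max_iter = 20000) {
  const uword m = A.n_rows, n = A.n_cols;
  const uword N = n + m;             // structural + artificial
  const double INF = datum::inf;

  mat Aall(m, N, fill::zeros);
  Aall.cols(0, n - 1) = A;

  vec L(N), U(N), x(N, fill::zeros);
  L.subvec(0, n - 1) = lb;  U.subvec(0, n - 1) = ub;
  L.subvec(n, N - 1).zeros();
  U.subvec(n, N - 1).fill(INF);

  ivec stat(N);
  for (uword j = 0; j < n; ++j) {
    bool lf = std::isfinite(L(j)), uf = std::isfinite(U(j));
    if (lf && uf)      { if (std::abs(L(j)) <= std::abs(U(j))) { x(j) = L(j); stat(j) = AT_LB; }
                         else { x(j) = U(j); stat(j) = AT_UB; } }
    else if (lf)       { x(j) = L(j); stat(j) = AT_LB; }
    else if (uf)       { x(j) = U(j); stat(j) = AT_UB; }
    else               { x(j) = 0.0;  stat(j) = FREE_NB; }
  }

  // artificial columns carry the sign of the initial residual
  vec r = b - Aall.cols(0, n - 1) * x.subvec(0, n - 1);
  uvec basis(m);
  for (uword i = 0; i < m; ++i) {
    double s = (r(i) >= 0.0) ? 1.0 : -1.0;
    Aall(i, n + i) = s;
    x(n + i) = std::abs(r(i));
    stat(n + i) = BASIC;
    basis(i) = n + i;
  }

  vec cost(N, fill::zeros);
  cost.subvec(n, N - 1).ones();        // phase 1
  int phase = 1;
  int iter = 0;
  const int bland_after = 2000;
  double bscale = std::max(1.0, norm(b, "inf"));

  auto recompute_basics = [&](void) -> bool {
    vec xn = x;
    for (uword i = 0; i < m; ++i) xn(basis(i)) = 0.0;
    vec rhs = b - Aall * xn;
    mat B = Aall.cols(basis);
    vec xb;
    if (!solve(xb, B, rhs, solve_opts::no_approx)) return false;
    for (uword i = 0; i < m; ++i) x(basis(i)) = xb(i);
    return true;
  };
  if (!recompute_basics())
    return Rcpp::List::create(Rcpp::Named("status") = "singular");

  int since_refresh = 0;
  while (true) {
    if (++iter > max_iter)
      return Rcpp::List::create(Rcpp::Named("status") = "maxiter");

    // one factorization per iteration, shared by pricing and ratio test
    mat Binv;
    if (!inv(Binv, Aall.cols(basis)))
      return Rcpp::List::create(Rcpp::Named("status") = "singular");
    if (++since_refresh >= 50) {                 // periodic numerical refresh
      if (!recompute_basics())
        return Rcpp::List::create(Rcpp::Named("status") = "singular");
      since_refresh = 0;
    }
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB(i) = cost(basis(i));
    vec y = Binv.t() * cB;

    // pricing (one gemv for all reduced costs)
    vec d = cost - Aall.t() * y;
    bool bland = iter > bland_after;
    sword q = -1; double best = tol; int qdir = 0;
    for (uword j = 0; j < N; ++j) {
      if (stat(j) == BASIC) continue;
      if (phase == 2 && j >= n) continue;         // artificials pinned
      double dj = d(j);
      int dir = 0; double viol = 0.0;
      if (stat(j) == AT_LB && dj < -tol)      { dir = +1; viol = -dj; }
      else if (stat(j) == AT_UB && dj > tol)  { dir = -1; viol =  dj; }
      else if (stat(j) == FREE_NB && std::abs(dj) > tol)
        { dir = (dj < 0) ? +1 : -1; viol = std::abs(dj); }
      if (dir != 0) {
        if (bland) { q = j; qdir = dir; break; }
        if (viol > best) { best = viol; q = j; qdir = dir; }
      }
    }

    if (q < 0) {                                   // optimal for this phase
      if (phase == 1) {
        double art = 0.0;
        for (uword j = n; j < N; ++j) art += std::abs(x(j));
        if (art > 1e-7 * bscale)
          return Rcpp::List::create(Rcpp::Named("status") = "infeasible");
        // pin artificials and switch to the real objective
        for (uword j = n; j < N; ++j) { U(j) = 0.0; }
        cost.zeros();
        cost.subvec(0, n - 1) = c;
        phase = 2;
        continue;
      }
      break;                                       // phase-2 optimum
    }

    vec w = Binv * Aall.col((uword)q);

    // ratio test: entering moves by t in direction qdir
    double t_own = INF;                            // own bound-to-bound range
    if (std::isfinite(L(q)) && std::isfinite(U(q))) t_own = U(q) - L(q);
    double t_min = t_own; sword leave = -1; int leave_to = AT_LB;
    for (uword i = 0; i < m; ++i) {
      double delta = -qdir * w(i);                 // d x_Bi / d t
      uword jb = basis(i);
      if (delta > tol) {
        if (std::isfinite(U(jb))) {
          double tt = (U(jb) - x(jb)) / delta;
          if (tt < t_min - 1e-12) { t_min = tt; leave = i; leave_to = AT_UB; }
        }
      } else if (delta < -tol) {
        if (std::isfinite(L(jb))) {
          double tt = (L(jb) - x(jb)) / delta;
          if (tt < t_min - 1e-12) { t_min = tt; leave = i; leave_to = AT_LB; }
        }
      }
    }

    if (!std::isfinite(t_min))
      return Rcpp::List::create(
        Rcpp::Named("status") = (phase == 1) ? "singular" : "unbounded");

    double t = std::max(t_min, 0.0);
    // move
    x(q) += qdir * t;
    for (uword i = 0; i < m; ++i) x(basis(i)) -= qdir * t * w(i);

    if (leave < 0) {                               // bound flip, basis unchanged
      stat(q) = (qdir > 0) ? AT_UB : AT_LB;
      x(q) = (qdir > 0) ? U(q) : L(q);
    } else {
      uword jl = basis(leave);
      stat(jl) = leave_to;
      x(jl) = (leave_to == AT_UB) ? U(jl) : L(jl);
      basis(leave) = (uword)q;
      stat(q) = BASIC;
      // basic values were updated incrementally; periodic refresh above
      // guards against drift
    }
  }

  recompute_basics();                            // final numerical refresh
  vec xs = x.subvec(0, n - 1);
  double obj = dot(c, xs);
  return Rcpp::List::create(
    Rcpp::Named("status") = "optimal",
    Rcpp::Named("objective") = obj,
    Rcpp::Named("x") = xs,
    Rcpp::Named("iterations") = iter);
}
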