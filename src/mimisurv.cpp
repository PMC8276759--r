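// Numerical core: Breslow partial likelihood, penalized Cox solvers
// (Newton for smooth penalties, IRLS + coordinate descent with
// soft-thresholding for l1 penalties), the alternating block-ascent
// fitter for the structured-component model, and the permutation loop.
//
// Penalty convention throughout: pen(b) = l1*||b||_1 + 0.5*l2*||b||^2,
// objective = log partial likelihood - pen (maximized).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---- survival ordering -----------------------------------------------------

// Sort samples by descending time; riskend[i] = last sorted index sharing
// time[i], so the risk set {q : y_q >= y_i} is sorted positions 0..riskend[i].
struct SurvOrder {
  uvec ord;       // sorted position -> original row
  vec  ev;        // event indicator, sorted
  uvec riskend;   // tie-block end per sorted position
  double nevent;
};

static SurvOrder surv_order(const vec& time, const vec& event) {
  SurvOrder s;
  s.ord = stable_sort_index(time, "descend");
  const uword N = time.n_elem;
  vec ts(N);
  s.ev.set_size(N);
  for (uword i = 0; i < N; ++i) {
    ts(i)   = time(s.ord(i));
    s.ev(i) = event(s.ord(i));
  }
  s.riskend.set_size(N);
  uword pos = 0;
  while (pos < N) {
    uword end = pos;
    while (end + 1 < N && ts(end + 1) == ts(pos)) ++end;
    for (uword q = pos; q <= end; ++q) s.riskend(q) = end;
    pos = end + 1;
  }
  s.nevent = accu(s.ev);
  return s;
}

// log partial likelihood, eta already in sorted (descending-time) order
static double breslow_loglik(const vec& eta_s, const SurvOrder& s) {
  const uword N = eta_s.n_elem;
  double m = eta_s.max();
  vec w = exp(eta_s - m);
  vec cw = cumsum(w);
  double ll = 0.0;
  for (uword i = 0; i < N; ++i)
    if (s.ev(i) == 1.0) ll += (eta_s(i) - m) - std::log(cw(s.riskend(i)));
  return ll;
}

// gradient and Hessian of the log partial likelihood wrt beta,
// X_s sorted by descending time
static void breslow_grad_hess(const mat& X_s, const vec& eta_s,
                              const SurvOrder& s, vec& g, mat& H) {
  const uword N = X_s.n_rows, P = X_s.n_cols;
  double m = eta_s.max();
  vec w = exp(eta_s - m);
  g.zeros(P);
  H.zeros(P, P);
  double S0 = 0.0;
  vec S1(P, fill::zeros);
  mat S2(P, P, fill::zeros);
  uword pos = 0;
  while (pos < N) {
    uword end = s.riskend(pos);
    for (uword q = pos; q <= end; ++q) {
      const double wq = w(q);
      S0 += wq;
      for (uword a = 0; a < P; ++a) {
        const double wx = wq * X_s(q, a);
        S1(a) += wx;
        for (uword b = a; b < P; ++b) S2(a, b) += wx * X_s(q, b);
      }
    }
    double d = 0.0;
    vec xe(P, fill::zeros);
    for (uword q = pos; q <= end; ++q)
      if (s.ev(q) == 1.0) { d += 1.0; xe += X_s.row(q).t(); }
    if (d > 0.0 && S0 > 0.0) {
      vec mu = S1 / S0;
      g += xe - d * mu;
      for (uword a = 0; a < P; ++a)
        for (uword b = a; b < P; ++b)
          H(a, b) += d * (S2(a, b) / S0 - mu(a) * mu(b));
    }
    pos = end + 1;
  }
  H = symmatu(H);
}

// per-sample score u_i and diagonal-Hessian weight d_i (Breslow),
// used by the IRLS + coordinate-descent solver
static void breslow_diag(const vec& eta_s, const SurvOrder& s,
                         vec& u, vec& dw) {
  const uword N = eta_s.n_elem;
  double m = eta_s.max();
  vec w = exp(eta_s - m);
  vec cw = cumsum(w);
  // suffix sums over event blocks k with riskend_k >= i of d_k/S0_k, d_k/S0_k^2
  vec A(N, fill::zeros), B(N, fill::zeros);
  double accA = 0.0, accB = 0.0;
  uword i = N;
  while (i > 0) {
    --i;
    if (s.riskend(i) == i) {
      // i is the last position of its tie block: add this block's event mass
      uword end = i;
      uword start = end;
      while (start > 0 && s.riskend(start - 1) == end) --start;
      double d = 0.0;
      for (uword q = start; q <= end; ++q) if (s.ev(q) == 1.0) d += 1.0;
      double S0 = cw(end);
      if (d > 0.0 && S0 > 0.0) { accA += d / S0; accB += d / (S0 * S0); }
    }
    A(i) = accA;
    B(i) = accB;
  }
  u.set_size(N);
  dw.set_size(N);
  for (uword q = 0; q < N; ++q) {
    u(q)  = s.ev(q) - w(q) * A(q);
    dw(q) = w(q) * A(q) - w(q) * w(q) * B(q);
    if (dw(q) < 1e-10) dw(q) = 1e-10;
  }
}

static double pen_value(const vec& b, double l1, double l2) {
  return l1 * accu(abs(b)) + 0.5 * l2 * dot(b, b);
}

// minimize g(c) = l1w*A1/c + 0.5*l2w*A2/c^2 + l1b*Bb*c + 0.5*l2b*B2*c^2 over
// c > 0: the per-set penalty along the hazard-invariant scale manifold
// (a -> a/c, beta -> c*beta). Convex in c; golden-section on log-scale.
static double rebalance_scale(double A1, double A2, double Bb, double B2,
                              double l1w, double l2w, double l1b, double l2b) {
  auto g = [&](double c) {
    return l1w * A1 / c + 0.5 * l2w * A2 / (c * c) + l1b * Bb * c +
           0.5 * l2b * B2 * c * c;
  };
  double lo = std::log(1e-4), hi = std::log(1e4);
  const double gr = 0.618033988749895;
  double a = lo, b = hi;
  double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
  double f1 = g(std::exp(c1)), f2 = g(std::exp(c2));
  for (int k = 0; k < 60; ++k) {
    if (f1 < f2) { b = c2; c2 = c1; f2 = f1; c1 = b - gr * (b - a); f1 = g(std::exp(c1)); }
    else         { a = c1; c1 = c2; f1 = f2; c2 = a + gr * (b - a); f2 = g(std::exp(c2)); }
  }
  double c = std::exp(0.5 * (a + b));
  return (g(c) <= g(1.0)) ? c : 1.0;  // never accept a penalty increase
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// ---- penalized Cox fit -----------------------------------------------------

struct CoxFitRes {
  vec beta;
  double loglik;     // unpenalized, at solution
  double obj;        // penalized objective
  int iter;
  bool converged;
  bool separation;
};

// Newton with step halving; smooth penalty only (l1 == 0)
static CoxFitRes cox_newton(const mat& X_s, const SurvOrder& s,
                            double l2, vec beta, double tol, int maxit) {
  const uword P = X_s.n_cols;
  CoxFitRes r;
  r.separation = false;
  r.converged = false;
  vec eta = X_s * beta;
  double obj = breslow_loglik(eta, s) - 0.5 * l2 * dot(beta, beta);
  int it = 0;
  for (; it < maxit; ++it) {
    vec g;
    mat H;
    breslow_grad_hess(X_s, eta, s, g, H);
    vec gp = g - l2 * beta;
    if (abs(gp).max() < 1e-6) { r.converged = true; break; }
    mat Hp = H + (l2 + 1e-10) * eye(P, P);
    vec delta;
    if (!solve(delta, Hp, gp, solve_opts::likely_sympd + solve_opts::no_approx)) {
      solve(delta, Hp + 1e-6 * eye(P, P), gp);
    }
    double step = 1.0;
    double objn = obj;
    vec bn = beta;
    bool improved = false;
    for (int h = 0; h < 40; ++h) {
      bn = beta + step * delta;
      objn = breslow_loglik(X_s * bn, s) - 0.5 * l2 * dot(bn, bn);
      if (std::isfinite(objn) && objn >= obj - 1e-12) { improved = true; break; }
      step *= 0.5;
    }
    if (!improved) { r.converged = true; break; }  // no ascent direction left
    beta = bn;
    eta = X_s * beta;
    bool done = std::fabs(objn - obj) / (std::fabs(objn) + 1.0) < tol;
    obj = objn;
    if (done) { r.converged = true; ++it; break; }
  }
  if (norm(beta, 2) > 1e3) { r.separation = true; r.converged = false; }
  r.beta = beta;
  r.loglik = breslow_loglik(X_s * beta, s);
  r.obj = r.loglik - 0.5 * l2 * dot(beta, beta);
  r.iter = it;
  return r;
}

// IRLS + cyclic coordinate descent with soft-thresholding (l1 > 0);
// backtracks toward the previous iterate if the penalized objective drops.
static CoxFitRes cox_cd(const mat& X_s, const SurvOrder& s,
                        double l1, double l2, vec beta,
                        double tol, int maxit) {
  const uword N = X_s.n_rows, P = X_s.n_cols;
  CoxFitRes r;
  r.separation = false;
  r.converged = false;
  vec eta = X_s * beta;
  double obj = breslow_loglik(eta, s) - pen_value(beta, l1, l2);
  int it = 0;
  for (; it < maxit; ++it) {
    vec u, dw;
    breslow_diag(eta, s, u, dw);
    vec z = eta + u / dw;                       // working response
    // coordinate descent on 0.5*sum dw*(z - X b)^2 + pen
    vec bnew = beta;
    vec res = z - X_s * bnew;
    vec xx(P);
    for (uword j = 0; j < P; ++j) {
      double v = 0.0;
      for (uword q = 0; q < N; ++q) v += dw(q) * X_s(q, j) * X_s(q, j);
      xx(j) = v;
    }
    for (int sweep = 0; sweep < 50; ++sweep) {
      double maxdel = 0.0;
      for (uword j = 0; j < P; ++j) {
        if (xx(j) <= 0.0) continue;             // degenerate (all-zero) column
        double xr = 0.0;
        for (uword q = 0; q < N; ++q) xr += dw(q) * X_s(q, j) * res(q);
        double bj = soft(xr + xx(j) * bnew(j), l1) / (xx(j) + l2);
        double del = bj - bnew(j);
        if (del != 0.0) {
          res -= del * X_s.col(j);
          bnew(j) = bj;
          maxdel = std::max(maxdel, std::fabs(del));
        }
      }
      if (maxdel < 1e-9) break;
    }
    // accept only non-decreasing steps on the true penalized objective
    double objn = breslow_loglik(X_s * bnew, s) - pen_value(bnew, l1, l2);
    double step = 1.0;
    int h = 0;
    while ((!std::isfinite(objn) || objn < obj - 1e-12) && h < 30) {
      step *= 0.5;
      bnew = beta + step * (bnew - beta);
      objn = breslow_loglik(X_s * bnew, s) - pen_value(bnew, l1, l2);
      ++h;
    }
    if (!std::isfinite(objn) || objn < obj - 1e-12) { r.converged = true; break; }
    double maxch = abs(bnew - beta).max();
    beta = bnew;
    eta = X_s * beta;
    bool done = (std::fabs(objn - obj) / (std::fabs(objn) + 1.0) < tol) ||
                (maxch < 1e-8);
    obj = objn;
    if (done) { r.converged = true; ++it; break; }
  }
  if (norm(beta, 2) > 1e3) { r.separation = true; r.converged = false; }
  r.beta = beta;
  r.loglik = breslow_loglik(X_s * beta, s);
  r.obj = r.loglik - pen_value(beta, l1, l2);
  r.iter = it;
  return r;
}

static CoxFitRes cox_fit_core(const mat& X_s, const SurvOrder& s,
                              double l1, double l2, vec init,
                              double tol, int maxit) {
  if (l1 > 0.0) return cox_cd(X_s, s, l1, l2, init, tol, maxit);
  return cox_newton(X_s, s, l2, init, tol, maxit);
}

// ---- exported: partial likelihood and generic penalized fit ---------------

// [[Rcpp::export]]
double cpp_cox_loglik(const arma::mat& X, const arma::vec& beta,
                      const arma::vec& time, const arma::vec& event) {
  SurvOrder s = surv_order(time, event);
  mat X_s = X.rows(s.ord);
  return breslow_loglik(X_s * beta, s);
}

// [[Rcpp::export]]
Rcpp::List cpp_cox_fit(const arma::mat& X, const arma::vec& time,
                       const arma::vec& event, double l1, double l2,
                       const arma::vec& init, double tol, int maxit) {
  SurvOrder s = surv_order(time, event);
  mat X_s = X.rows(s.ord);
  CoxFitRes r = cox_fit_core(X_s, s, l1, l2, init, tol, maxit);
  return Rcpp::List::create(
      Rcpp::Named("coef") = r.beta,
      Rcpp::Named("loglik") = r.loglik,
      Rcpp::Named("objective") = r.obj,
      Rcpp::Named("iterations") = r.iter,
      Rcpp::Named("converged") = r.converged,
      Rcpp::Named("separation") = r.separation);
}

// observed information (negative Hessian of the log partial likelihood)
// [[Rcpp::export]]
arma::mat cpp_cox_info(const arma::mat& X, const arma::vec& beta,
                       const arma::vec& time, const arma::vec& event) {
  SurvOrder s = surv_order(time, event);
  mat X_s = X.rows(s.ord);
  vec g;
  mat H;
  breslow_grad_hess(X_s, X_s * beta, s, g, H);
  return H;
}

// max_j |score_j| at beta = 0: the smallest l1 with an all-zero solution
// [[Rcpp::export]]
double cpp_cox_lambda_max(const arma::mat& X, const arma::vec& time,
                          const arma::vec& event) {
  SurvOrder s = surv_order(time, event);
  mat X_s = X.rows(s.ord);
  vec g;
  mat H;
  breslow_grad_hess(X_s, vec(X.n_rows, fill::zeros), s, g, H);
  return abs(g).max();
}

// ---- structured-component ALS fitter ---------------------------------------

struct AlsPen { double l1w, l2w, l1b, l2b; };

struct AlsRes {
  vec beta, g0, w;
  std::vector<double> trace;  // phi after each half-step
  int iter;
  bool converged;
};

// Z: N x J miRNA columns (centered); Xh: N x M adjusted-mRNA columns
// (centered), setidx: 0-based set index per Xh column. All rows already in
// sorted (descending-time) order matching s.
static AlsRes als_core(const mat& Z_s, const mat& Xh_s, const uvec& setidx,
                       const SurvOrder& s, const AlsPen& p,
                       double tol, int maxit, bool want_trace,
                       int inner_maxit = 100) {
  const uword N = Z_s.n_rows, J = Z_s.n_cols, M = Xh_s.n_cols;
  AlsRes r;
  r.converged = false;

  // columns of Xh per set
  std::vector<std::vector<uword>> cols(J);
  for (uword m = 0; m < M; ++m) cols[setidx(m)].push_back(m);

  // init: gamma_j0 = 1/sd(z_j), w = 0 (components start near unit variance)
  vec g0(J), w(M, fill::zeros), beta(J, fill::zeros);
  for (uword j = 0; j < J; ++j) {
    double sd = stddev(Z_s.col(j));
    g0(j) = (sd > 0.0) ? 1.0 / sd : 1.0;
  }
  mat F(N, J);
  auto rebuild_F = [&](void) {
    for (uword j = 0; j < J; ++j) {
      vec f = g0(j) * Z_s.col(j);
      for (uword m : cols[j]) f += w(m) * Xh_s.col(m);
      F.col(j) = f;
    }
  };
  rebuild_F();

  // beta initialization: ridge Cox on the initial (standardized-z) components
  double l2init = (p.l1b == 0.0 && p.l2b > 0.0) ? p.l2b : 1.0;
  beta = cox_newton(F, s, l2init, beta, 1e-8, 20).beta;

  auto phi = [&](void) {
    vec a(J + M);
    a.subvec(0, J - 1) = g0;
    if (M > 0) a.subvec(J, J + M - 1) = w;
    return breslow_loglik(F * beta, s) - pen_value(a, p.l1w, p.l2w) -
           pen_value(beta, p.l1b, p.l2b);
  };

  double ph = phi();
  int it = 0;
  for (; it < maxit; ++it) {
    // beta-step: penalized Cox on the current components
    beta = cox_fit_core(F, s, p.l1b, p.l2b, beta, 1e-9, inner_maxit).beta;
    if (want_trace) r.trace.push_back(phi());

    // w-step: inner weights of active sets (beta_j != 0), columns scaled by beta_j
    std::vector<uword> act;
    for (uword j = 0; j < J; ++j) if (beta(j) != 0.0) act.push_back(j);
    if (!act.empty()) {
      uword Pj = 0;
      for (uword j : act) Pj += 1 + cols[j].size();
      mat D(N, Pj);
      vec a0(Pj);
      uword c = 0;
      for (uword j : act) {
        D.col(c) = beta(j) * Z_s.col(j);
        a0(c++) = g0(j);
        for (uword m : cols[j]) {
          D.col(c) = beta(j) * Xh_s.col(m);
          a0(c++) = w(m);
        }
      }
      // diagonal-IRLS coordinate solver: O(N P) per pass, monotone by
      // backtracking; exact inner maximization is unnecessary for block ascent
      vec a1 = cox_cd(D, s, p.l1w, p.l2w, a0, 1e-9, inner_maxit).beta;
      c = 0;
      for (uword j : act) {
        g0(j) = a1(c++);
        for (uword m : cols[j]) w(m) = a1(c++);
      }
    }
    // inactive sets: block optimum under a nonzero penalty is zero
    if (p.l1w + p.l2w > 0.0) {
      for (uword j = 0; j < J; ++j)
        if (beta(j) == 0.0) {
          g0(j) = 0.0;
          for (uword m : cols[j]) w(m) = 0.0;
        }
    }
    // scale rebalancing: per set, move along (a_j/c, c*beta_j), which leaves
    // the hazard fixed and minimizes the total penalty — strictly ascending
    // in phi and it removes the slow scale-trading direction of block ascent
    if (p.l1w + p.l2w > 0.0 && p.l1b + p.l2b > 0.0) {
      for (uword j = 0; j < J; ++j) {
        if (beta(j) == 0.0) continue;
        double A1 = std::fabs(g0(j)), A2 = g0(j) * g0(j);
        for (uword m : cols[j]) {
          A1 += std::fabs(w(m));
          A2 += w(m) * w(m);
        }
        if (A1 == 0.0) continue;
        double c = rebalance_scale(A1, A2, std::fabs(beta(j)),
                                   beta(j) * beta(j), p.l1w, p.l2w, p.l1b,
                                   p.l2b);
        g0(j) /= c;
        for (uword m : cols[j]) w(m) /= c;
        beta(j) *= c;
      }
    }
    rebuild_F();
    double ph2 = phi();
    if (want_trace) r.trace.push_back(ph2);
    if (std::fabs(ph2 - ph) / (std::fabs(ph2) + 1.0) < tol) {
      r.converged = true;
      ph = ph2;
      ++it;
      break;
    }
    ph = ph2;
  }
  r.beta = beta;
  r.g0 = g0;
  r.w = w;
  r.iter = it;
  return r;
}

// standardize: report beta on the unit-variance component scale with
// gamma_j0 >= 0 (sign fixed by the first nonzero inner weight if gamma is 0)
static void als_standardize(const mat& Z_s, const mat& Xh_s, const uvec& setidx,
                            AlsRes& r) {
  const uword N = Z_s.n_rows, J = Z_s.n_cols, M = Xh_s.n_cols;
  std::vector<std::vector<uword>> cols(J);
  for (uword m = 0; m < M; ++m) cols[setidx(m)].push_back(m);
  for (uword j = 0; j < J; ++j) {
    vec f = r.g0(j) * Z_s.col(j);
    for (uword m : cols[j]) f += r.w(m) * Xh_s.col(m);
    double sdev = (N > 1) ? stddev(f) : 0.0;
    if (sdev > 0.0) {
      r.beta(j) *= sdev;
      r.g0(j) /= sdev;
      for (uword m : cols[j]) r.w(m) /= sdev;
    } else {
      // vacuous component (inner weights all zero, e.g. emptied by a
      // selection penalty): it carries no covariate, so its effect is zero
      r.beta(j) = 0.0;
    }
    double sgn = 0.0;
    if (r.g0(j) != 0.0) sgn = (r.g0(j) > 0.0) ? 1.0 : -1.0;
    else
      for (uword m : cols[j])
        if (r.w(m) != 0.0) { sgn = (r.w(m) > 0.0) ? 1.0 : -1.0; break; }
    if (sgn < 0.0) {
      r.g0(j) = -r.g0(j);
      r.beta(j) = -r.beta(j);
      for (uword m : cols[j]) r.w(m) = -r.w(m);
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_als_fit(const arma::mat& Z, const arma::mat& Xh,
                       const arma::uvec& setidx, const arma::vec& time,
                       const arma::vec& event, double l1w, double l2w,
                       double l1b, double l2b, double tol, int maxit,
                       bool standardize, int inner_maxit) {
  SurvOrder s = surv_order(time, event);
  mat Z_s = Z.rows(s.ord);
  mat Xh_s = Xh.n_cols > 0 ? mat(Xh.rows(s.ord)) : mat(Z.n_rows, 0);
  AlsPen p{l1w, l2w, l1b, l2b};
  AlsRes r = als_core(Z_s, Xh_s, setidx, s, p, tol, maxit, true, inner_maxit);
  vec beta_raw = r.beta, g0_raw = r.g0, w_raw = r.w;
  if (standardize) als_standardize(Z_s, Xh_s, setidx, r);
  return Rcpp::List::create(
      Rcpp::Named("beta") = r.beta,
      Rcpp::Named("gamma0") = r.g0,
      Rcpp::Named("w") = r.w,
      Rcpp::Named("beta_raw") = beta_raw,
      Rcpp::Named("gamma0_raw") = g0_raw,
      Rcpp::Named("w_raw") = w_raw,
      Rcpp::Named("trace") = r.trace,
      Rcpp::Named("iterations") = r.iter,
      Rcpp::Named("converged") = r.converged);
}

// Permutation engine: refit the structured model for each permutation of the
// survival rows and each penalty configuration; returns standardized
// |beta|-ready estimates. pens: K x 4 matrix of (l1w, l2w, l1b, l2b).
// perms: N x B matrix of 0-based row indices into (time, event).
// [[Rcpp::export]]
arma::cube cpp_perm_betas(const arma::mat& Z, const arma::mat& Xh,
                          const arma::uvec& setidx, const arma::vec& time,
                          const arma::vec& event, const arma::umat& perms,
                          const arma::mat& pens, double tol, int maxit,
                          int inner_maxit) {
  const uword N = Z.n_rows, J = Z.n_cols, B = perms.n_cols, K = pens.n_rows;
  cube out(B, J, K);
  for (uword b = 0; b < B; ++b) {
    vec tp(N), ep(N);
    for (uword i = 0; i < N; ++i) {
      tp(i) = time(perms(i, b));
      ep(i) = event(perms(i, b));
    }
    SurvOrder s = surv_order(tp, ep);
    mat Z_s = Z.rows(s.ord);
    mat Xh_s = Xh.n_cols > 0 ? mat(Xh.rows(s.ord)) : mat(N, 0);
    for (uword k = 0; k < K; ++k) {
      AlsPen p{pens(k, 0), pens(k, 1), pens(k, 2), pens(k, 3)};
      AlsRes r = als_core(Z_s, Xh_s, setidx, s, p, tol, maxit, false,
                          inner_maxit);
      als_standardize(Z_s, Xh_s, setidx, r);
      for (uword j = 0; j < J; ++j) out(b, j, k) = r.beta(j);
    }
    if (b % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
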