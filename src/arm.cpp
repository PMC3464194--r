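// Two-joint planar arm: dynamics, finite-horizon discounted-effort optimal
// control (gradient method on the discrete-time problem, exact discrete
// adjoint, Barzilai-Borwein steps with backtracking, quadratic-penalty
// continuation on the terminal constraint), emergent-duration search, and
// the receding-horizon closed-loop simulator with a delayed-observation
// estimator and signal-dependent control noise.
//
// State x (12): theta[2], omega[2], a[4], e[4]. Control u (4).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Arm {
  double l1, l2, I1, I2, m1, m2, c1, c2, tau;
  mat AF;   // Amom * diag(Fmax), 2 x 4
  mat D;    // force-field matrix, 2 x 2
};

static Arm make_arm(const Rcpp::List& par) {
  Arm A;
  A.l1 = par["l1"]; A.l2 = par["l2"]; A.I1 = par["I1"]; A.I2 = par["I2"];
  A.m1 = par["m1"]; A.m2 = par["m2"]; A.c1 = par["c1"]; A.c2 = par["c2"];
  A.tau = par["tau"];
  mat Amom = Rcpp::as<mat>(par["Amom"]);
  vec Fmax = Rcpp::as<vec>(par["Fmax"]);
  A.AF = Amom * diagmat(Fmax);
  A.D = Rcpp::as<mat>(par["D"]);
  return A;
}

static inline void hand_jac(const Arm& A, double t1, double t2, mat& J) {
  double s1 = std::sin(t1), c1 = std::cos(t1);
  double s12 = std::sin(t1 + t2), c12 = std::cos(t1 + t2);
  J(0, 0) = -A.l1 * s1 - A.l2 * s12; J(0, 1) = -A.l2 * s12;
  J(1, 0) =  A.l1 * c1 + A.l2 * c12; J(1, 1) =  A.l2 * c12;
}

// joint accelerations given theta, omega and muscle torques
static inline void arm_acc(const Arm& A, const double* th, const double* om,
                           const vec& tq_mus, bool field, double* acc) {
  double ct = std::cos(th[1]), st = std::sin(th[1]);
  double m22 = A.I2 + A.m2 * A.c2 * A.c2;
  double blc = A.m2 * A.l1 * A.c2;
  double m11 = A.I1 + A.m1 * A.c1 * A.c1 + m22 +
               A.m2 * A.l1 * A.l1 + 2.0 * blc * ct;
  double m12 = m22 + blc * ct;
  double h = blc * st;
  double t1 = tq_mus(0) + h * (2.0 * om[0] * om[1] + om[1] * om[1]);
  double t2 = tq_mus(1) - h * om[0] * om[0];
  if (field) {
    mat J(2, 2);
    hand_jac(A, th[0], th[1], J);
    vec omv = {om[0], om[1]};
    vec tf = J.t() * (A.D * (J * omv));
    t1 += tf(0); t2 += tf(1);
  }
  double det = m11 * m22 - m12 * m12;
  acc[0] = ( m22 * t1 - m12 * t2) / det;
  acc[1] = (-m12 * t1 + m11 * t2) / det;
}

// full state derivative
static void arm_dyn(const Arm& A, const vec& x, const vec& u, bool field,
                    vec& dx) {
  vec tq = A.AF * x.subvec(4, 7);
  double acc[2];
  arm_acc(A, x.memptr(), x.memptr() + 2, tq, field, acc);
  dx(0) = x(2); dx(1) = x(3);
  dx(2) = acc[0]; dx(3) = acc[1];
  dx.subvec(4, 7) = (x.subvec(8, 11) - x.subvec(4, 7)) / A.tau;
  dx.subvec(8, 11) = (u - x.subvec(8, 11)) / A.tau;
}

// [[Rcpp::export]]
arma::vec arm_dyn_cpp(Rcpp::List par, arma::vec x, arma::vec u,
                      bool field_on = false) {
  Arm A = make_arm(par);
  vec dx(12);
  arm_dyn(A, x, u, field_on, dx);
  return dx;
}

// partials of the acceleration wrt (theta, omega) by central differences,
// and wrt activations analytically (M^{-1} AF)
static void acc_jacobians(const Arm& A, const vec& x, mat& Gth, mat& Gom,
                          mat& Ga) {
  const double hfd = 1e-6;
  vec tq = A.AF * x.subvec(4, 7);
  double thp[2], omp[2], ap[2], am2[2];
  for (int j = 0; j < 2; ++j) {
    thp[0] = x(0); thp[1] = x(1);
    thp[j] += hfd;
    arm_acc(A, thp, x.memptr() + 2, tq, false, ap);
    thp[j] -= 2 * hfd;
    arm_acc(A, thp, x.memptr() + 2, tq, false, am2);
    Gth(0, j) = (ap[0] - am2[0]) / (2 * hfd);
    Gth(1, j) = (ap[1] - am2[1]) / (2 * hfd);
    omp[0] = x(2); omp[1] = x(3);
    omp[j] += hfd;
    arm_acc(A, x.memptr(), omp, tq, false, ap);
    omp[j] -= 2 * hfd;
    arm_acc(A, x.memptr(), omp, tq, false, am2);
    Gom(0, j) = (ap[0] - am2[0]) / (2 * hfd);
    Gom(1, j) = (ap[1] - am2[1]) / (2 * hfd);
  }
  double ct = std::cos(x(1));
  double m22 = A.I2 + A.m2 * A.c2 * A.c2;
  double blc = A.m2 * A.l1 * A.c2;
  double m11 = A.I1 + A.m1 * A.c1 * A.c1 + m22 +
               A.m2 * A.l1 * A.l1 + 2.0 * blc * ct;
  double m12 = m22 + blc * ct;
  double det = m11 * m22 - m12 * m12;
  mat Minv = {{m22 / det, -m12 / det}, {-m12 / det, m11 / det}};
  Ga = Minv * A.AF;
}

struct OcpWork {
  mat X;        // (n+1) x 12 states
  vec disc;     // exp(-k t_i), length n
  double cost_eff, cost_pen, term_err;
};

// forward rollout + cost under penalty weight mu
static double ocp_forward(const Arm& A, const mat& U, const vec& x0,
                          const vec& xs, const vec& w, double eta,
                          double eps, double mu, OcpWork& wk) {
  int n = U.n_rows;
  vec x = x0, dx(12);
  wk.X.row(0) = x.t();
  double ce = 0.0;
  for (int i = 0; i < n; ++i) {
    vec u = U.row(i).t();
    ce += eta * eps * wk.disc(i) * dot(u, u);
    arm_dyn(A, x, u, false, dx);
    x += eta * dx;
    wk.X.row(i + 1) = x.t();
  }
  vec del = x - xs;
  wk.cost_eff = ce;
  wk.cost_pen = 0.5 * mu * dot(w % del, del);
  return ce + wk.cost_pen;
}

// exact gradient of the discrete cost via the adjoint recursion
static void ocp_gradient(const Arm& A, const mat& U, const vec& xs,
                         const vec& w, double eta, double eps, double mu,
                         const OcpWork& wk, mat& G) {
  int n = U.n_rows;
  vec del = wk.X.row(n).t() - xs;
  vec lam = mu * (w % del);
  mat Gth(2, 2), Gom(2, 2), Ga(2, 4);
  for (int i = n - 1; i >= 0; --i) {
    // gradient wrt u_i uses lambda_{i+1}
    G.row(i) = (2.0 * eta * eps * wk.disc(i)) * U.row(i) +
               (eta / A.tau) * lam.subvec(8, 11).t();
    // lambda_i = lambda_{i+1} + eta * Jx' lambda_{i+1}
    vec x = wk.X.row(i).t();
    acc_jacobians(A, x, Gth, Gom, Ga);
    vec lth = lam.subvec(0, 1), lom = lam.subvec(2, 3);
    vec la = lam.subvec(4, 7), le = lam.subvec(8, 11);
    vec nth = Gth.t() * lom;
    vec nom = lth + Gom.t() * lom;
    vec na = Ga.t() * lom - la / A.tau;
    vec ne = (la - le) / A.tau;
    lam.subvec(0, 1) += eta * nth;
    lam.subvec(2, 3) += eta * nom;
    lam.subvec(4, 7) += eta * na;
    lam.subvec(8, 11) += eta * ne;
  }
}

static double hand_term_err(const Arm& A, const vec& xN, const vec& xs,
                            double w_mus = 0.1) {
  mat J(2, 2);
  double p1[2], p2[2];
  p1[0] = A.l1 * std::cos(xN(0)) + A.l2 * std::cos(xN(0) + xN(1));
  p1[1] = A.l1 * std::sin(xN(0)) + A.l2 * std::sin(xN(0) + xN(1));
  p2[0] = A.l1 * std::cos(xs(0)) + A.l2 * std::cos(xs(0) + xs(1));
  p2[1] = A.l1 * std::sin(xs(0)) + A.l2 * std::sin(xs(0) + xs(1));
  hand_jac(A, xN(0), xN(1), J);
  vec hv = J * xN.subvec(2, 3);
  double ep = std::hypot(p1[0] - p2[0], p1[1] - p2[1]);
  double ev = norm(hv, 2);
  double em = std::max(abs(xN.subvec(4, 7)).max(), abs(xN.subvec(8, 11)).max());
  return std::max({ep, 0.2 * ev, w_mus * em});
}

struct OcpResult {
  mat U, X;
  double J_u, cost, gnorm, term_err, mu;
  int iters;
  bool converged;
};

// BB-gradient solve at fixed horizon; U is the warm start (resized outside).
// mu_start lets warm-started calls resume at the penalty stage that already
// satisfied the terminal constraint, skipping the continuation ladder.
static OcpResult ocp_solve(const Arm& A, const vec& x0, const vec& xs,
                           double T, double gamma, double eps, double eta,
                           mat U, double tol_term, int max_iter,
                           double mu_start = 1e2, double w_mus = 0.1) {
  int n = std::max(2, (int)std::lround(T / eta));
  if ((int)U.n_rows != n) U.resize(n, 4);
  double k = 1.0 / gamma;
  OcpWork wk;
  wk.X.set_size(n + 1, 12);
  wk.disc.set_size(n);
  for (int i = 0; i < n; ++i) wk.disc(i) = std::exp(-k * eta * i);
  vec w = {1, 1, 0.1, 0.1, w_mus, w_mus, w_mus, w_mus,
           w_mus, w_mus, w_mus, w_mus};

  double mu = std::min(std::max(mu_start, 1e2), 1e10);
  mat G(n, 4), Gprev(n, 4), Uprev(n, 4);
  double cost = ocp_forward(A, U, x0, xs, w, eta, eps, mu, wk);
  int it_total = 0;
  bool ok = false;
  for (int outer = 0; outer < 10; ++outer) {
    ocp_gradient(A, U, xs, w, eta, eps, mu, wk, G);
    double alpha = 1e-2 / std::max(1e-12, abs(G).max());
    int stall = 0;
    for (int it = 0; it < max_iter; ++it) {
      ++it_total;
      mat Ut = U - alpha * G;
      OcpWork wk2 = wk;
      double ct = ocp_forward(A, Ut, x0, xs, w, eta, eps, mu, wk2);
      int bt = 0;
      double gg = accu(G % G);
      while (ct > cost - 1e-4 * alpha * gg && bt < 40) {
        alpha *= 0.5; ++bt;
        Ut = U - alpha * G;
        ct = ocp_forward(A, Ut, x0, xs, w, eta, eps, mu, wk2);
      }
      if (bt >= 40) break;
      Uprev = U; Gprev = G;
      U = Ut; wk = wk2;
      double prev_cost = cost;
      cost = ct;
      ocp_gradient(A, U, xs, w, eta, eps, mu, wk, G);
      // Barzilai-Borwein step (type 2), safeguarded
      mat dU = U - Uprev, dG = G - Gprev;
      double num = accu(dU % dG), den = accu(dG % dG);
      alpha = (den > 1e-300 && num > 0) ? num / den
                                        : 2.0 * alpha;
      alpha = std::min(std::max(alpha, 1e-10), 1e4);
      double gmax = abs(G).max();
      if (gmax < 1e-6 * (1.0 + std::abs(cost))) break;
      if (std::abs(prev_cost - cost) < 1e-12 * (1.0 + std::abs(cost))) {
        if (++stall > 3) break;
      } else stall = 0;
    }
    double terr = hand_term_err(A, wk.X.row(n).t(), xs, w_mus);
    if (terr < tol_term) { ok = true; break; }
    if (mu > 1e10) break;
    mu *= 10.0;
    cost = ocp_forward(A, U, x0, xs, w, eta, eps, mu, wk);
  }
  OcpResult res;
  res.U = U; res.X = wk.X;
  res.J_u = wk.cost_eff; res.cost = cost;
  res.gnorm = abs(G).max();
  res.term_err = hand_term_err(A, wk.X.row((int)U.n_rows).t(), xs, w_mus);
  res.mu = mu;
  res.iters = it_total;
  res.converged = ok;
  return res;
}

// warm-start context shared across neighboring solves
struct WarmCtx { mat U; double mu = 1e2; };

// resample a control path to n rows by linear interpolation (warm starting
// across horizons)
static mat resample_U(const mat& U, int n) {
  int m = U.n_rows;
  if (m == n) return U;
  mat V(n, 4);
  if (m < 2) { V.zeros(); return V; }
  for (int i = 0; i < n; ++i) {
    double s = (double)i * (m - 1) / std::max(1, n - 1);
    int j = std::min((int)std::floor(s), m - 2);
    double f = s - j;
    V.row(i) = (1 - f) * U.row(j) + f * U.row(j + 1);
  }
  return V;
}

// [[Rcpp::export]]
Rcpp::List arm_ocp_cpp(Rcpp::List par, arma::vec x0, arma::vec xs, double T,
                       double gamma, double eps, double eta = 1e-3,
                       Rcpp::Nullable<Rcpp::NumericMatrix> U0 = R_NilValue,
                       double tol_term = 1e-3, int max_iter = 3000,
                       double w_mus = 0.1) {
  Arm A = make_arm(par);
  int n = std::max(2, (int)std::lround(T / eta));
  mat U(n, 4, fill::zeros);
  if (U0.isNotNull()) U = resample_U(Rcpp::as<mat>(U0.get()), n);
  OcpResult r = ocp_solve(A, x0, xs, T, gamma, eps, eta, U, tol_term,
                          max_iter, 1e2, w_mus);
  return Rcpp::List::create(
      Rcpp::Named("U") = r.U, Rcpp::Named("X") = r.X,
      Rcpp::Named("J_u") = r.J_u, Rcpp::Named("cost") = r.cost,
      Rcpp::Named("grad_norm") = r.gnorm,
      Rcpp::Named("term_err") = r.term_err,
      Rcpp::Named("iters") = r.iters,
      Rcpp::Named("converged") = r.converged);
}

// utility of acting in horizon T from x0 (solves the OCP)
static double arm_utility(const Arm& A, const vec& x0, const vec& xs,
                          double T, double gamma, double eps, double eta,
                          double rho_r, WarmCtx& ws, double& J_u,
                          int max_iter) {
  int n = std::max(2, (int)std::lround(T / eta));
  mat U = resample_U(ws.U, n);
  OcpResult r = ocp_solve(A, x0, xs, T, gamma, eps, eta, U, 1e-3, max_iter,
                          ws.mu);
  ws.U = r.U;
  // carry the penalty stage forward only from feasible solves; a failed
  // short-horizon solve must not poison its neighbors
  ws.mu = r.converged ? r.mu : 1e2;
  J_u = r.J_u;
  return rho_r * std::exp(-T / gamma) - r.J_u;
}

struct DurResult { double T, utility, J_u; mat U; double mu; };

// golden-section duration search with warm-started solves
static DurResult arm_duration(const Arm& A, const vec& x0, const vec& xs,
                              double gamma, double eps, double eta,
                              double rho_r, double Tlo, double Thi,
                              const WarmCtx& init, bool prescan, int max_iter,
                              double tol = 1e-3) {
  WarmCtx Uws = init;
  double Ju;
  double a = Tlo, b = Thi;
  if (prescan) {
    int np = 12;
    double best = -datum::inf, bestT = Tlo;
    WarmCtx bestU;
    int pre_iter = std::max(80, max_iter / 4);   // coarse bracket location
    for (int i = np - 1; i >= 0; --i) {          // long (easy) horizons first
      double T = std::exp(std::log(Tlo) +
                          (std::log(Thi) - std::log(Tlo)) * i / (np - 1.0));
      double v = arm_utility(A, x0, xs, T, gamma, eps, eta, rho_r, Uws, Ju, pre_iter);
      if (v > best) { best = v; bestT = T; bestU = Uws; }
    }
    double fac = std::pow(Thi / Tlo, 1.0 / (np - 1.0));
    a = std::max(Tlo, bestT / fac);
    b = std::min(Thi, bestT * fac);
    Uws = bestU;
  }
  const double gr = 0.6180339887498949;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = arm_utility(A, x0, xs, x1, gamma, eps, eta, rho_r, Uws, Ju, max_iter);
  double f2 = arm_utility(A, x0, xs, x2, gamma, eps, eta, rho_r, Uws, Ju, max_iter);
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = arm_utility(A, x0, xs, x2, gamma, eps, eta, rho_r, Uws, Ju, max_iter);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = arm_utility(A, x0, xs, x1, gamma, eps, eta, rho_r, Uws, Ju, max_iter);
    }
  }
  DurResult res;
  res.T = 0.5 * (a + b);
  res.utility = arm_utility(A, x0, xs, res.T, gamma, eps, eta, rho_r, Uws,
                            Ju, max_iter);
  res.J_u = Ju;
  res.U = Uws.U;
  res.mu = Uws.mu;
  return res;
}

// [[Rcpp::export]]
Rcpp::List arm_duration_cpp(Rcpp::List par, arma::vec x0, arma::vec xs,
                            double gamma, double eps, double rho_r,
                            double eta = 1e-3, double Tlo = 0.05,
                            double Thi = 3.0, int max_iter = 800) {
  Arm A = make_arm(par);
  WarmCtx ws;
  DurResult r = arm_duration(A, x0, xs, gamma, eps, eta, rho_r, Tlo, Thi,
                             ws, true, max_iter);
  return Rcpp::List::create(
      Rcpp::Named("T") = r.T, Rcpp::Named("utility") = r.utility,
      Rcpp::Named("J_u") = r.J_u, Rcpp::Named("U") = r.U);
}

// [[Rcpp::export]]
Rcpp::List arm_sim_cpp(Rcpp::List par, arma::vec x0, arma::vec xs,
                       double gamma, double eps, double rho_r,
                       double eta, int delay_steps, double sdn,
                       double sin_sd, int nmax, int replan_every,
                       int refresh_every, int jump_step, arma::vec xs2,
                       int field_from, double Tmin, double Tmax,
                       int max_iter_warm = 120, int max_iter_cold = 800) {
  Rcpp::RNGScope rng;
  Arm A = make_arm(par);
  vec goal = xs;
  bool noisy = (sdn > 0) || (sin_sd > 0);

  // histories
  mat th_hist(nmax + 1, 4);          // true theta, omega
  mat mus_model(nmax + 1, 8);        // forward-model muscle states
  mat u_hist(nmax, 4, fill::zeros);  // commanded controls

  vec x = x0, dx(12), xmodel = x0;
  th_hist.row(0) = x.subvec(0, 3).t();
  mus_model.row(0) = x0.subvec(4, 11).t();

  // initial plan
  WarmCtx ws;
  DurResult plan = arm_duration(A, x0, goal, gamma, eps, eta, rho_r,
                                Tmin, Tmax, ws, true, max_iter_cold);
  ws.U = plan.U; ws.mu = plan.mu;
  double T_go = plan.T;
  mat U_plan = plan.U;
  int idx = 0;
  bool viable = plan.utility > 0;

  mat trace(nmax, 1 + 4 + 2 + 2 + 1 + 4 + 2);
  // cols: t, th1, th2, om1, om2, hx, hy, hvx, hvy, speed, u1..u4, Tgo, util

  double utility_now = plan.utility;
  for (int j = 0; j < nmax; ++j) {
    bool replan_now = (j > 0) && (j % replan_every == 0);
    if (j == jump_step) { goal = xs2; replan_now = true; }
    if (replan_now) {
      // estimate current state
      vec xh(12);
      if (!noisy && delay_steps == 0) {
        xh = x;
      } else if (j < delay_steps) {
        xh = xmodel;
      } else {
        vec xd(12);
        int jd = j - delay_steps;
        xd.subvec(0, 3) = th_hist.row(jd).t();
        if (sin_sd > 0)
          for (int q = 0; q < 4; ++q) xd(q) += sin_sd * R::norm_rand();
        xd.subvec(4, 11) = mus_model.row(jd).t();
        for (int i = jd; i < j; ++i) {
          arm_dyn(A, xd, u_hist.row(i).t(), false, dx);
          xd += eta * dx;
        }
        xh = xd;
      }
      // warm start from the unconsumed tail of the current plan
      mat Utail = (idx < (int)U_plan.n_rows)
                    ? U_plan.rows(idx, U_plan.n_rows - 1)
                    : mat(2, 4, fill::zeros);
      ws.U = Utail;
      if (j == jump_step) {
        // full re-search after a perceived goal change
        DurResult r = arm_duration(A, xh, goal, gamma, eps, eta, rho_r,
                                   Tmin, Tmax, ws, true, max_iter_cold);
        T_go = r.T; U_plan = r.U; utility_now = r.utility;
        ws.U = r.U; ws.mu = r.mu;
        viable = r.utility > 0;
      } else if (refresh_every > 0 && (j % refresh_every == 0)) {
        double lo = std::max(Tmin, T_go - 0.04);
        double hi = std::min(Tmax, std::max(T_go + 0.04, lo + 0.01));
        DurResult r = arm_duration(A, xh, goal, gamma, eps, eta, rho_r,
                                   lo, hi, ws, false, max_iter_warm);
        T_go = r.T; U_plan = r.U; utility_now = r.utility;
        ws.U = r.U; ws.mu = r.mu;
        viable = r.utility > 0;
      } else {
        int n = std::max(2, (int)std::lround(T_go / eta));
        mat Uw = resample_U(Utail, n);
        OcpResult r = ocp_solve(A, xh, goal, T_go, gamma, eps, eta, Uw,
                                1e-3, max_iter_warm, ws.mu);
        U_plan = r.U; ws.U = r.U;
        ws.mu = r.converged ? r.mu : 1e2;
        utility_now = rho_r * std::exp(-T_go / gamma) - r.J_u;
        viable = utility_now > 0;
      }
      idx = 0;
    }
    vec u = (viable && idx < (int)U_plan.n_rows)
              ? U_plan.row(idx).t() : vec(4, fill::zeros);
    u_hist.row(j) = u.t();
    // forward-model muscle states under the commanded control
    vec am = mus_model.row(j).t();
    vec am2(8);
    am2.subvec(0, 3) = am.subvec(0, 3) +
      (eta / A.tau) * (am.subvec(4, 7) - am.subvec(0, 3));
    am2.subvec(4, 7) = am.subvec(4, 7) + (eta / A.tau) * (u - am.subvec(4, 7));
    mus_model.row(j + 1) = am2.t();
    // pure prediction (used before observations arrive)
    arm_dyn(A, xmodel, u, false, dx);
    xmodel += eta * dx;
    // true plant step with signal-dependent control noise
    vec un = u;
    if (sdn > 0)
      for (int q = 0; q < 4; ++q)
        un(q) += sdn * std::abs(u(q)) * R::norm_rand();
    bool field = (field_from >= 0) && (j >= field_from);
    arm_dyn(A, x, un, field, dx);
    // record before stepping (state at time t_j)
    mat J(2, 2);
    hand_jac(A, x(0), x(1), J);
    vec hv = J * x.subvec(2, 3);
    double hx = A.l1 * std::cos(x(0)) + A.l2 * std::cos(x(0) + x(1));
    double hy = A.l1 * std::sin(x(0)) + A.l2 * std::sin(x(0) + x(1));
    trace(j, 0) = j * eta;
    trace(j, 1) = x(0); trace(j, 2) = x(1);
    trace(j, 3) = x(2); trace(j, 4) = x(3);
    trace(j, 5) = hx; trace(j, 6) = hy;
    trace(j, 7) = hv(0); trace(j, 8) = hv(1);
    trace(j, 9) = norm(hv, 2);
    for (int q = 0; q < 4; ++q) trace(j, 10 + q) = u(q);
    trace(j, 14) = T_go;
    trace(j, 15) = utility_now;
    x += eta * dx;
    th_hist.row(j + 1) = x.subvec(0, 3).t();
    T_go = std::max(Tmin, T_go - eta);
    ++idx;
  }
  return Rcpp::List::create(Rcpp::Named("trace") = trace,
                            Rcpp::Named("T_plan") = plan.T,
                            Rcpp::Named("utility_plan") = plan.utility,
                            Rcpp::Named("J_u_plan") = plan.J_u);
}
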