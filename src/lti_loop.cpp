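// Receding-horizon closed loop for the linear plants. All horizon-dependent
// quantities are precomputed on the eta grid:
//   W_i   discounted controllability Gramian at horizon t_i
//   E_i   = exp(A t_i)
//   g_i   = exp(-k t_i) B' E_i' W_i^{-1}   (first-instant control gain row)
// so that per step the controller scans J(i) = e^{-k t_i} (rho r -
// eps d' W_i^{-1} d) with d = x* - E_i xhat over a window around the previous
// optimum and applies u = g_i d. The estimator is a delayed-observation
// Kalman filter (observation = position and velocity, delay Delta), bridged
// to current time with the stored-control convolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List lti_precompute_cpp(arma::mat A, arma::mat B, double k, double eta,
                              int N, arma::mat V, arma::mat Eeta) {
  int n = A.n_rows;
  cube E(n, n, N + 1), Minv(n, n, N + 1);
  mat gains(N + 1, n, fill::zeros);
  vec ek(N + 1), valid(N + 1, fill::zeros);
  mat W(n, n, fill::zeros), Ei(n, n, fill::eye);
  E.slice(0) = Ei;
  ek(0) = 1.0;
  for (int i = 1; i <= N; ++i) {
    double ti = (i - 1) * eta;
    W += std::exp(-k * ti) * Ei * V * Ei.t();
    W = 0.5 * (W + W.t());
    Ei = Ei * Eeta;
    E.slice(i) = Ei;
    ek(i) = std::exp(-k * i * eta);
    mat Wi;
    bool ok = inv_sympd(Wi, W);
    if (ok && Wi.is_finite()) {
      Minv.slice(i) = Wi;
      gains.row(i) = ek(i) * (B.t() * Ei.t() * Wi);
      valid(i) = 1.0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("E") = E, Rcpp::Named("Minv") = Minv,
                            Rcpp::Named("gains") = gains,
                            Rcpp::Named("ek") = ek,
                            Rcpp::Named("valid") = valid);
}

// [[Rcpp::export]]
Rcpp::List lti_sim_cpp(Rcpp::List pre, arma::mat Ad, arma::mat Bd,
                       arma::mat H, arma::vec x0, arma::vec xs,
                       double rho_r, double eps, double eta, int d,
                       double sdn, double sin_sd, int nmax, int imin,
                       int nwin = 30) {
  Rcpp::RNGScope rng;
  cube E = Rcpp::as<cube>(pre["E"]);
  cube Minv = Rcpp::as<cube>(pre["Minv"]);
  mat gains = Rcpp::as<mat>(pre["gains"]);
  vec ek = Rcpp::as<vec>(pre["ek"]);
  vec valid = Rcpp::as<vec>(pre["valid"]);
  int N = E.n_slices - 1;
  int n = Ad.n_rows, m = H.n_rows;

  bool noisy = (sdn > 0) || (sin_sd > 0);
  mat x_hist(nmax + 1, n);
  mat u_hist(nmax, 1, fill::zeros);
  vec x = x0, xh = x0;
  x_hist.row(0) = x.t();

  // delayed Kalman filter state
  vec xd = x0;
  mat Pd(n, n, fill::zeros);
  mat Robs = sin_sd * sin_sd * eye(m, m);
  mat Add = eye(n, n);
  for (int i = 0; i < d; ++i) Add = Add * Ad;
  mat Qd1 = Bd * Bd.t();
  vec csum(n, fill::zeros);
  bool csum_init = false;

  auto scanJ = [&](const vec& xhat, int lo, int hi, int& ibest,
                   double& Jbest) {
    lo = std::max(lo, imin); hi = std::min(hi, N);
    ibest = -1; Jbest = -datum::inf;
    for (int i = lo; i <= hi; ++i) {
      if (valid(i) == 0) continue;
      vec dd = xs - E.slice(i) * xhat;
      double J = ek(i) * (rho_r - eps * dot(dd, Minv.slice(i) * dd));
      if (J > Jbest) { Jbest = J; ibest = i; }
    }
  };

  int iprev = -1;
  mat trace(nmax, 1 + n + n + 1 + 2);
  for (int j = 0; j < nmax; ++j) {
    // ----- estimate -----
    if (!noisy && d == 0) {
      xh = x;
    } else if (j < d) {
      // no observation yet: pure forward model (exact under zero noise)
      // xh propagated below after control is chosen
    } else {
      if (j == d) {
        // first observation: xd is x0 exactly, P stays 0 after update
        csum.zeros();
        mat Ap = eye(n, n);
        for (int i = d - 1; i >= 0; --i) {
          csum += Ap * (Bd * u_hist.row(i).t());
          Ap = Ap * Ad;
        }
        csum_init = true;
      } else {
        // predict delayed estimate one step with the stored control
        vec ud = u_hist.row(j - d - 1).t();
        xd = Ad * xd + Bd * ud;
        double su = sdn * std::abs(ud(0));
        Pd = Ad * Pd * Ad.t() + (su * su) * Qd1;
        Pd = 0.5 * (Pd + Pd.t());
      }
      // observation of the state at time j - d
      vec y = H * x_hist.row(j - d).t();
      if (sin_sd > 0)
        for (int q = 0; q < m; ++q) y(q) += sin_sd * R::norm_rand();
      mat S = H * Pd * H.t() + Robs;
      if (sin_sd > 0) {
        mat K = Pd * H.t() * inv_sympd(S);
        xd += K * (y - H * xd);
        Pd = (eye(n, n) - K * H) * Pd;
        Pd = 0.5 * (Pd + Pd.t());
      } else {
        // noiseless observation: substitute observed components
        xd.subvec(0, m - 1) = y;
        Pd.zeros();
      }
      xh = Add * xd + csum;
    }
    // ----- duration + control -----
    int ibest; double Jbest;
    if (iprev < 0) scanJ(xh, imin, N, ibest, Jbest);
    else {
      scanJ(xh, iprev - nwin, iprev + nwin, ibest, Jbest);
      while (ibest >= 0 &&
             (ibest == std::max(iprev - nwin, imin) ||
              ibest == std::min(iprev + nwin, N)) ) {
        int lo = std::max(imin, ibest - 4 * nwin);
        int hi = std::min(N, ibest + 4 * nwin);
        int ib2; double Jb2;
        scanJ(xh, lo, hi, ib2, Jb2);
        if (ib2 == ibest) break;
        ibest = ib2; Jbest = Jb2;
        if (lo == imin && hi == N) break;
      }
    }
    double u = 0.0;
    bool viable = (ibest >= 0) && (Jbest > 0);
    if (viable) {
      vec dd = xs - E.slice(ibest) * xh;
      u = dot(gains.row(ibest).t(), dd);
      iprev = ibest;
    }
    u_hist(j, 0) = u;
    // record state at t_j
    trace(j, 0) = j * eta;
    for (int q = 0; q < n; ++q) trace(j, 1 + q) = x(q);
    for (int q = 0; q < n; ++q) trace(j, 1 + n + q) = xh(q);
    trace(j, 1 + 2 * n) = u;
    trace(j, 2 + 2 * n) = viable ? ibest * eta : NA_REAL;
    trace(j, 3 + 2 * n) = Jbest;
    // ----- step the plant -----
    double un = u;
    if (sdn > 0) un += sdn * std::abs(u) * R::norm_rand();
    x = Ad * x + Bd * un;
    x_hist.row(j + 1) = x.t();
    if (noisy && j < d) {
      // pure forward model before the first observation
      xh = Ad * xh + Bd * u;
    } else if (csum_init) {
      csum = Ad * csum + Bd * u;
      if (j >= d) csum -= Add * (Bd * u_hist.row(j - d).t());
    }
  }
  return Rcpp::List::create(Rcpp::Named("trace") = trace);
}
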