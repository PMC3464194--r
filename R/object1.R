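# Closed-form discounted-effort optimal control for the point mass.
#
# Finite-horizon problem: minimize eps * int_0^T exp(-s/gamma) u(s)^2 ds
# subject to p' = v, m v' = u, x(0) = (0,0), x(T) = (A,0).
#
# Pontryagin with the discounted integrand gives u*(t) proportional to
# exp(t/gamma) times a linear function of t. Writing nu = lambda(T) and
# W(T) = int_0^T exp(-ks) e^{As} B B' e^{A's} ds (k = 1/gamma), the minimal
# cost is
#     J_u(T) = eps exp(-kT) d' W(T)^{-1} d,   d = x* - e^{AT} x0,
# and for the double integrator W reduces to exponential moments
# J_n = int_0^T s^n exp(-ks) ds:
#     J_u(T) = eps exp(-kT) A^2 m^2 J0 / (J2 J0 - J1^2).
# Stationarity of J_inf(T) = rho r exp(-kT) - J_u(T) in T gives the optimal
# duration as the root of  vigor * r = Psi(T)  with
#     Psi(T) = A^2 m^2 [ J0/D + exp(-kT) (J1 - T J0)^2 / (k D^2) ],
#     D = J2 J0 - J1^2,
# which is the analytic amplitude/reward/vigor/discount duration law
# T*(A, r, rho/eps, gamma).

# exponential moments J0, J1, J2 with a series fallback for small k*T
exp_moments <- function(T, k) {
  x <- k * T
  if (x > 1e-4) {
    e <- exp(-x)
    c((1 - e) / k,
      (1 - e * (1 + x)) / k^2,
      (2 - e * (2 + 2 * x + x^2)) / k^3)
  } else {
    c(T * (1 - x / 2 + x^2 / 6 - x^3 / 24),
      T^2 * (1 / 2 - x / 3 + x^2 / 8 - x^3 / 30),
      T^3 * (1 / 3 - x / 4 + x^2 / 10 - x^3 / 36))
  }
}

#' Discounted effort of the optimal point-to-point point-mass movement
#'
#' The minimal value of \eqn{\epsilon\int_0^T e^{-s/\gamma} u(s)^2 ds} for a
#' rest-to-rest displacement of amplitude `A` in time `T`, in closed form.
#' In the undiscounted limit it reduces to the classical minimum-effort cost
#' \eqn{12 A^2 m^2 / T^3}.
#'
#' @param T movement duration (s).
#' @param A displacement amplitude (m).
#' @param gamma discount time constant (s).
#' @param eps effort scaling factor.
#' @param m mass (kg).
#' @return discounted effort (utility units).
#' @export
point_mass_effort <- function(T, A, gamma, eps = 1, m = 1) {
  stopifnot(all(T > 0), gamma > 0, eps > 0, m > 0)
  k <- 1 / gamma
  one <- function(T) {
    J <- exp_moments(T, k)
    exp(-k * T) * J[1] / (J[3] * J[1] - J[2]^2)
  }
  eps * A^2 * m^2 * vapply(T, one, numeric(1))
}

#' Discounted utility of a point-mass displacement as a function of duration
#'
#' \eqn{J_\infty(T) = \rho r e^{-T/\gamma} - J_u(T)} with \eqn{\rho =
#' \mathrm{vigor}\times\epsilon}; only the vigor ratio and `eps` scale enter.
#'
#' @inheritParams point_mass_effort
#' @param r reward magnitude.
#' @param vigor reward/effort valuation ratio (rho/eps).
#' @return utility (utility units); at `T -> 0+` with `A = 0` it approaches
#'   `eps * vigor * r`.
#' @export
point_mass_utility <- function(T, A, r, vigor, gamma, eps = 1, m = 1) {
  stopifnot(all(T > 0), gamma > 0, vigor > 0)
  eps * vigor * r * exp(-T / gamma) -
    point_mass_effort(T, A, gamma, eps = eps, m = m)
}

# marginal-effort law Psi(T): stationarity reads vigor * r = Psi(T)
.psi_point_mass <- function(T, A, k, m = 1) {
  J <- exp_moments(T, k)
  D <- J[3] * J[1] - J[2]^2
  A^2 * m^2 * (J[1] / D + exp(-k * T) * (J[2] - T * J[1])^2 / (k * D^2))
}

#' Closed-form optimal movement duration for the point mass
#'
#' Solves the stationarity condition of the discounted reward-minus-effort
#' objective analytically (root of the marginal law `vigor * r = Psi(T)`).
#' A stationary point exists iff `vigor * r > A^2 m^2 / gamma^3`; otherwise
#' the utility is negative for every duration and no viable action exists.
#'
#' @inheritParams point_mass_utility
#' @return list with `T` (s), `utility`, and logical `viable`. For `A = 0`,
#'   `T = 0` and `utility = eps * vigor * r`.
#' @export
closed_form_duration <- function(A, r, vigor, gamma, eps = 1, m = 1) {
  stopifnot(A >= 0, r > 0, vigor > 0, gamma > 0)
  if (A == 0) return(list(T = 0, utility = eps * vigor * r, viable = TRUE))
  k <- 1 / gamma
  if (vigor * r <= A^2 * m^2 * k^3)
    return(list(T = NA_real_, utility = NA_real_, viable = FALSE))
  f <- function(T) .psi_point_mass(T, A, k, m) - vigor * r
  hi <- 1
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  Tstar <- uniroot(f, c(1e-6, hi), tol = 1e-12)$root
  list(T = Tstar,
       utility = point_mass_utility(Tstar, A, r, vigor, gamma, eps, m),
       viable = TRUE)
}

# vigor implied by one (A, r, T) condition at a given gamma
.vigor_implied <- function(gamma, A, r, T, m = 1) {
  .psi_point_mass(T, A, 1 / gamma, m) / r
}

#' Identify vigor and discount from two amplitude/reward/duration conditions
#'
#' Two observed optimal durations in two (amplitude, reward) conditions pin
#' down the two internal parameters (vigor = rho/eps, gamma). Stationarity
#' gives vigor explicitly per condition at any gamma, so identification is a
#' single 1-D root in log(gamma).
#'
#' A solution requires the duration ratio to lie above the undiscounted-limit
#' boundary `sqrt(A2/A1) * (r1/r2)^(1/4)`; below it no (vigor, gamma) pair
#' reproduces the two durations and `ok = FALSE` is returned.
#'
#' @param cond1,cond2 numeric triples `c(A, r, T)`: amplitude (m), reward,
#'   observed duration (s).
#' @param gamma_bracket search bracket for gamma (s).
#' @param m mass (kg).
#' @return list with `vigor`, `gamma`, and logical `ok`.
#' @export
identify_parameters <- function(cond1, cond2,
                                gamma_bracket = c(1e-2, 1e3), m = 1) {
  stopifnot(length(cond1) == 3, length(cond2) == 3,
            cond1[3] > 0, cond2[3] > 0,
            !isTRUE(all.equal(cond1[1:2], cond2[1:2])))
  g <- function(lg) {
    gam <- exp(lg)
    log(.vigor_implied(gam, cond1[1], cond1[2], cond1[3], m)) -
      log(.vigor_implied(gam, cond2[1], cond2[2], cond2[3], m))
  }
  lo <- log(gamma_bracket[1]); hi <- log(gamma_bracket[2])
  flo <- g(lo); fhi <- g(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    return(list(vigor = NA_real_, gamma = NA_real_, ok = FALSE))
  lg <- uniroot(g, c(lo, hi), tol = 1e-14)$root
  gam <- exp(lg)
  list(vigor = .vigor_implied(gam, cond1[1], cond1[2], cond1[3], m),
       gamma = gam, ok = TRUE)
}
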