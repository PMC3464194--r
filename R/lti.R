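# Finite-horizon discounted-effort optimal control for linear plants.
#
# For x' = Ax + Bu, minimizing eps * int_0^T exp(-s/gamma) ||u||^2 ds with
# fixed endpoints, the Pontryagin system is linear and solves in closed form:
#   u*(s)  = -(exp(ks)/2eps) B' e^{A'(T-s)} nu,          k = 1/gamma
#   nu     = -2 eps exp(-kT) W(T)^{-1} (x* - e^{AT} x0)
#   J_u(T) = eps exp(-kT) d' W(T)^{-1} d,  d = x* - e^{AT} x0
# with the discounted controllability Gramian
#   W(T) = int_0^T exp(-ks) e^{As} B B' e^{A's} ds,
# computed by the block-matrix-exponential (Van Loan) identity. This
# parametrization stays bounded for marginally stable A, unlike the forward
# costate form.

# dense matrix exponential, scaling-and-squaring with Pade(6)
expm_dense <- function(A) {
  n <- nrow(A)
  nrmA <- max(rowSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrmA, 1e-300))) + 1L)
  As <- A / 2^j
  # Pade(6,6)
  c6 <- c(1, 1/2, 5/44, 1/66, 1/792, 1/15840, 1/665280)
  A2 <- As %*% As; A4 <- A2 %*% A2; A6 <- A4 %*% A2
  I <- diag(n)
  U <- As %*% (c6[2] * I + c6[4] * A2 + c6[6] * A4)
  V <- c6[1] * I + c6[3] * A2 + c6[5] * A4 + c6[7] * A6
  E <- solve(V - U, V + U)
  for (i in seq_len(j)) E <- E %*% E
  E
}

#' Linear time-invariant system from a linear plant spec
#'
#' Builds the (A, B, H) matrices of Object I (2 states) or Object II
#' (4 states: position, velocity, activation, excitation) and asserts
#' controllability via the Kalman rank condition.
#'
#' @param spec a [point_mass()] or [filtered_point_mass()] spec.
#' @return object of class `lti_system` with fields `A`, `B`, `H`
#'   (observation of position and velocity), `n`, and the originating `spec`.
#' @export
lti_system <- function(spec) {
  if (inherits(spec, "point_mass_spec")) {
    A <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
    B <- matrix(c(0, 1 / spec$m), 2, 1)
    H <- diag(2)
  } else if (inherits(spec, "filtered_point_spec")) {
    A <- matrix(0, 4, 4)
    A[1, 2] <- 1
    A[2, 3] <- spec$g / spec$m
    A[3, 3] <- -1 / spec$tau; A[3, 4] <- 1 / spec$tau
    A[4, 4] <- -1 / spec$tau
    B <- matrix(c(0, 0, 0, 1 / spec$tau), 4, 1)
    H <- cbind(diag(2), matrix(0, 2, 2))
  } else stop("not a linear plant spec")
  n <- nrow(A)
  ctrb <- B
  for (i in seq_len(n - 1)) ctrb <- cbind(ctrb, A %*% ctrb[, ncol(ctrb), drop = FALSE])
  if (qr(ctrb)$rank < n) stop("system is not controllable")
  structure(list(A = A, B = B, H = H, n = n, spec = spec),
            class = "lti_system")
}

# discounted controllability Gramian W(T) by Van Loan's block exponential:
# upper-right block of exp([[ -F, Q ], [ 0, -A' ]] T) equals
# e^{-FT} int_0^T e^{Fs} Q e^{-A's} ds with F = A - kI ... we need
# V = int_0^T e^{(A-kI)s} Q e^{A's} ds; use blocks [[A-kI, Q],[0, A']]:
# exp gives upper-right = int e^{(A-kI)(T-s)} Q e^{A's} ds which by s->T-s
# equals int e^{(A-kI)s} Q e^{A'(T-s)} ds = V e^{A'T} ... simplest correct
# route: C = [[-(A - kI), Q], [0, A']]; upper-right of exp(CT) is
# int_0^T e^{-(A-kI)(T-s)} Q e^{A's} ds = e^{-(A-kI)T} V, so
# V = e^{(A-kI)T} * upperright.
disc_gramian <- function(sys, T, gamma) {
  stopifnot(T > 0, gamma > 0)
  n <- sys$n; k <- 1 / gamma
  F <- sys$A - k * diag(n)
  Q <- sys$B %*% t(sys$B)
  C <- rbind(cbind(-F, Q), cbind(matrix(0, n, n), t(sys$A)))
  E <- expm_dense(C * T)
  W <- expm_dense(F * T) %*% E[1:n, (n + 1):(2 * n), drop = FALSE]
  (W + t(W)) / 2
}

#' Solve the discounted-effort finite-horizon problem for a linear plant
#'
#' Closed-form two-point boundary solution: drives the state from `x0` to
#' `xstar` in exactly `T` seconds while minimizing the discounted quadratic
#' effort. For Object II the terminal state is full rest (target position,
#' zero velocity, zero muscle activation and excitation) unless `xstar`
#' supplies all four components.
#'
#' @param sys an [lti_system()].
#' @param x0 initial state (length `sys$n`, or position/velocity padded with
#'   zeros).
#' @param xstar goal state, padded like `x0`.
#' @param T horizon (s).
#' @param gamma discount time constant (s).
#' @param eps effort scaling.
#' @param dt output grid step (s).
#' @param constrained indices of the state components pinned at `T`
#'   (default: all). E.g. `1:4` pins position/velocity and leaves muscle
#'   states free (the minimal terminal contract).
#' @return an `optimal_trajectory`: list with `time`, `state` (rows = times),
#'   `control`, `J_u`, `T`, and the boundary residual `boundary_error`
#'   (over the constrained components).
#' @export
solve_finite_horizon_linear <- function(sys, x0, xstar, T, gamma,
                                        eps = 1, dt = 1e-3,
                                        constrained = NULL) {
  stopifnot(inherits(sys, "lti_system"), T > 0, gamma > 0, eps > 0)
  n <- sys$n
  if (is.null(constrained)) constrained <- seq_len(n)
  pad <- function(x) { y <- numeric(n); y[seq_along(x)] <- x; y }
  x0 <- pad(x0); xstar <- pad(xstar)
  k <- 1 / gamma

  # grid quantities: e^{A t_i} and the running Gramian W(t_i); using the
  # same accumulated W for the boundary solve and for the path makes
  # x(T) = xstar hold to solve() roundoff even when W is ill-conditioned
  nstep <- max(2L, ceiling(T / dt))
  h <- T / nstep
  tt <- seq(0, T, by = h)
  Eh <- expm_dense(sys$A * h)
  Vh <- disc_gramian(sys, h, gamma)       # local Gramian over one grid step
  Elist <- vector("list", nstep + 1L)
  Wlist <- vector("list", nstep + 1L)
  Elist[[1L]] <- diag(n); Wlist[[1L]] <- matrix(0, n, n)
  for (i in seq_len(nstep)) {
    s <- (i - 1L) * h
    Wlist[[i + 1L]] <- Wlist[[i]] +
      exp(-k * s) * Elist[[i]] %*% Vh %*% t(Elist[[i]])
    Elist[[i + 1L]] <- Elist[[i]] %*% Eh
  }
  W <- Wlist[[nstep + 1L]]
  # terminal costate lives in the constrained subspace: nu = S' nu_tilde
  Wc <- W[constrained, constrained, drop = FALSE]
  rc <- rcond(Wc)
  if (!is.finite(rc) || rc < 1e-15)
    stop("boundary solve ill-conditioned at T = ", signif(T, 4),
         " s (reciprocal condition ", signif(rc, 2), ")")
  d_full <- xstar - Elist[[nstep + 1L]] %*% x0
  d <- d_full[constrained]
  Winv_d <- solve(Wc, d)
  nu <- numeric(n)
  nu[constrained] <- -2 * eps * exp(-k * T) * Winv_d
  J_u <- as.numeric(eps * exp(-k * T) * crossprod(d, Winv_d))

  # exact path on the grid:
  #   u(t) = -(e^{kt}/2 eps) B' e^{A'(T-t)} nu
  #   x(t) = e^{At} x0 - (e^{kt}/2 eps) W(t) e^{A'(T-t)} nu
  m <- ncol(sys$B)
  state <- matrix(NA_real_, nstep + 1L, n)
  control <- matrix(NA_real_, nstep + 1L, m)
  EhT <- t(Eh)
  Fs <- diag(n)                            # e^{A'(T - t_i)}, built backward
  for (i in (nstep + 1L):1L) {
    s <- (i - 1L) * h
    Fn <- Fs %*% nu
    control[i, ] <- -(exp(k * s) / (2 * eps)) *
      as.numeric(crossprod(sys$B, Fn))
    state[i, ] <- as.numeric(Elist[[i]] %*% x0) -
      (exp(k * s) / (2 * eps)) * as.numeric(Wlist[[i]] %*% Fn)
    if (i > 1L) Fs <- EhT %*% Fs
  }
  structure(list(time = tt, state = state, control = control,
                 J_u = J_u, T = T, gamma = gamma, eps = eps,
                 boundary_error = sqrt(sum(
                   (state[nstep + 1L, constrained] -
                      xstar[constrained])^2))),
            class = "optimal_trajectory")
}

#' @export
print.optimal_trajectory <- function(x, ...) {
  cat(sprintf(
    "<optimal_trajectory> T = %.4g s, J_u = %.6g, boundary error = %.2g\n",
    x$T, x$J_u, x$boundary_error))
  invisible(x)
}

#' Export an optimal trajectory as a data frame
#'
#' @param traj an `optimal_trajectory`.
#' @return data.frame with time, state columns `x1..xn`, control `u1..um`.
#' @export
trajectory_table <- function(traj) {
  d <- data.frame(t = traj$time)
  st <- as.data.frame(traj$state); names(st) <- paste0("x", seq_len(ncol(st)))
  ct <- as.data.frame(traj$control); names(ct) <- paste0("u", seq_len(ncol(ct)))
  cbind(d, st, ct)
}
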