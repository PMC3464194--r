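# R interface to the gradient-based finite-horizon solver for the arm.

#' Hamiltonian of the discounted-effort control problem
#'
#' \eqn{H(x, \lambda, u, t) = \epsilon e^{-t/\gamma}\|u\|^2 + \lambda^\top
#' f(x, u)}. The optimal control minimizes H pointwise (Pontryagin), so at a
#' converged solution the control gradient \eqn{\partial H/\partial u =
#' 2\epsilon e^{-t/\gamma} u + (\partial f/\partial u)^\top \lambda}
#' vanishes along the path.
#'
#' @param plant a plant spec.
#' @param state,costate state and costate vectors (plant state dimension).
#' @param control control vector.
#' @param internal an [internal_params()] (uses `eps`, `gamma`).
#' @param t time (s), for the discount weight.
#' @param field_on apply the arm's force field in the dynamics.
#' @return scalar Hamiltonian value.
#' @export
hamiltonian <- function(plant, state, costate, control, internal, t,
                        field_on = FALSE) {
  f <- plant_derivative(plant, state, control, field_on)
  internal$eps * exp(-t / internal$gamma) * sum(control^2) +
    sum(costate * f)
}

# full state derivative for any plant (R reference path)
plant_derivative <- function(plant, state, control, field_on = FALSE) {
  if (inherits(plant, "point_mass_spec")) {
    point_mass_derivative(plant, state, control)
  } else if (inherits(plant, "filtered_point_spec")) {
    sys <- lti_system(plant)
    as.numeric(sys$A %*% state + sys$B %*% control)
  } else {
    arm_state_derivative(plant, state, control, field_on)
  }
}

arm_par_list <- function(spec) {
  spec[c("l1", "l2", "I1", "I2", "m1", "m2", "c1", "c2",
         "tau", "Fmax", "Amom", "D")]
}

#' Finite-horizon optimal control for the two-joint arm
#'
#' Gradient-based solution of the discounted-effort problem with terminal
#' full-rest constraint (joint target, zero velocity, muscles at rest),
#' handled by quadratic penalty with continuation. The time grid is the
#' integration step `eta` (1 ms); gradients are exact for the discretized
#' problem (discrete adjoint).
#'
#' @param spec a [planar_arm()] spec.
#' @param x0 initial 12-state (or `c(theta, omega)`, muscles at rest).
#' @param xstar goal: a 12-state, a joint pair (rad), or a hand position
#'   2-vector (m) resolved by inverse kinematics.
#' @param T horizon (s).
#' @param gamma,eps discount (s) and effort scaling.
#' @param eta grid step (s).
#' @param init optional warm-start control matrix (n x 4).
#' @param cache optional environment; stores the solved control path under
#'   `$U` for warm-starting subsequent calls (used by the duration search).
#' @param max_iter gradient-iteration budget per penalty stage.
#' @param tol_term terminal-error tolerance (hand metric, m scale).
#' @param muscle_rest constrain terminal muscle activation/excitation to
#'   zero (default; makes "u = 0 after T" self-consistent). `FALSE` leaves
#'   muscle states free, the minimal contract (position + velocity only).
#' @return an `optimal_trajectory` with fields `time`, `state`, `control`,
#'   `J_u`, `T`, `grad_norm`, `term_err`, `converged`.
#' @export
solve_finite_horizon_arm <- function(spec, x0, xstar, T, gamma, eps = 1,
                                     eta = 1e-3, init = NULL, cache = NULL,
                                     max_iter = 800, tol_term = 1e-3,
                                     muscle_rest = TRUE) {
  stopifnot(inherits(spec, "planar_arm_spec"), T > 0)
  pad <- function(x) { y <- numeric(12); y[seq_along(x)] <- x; y }
  x0 <- pad(x0)
  xs <- if (length(xstar) == 12) xstar else
    pad(if (length(xstar) == 2 && max(abs(xstar)) < (spec$l1 + spec$l2))
      tryCatch(arm_inverse_kinematics(spec, xstar), error = function(e) xstar)
      else xstar)
  U0 <- init
  if (is.null(U0) && !is.null(cache) && !is.null(cache$U)) U0 <- cache$U
  sol <- arm_ocp_cpp(arm_par_list(spec), x0, xs, T, gamma, eps, eta,
                     U0 = U0, tol_term = tol_term, max_iter = max_iter,
                     w_mus = if (muscle_rest) 0.1 else 0)
  if (!is.null(cache)) cache$U <- sol$U
  n <- nrow(sol$U)
  structure(list(time = seq(0, by = eta, length.out = n + 1L),
                 state = sol$X, control = rbind(sol$U, 0),
                 J_u = sol$J_u, T = T, gamma = gamma, eps = eps,
                 grad_norm = sol$grad_norm, term_err = sol$term_err,
                 converged = sol$converged,
                 boundary_error = sol$term_err),
            class = "optimal_trajectory")
}

#' Emergent optimal duration for an arm movement (native search)
#'
#' Golden-section duration search run natively with warm-started solves;
#' equivalent to [optimal_duration()] on the arm plant but substantially
#' faster.
#'
#' @inheritParams solve_finite_horizon_arm
#' @param task a [task_params()] (hand-position goal and reward).
#' @param internal an [internal_params()].
#' @param bracket duration bracket (s).
#' @return list with `T`, `utility`, `J_u`, `status`.
#' @export
arm_optimal_duration <- function(spec, x0, task, internal,
                                 bracket = c(0.05, 3), eta = 1e-3) {
  xs <- goal_state(spec, task)
  pad <- function(x) { y <- numeric(12); y[seq_along(x)] <- x; y }
  r <- arm_duration_cpp(arm_par_list(spec), pad(x0), xs,
                        internal$gamma, internal$eps,
                        internal$rho * task$r, eta,
                        bracket[1], bracket[2])
  list(T = r$T, utility = r$utility, J_u = r$J_u,
       status = if (r$utility > 0) "ok" else "no_viable_action")
}
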