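# The infinite-horizon layer: discounted reward minus discounted effort as a
# function of prospective movement duration, and the golden-section search
# that turns it into an emergent optimal duration + utility.

#' Task parameters: rewarded goal state
#'
#' @param xstar goal position (scalar for the point objects, hand position
#'   2-vector for the arm). Interpreted as "at rest at this position".
#' @param r reward magnitude (>= 0).
#' @return list of class `task_params`.
#' @export
task_params <- function(xstar, r) {
  stopifnot(r >= 0)
  structure(list(xstar = xstar, r = r), class = "task_params")
}

#' Internal (subjective) parameters
#'
#' `rho` values reward, `eps` values effort, `gamma` is the discount time
#' constant. Behavior depends on `rho` and `eps` only through the vigor ratio
#' `rho/eps`; utilities scale with `eps`.
#'
#' @param rho reward valuation (> 0). May be given implicitly via `vigor`.
#' @param eps effort valuation (> 0).
#' @param gamma discount time constant, seconds (> 0).
#' @param vigor alternative to `rho`: the ratio rho/eps.
#' @return list of class `internal_params` with fields rho, eps, gamma, vigor.
#' @export
internal_params <- function(rho = NULL, eps = 1, gamma = 2, vigor = NULL) {
  if (is.null(rho)) {
    stopifnot(!is.null(vigor))
    rho <- vigor * eps
  }
  stopifnot(rho > 0, eps > 0, gamma > 0)
  structure(list(rho = rho, eps = eps, gamma = gamma, vigor = rho / eps),
            class = "internal_params")
}

# effort J_u(T) of the optimal point-to-point movement, by plant
plant_effort <- function(plant, x0, xstar_full, T, internal, ...) {
  UseMethod("plant_effort")
}

#' @export
plant_effort.point_mass_spec <- function(plant, x0, xstar_full, T, internal,
                                         ...) {
  # analytic when rest-to-rest (the common case); Gramian otherwise
  if (length(x0) >= 2 && x0[2] == 0 && xstar_full[2] == 0) {
    point_mass_effort(T, abs(xstar_full[1] - x0[1]), internal$gamma,
                      eps = internal$eps, m = plant$m)
  } else {
    sys <- lti_system(plant)
    lti_effort(sys, x0, xstar_full, T, internal)
  }
}

#' @export
plant_effort.filtered_point_spec <- function(plant, x0, xstar_full, T,
                                             internal, ...) {
  lti_effort(lti_system(plant), x0, xstar_full, T, internal)
}

lti_effort <- function(sys, x0, xstar_full, T, internal) {
  n <- sys$n
  pad <- function(x) { y <- numeric(n); y[seq_along(x)] <- x; y }
  x0 <- pad(x0); xs <- pad(xstar_full)
  W <- disc_gramian(sys, T, internal$gamma)
  d <- xs - expm_dense(sys$A * T) %*% x0
  as.numeric(internal$eps * exp(-T / internal$gamma) * crossprod(d, solve(W, d)))
}

#' @export
plant_effort.planar_arm_spec <- function(plant, x0, xstar_full, T, internal,
                                         cache = NULL, ...) {
  sol <- solve_finite_horizon_arm(plant, x0, xstar_full, T,
                                  gamma = internal$gamma, eps = internal$eps,
                                  cache = cache)
  sol$J_u
}

# goal state padded to the plant's full state dimension ("at rest at xstar")
goal_state <- function(plant, task) {
  n <- state_dim(plant)
  xs <- numeric(n)
  if (inherits(plant, "planar_arm_spec")) {
    xs[1:2] <- if (length(task$xstar) == 2)
      arm_inverse_kinematics(plant, task$xstar) else task$xstar
  } else {
    xs[1] <- task$xstar[1]
  }
  xs
}

#' Discounted utility of acting in a prospective duration T
#'
#' \eqn{J_\infty(T) = \rho r e^{-T/\gamma} - J_u(T)}, where \eqn{J_u(T)} is
#' the eps-weighted discounted effort of the optimal finite-horizon movement
#' from `x0` to the rewarded state in exactly `T` seconds.
#'
#' @param plant a plant spec.
#' @param x0 initial state (padded with zeros to the plant state dimension).
#' @param task a [task_params()].
#' @param internal an [internal_params()].
#' @param T prospective duration (s).
#' @param ... passed to the plant's finite-horizon solver (e.g. `cache` for
#'   the arm).
#' @return utility (scalar).
#' @export
utility_of_duration <- function(plant, x0, task, internal, T, ...) {
  stopifnot(T > 0)
  reward <- internal$rho * task$r * exp(-T / internal$gamma)
  xs <- goal_state(plant, task)
  reward - plant_effort(plant, x0, xs, T, internal, ...)
}

# golden-section maximization of a unimodal f on [lo, hi]
golden_section_max <- function(f, lo, hi, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  xm <- (a + b) / 2
  list(x = xm, value = f(xm))
}

#' Emergent optimal movement duration by golden-section search
#'
#' Maximizes [utility_of_duration()] over `T`. A coarse pre-scan (25 points)
#' locates a bracketing triple before the golden-section refinement, guarding
#' against non-unimodal curves; the returned duration is accurate to `tol`
#' (1 ms by default).
#'
#' @inheritParams utility_of_duration
#' @param bracket duration search range (s).
#' @param tol duration tolerance (s).
#' @return list with `T` (s), `utility`, and `status`: `"ok"`,
#'   `"no_viable_action"` (maximal utility non-positive), or `"boundary"`
#'   (maximum at a bracket edge).
#' @export
optimal_duration <- function(plant, x0, task, internal,
                             bracket = c(1e-3, 10), tol = 1e-3, ...) {
  stopifnot(bracket[1] > 0, bracket[2] > bracket[1])
  f <- function(T) utility_of_duration(plant, x0, task, internal, T, ...)
  # pre-scan
  Ts <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 25))
  vals <- vapply(Ts, function(T) tryCatch(f(T), error = function(e) -Inf),
                 numeric(1))
  i <- which.max(vals)
  if (!is.finite(vals[i]))
    return(list(T = NA_real_, utility = NA_real_, status = "no_viable_action"))
  if (i == 1L || i == length(Ts)) {
    res <- list(x = Ts[i], value = vals[i])
    status <- "boundary"
  } else {
    res <- golden_section_max(f, Ts[i - 1L], Ts[i + 1L], tol = tol)
    status <- "ok"
  }
  if (res$value <= 0) status <- "no_viable_action"
  list(T = res$x, utility = res$value, status = status)
}

#' Utility curve over a duration grid
#'
#' Tabulates the discounted reward, the effort, and their difference on a
#' grid of prospective durations (the objective-function plot).
#'
#' @inheritParams optimal_duration
#' @param Tgrid duration grid (s).
#' @return data.frame with columns `T`, `reward`, `effort`, `utility`, plus
#'   attributes `Tstar` and `utility_max`.
#' @export
utility_curve <- function(plant, x0, task, internal, Tgrid, ...) {
  xs <- goal_state(plant, task)
  eff <- vapply(Tgrid, function(T)
    plant_effort(plant, x0, xs, T, internal, ...), numeric(1))
  rew <- internal$rho * task$r * exp(-Tgrid / internal$gamma)
  out <- data.frame(T = Tgrid, reward = rew, effort = eff,
                    utility = rew - eff)
  i <- which.max(out$utility)
  attr(out, "Tstar") <- out$T[i]
  attr(out, "utility_max") <- out$utility[i]
  out
}
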