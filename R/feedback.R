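# Closed-loop simulation: receding-horizon controller, delayed-observation
# Kalman estimation, signal-dependent motor noise, perturbation events,
# movement-end detection.

#' Noise and delay specification
#'
#' @param sigma_sdn_m multiplicative (signal-dependent) motor-noise factor:
#'   the control applied over one integration step is `u * (1 +
#'   sigma_sdn_m * xi)` with `xi` standard normal (the discrete-time
#'   optimal-feedback-control convention at the 1 ms step).
#' @param sigma_sin_s additive observation noise s.d. (observation units).
#' @param delay_s sensory feedback delay (s), default 0.13.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(sigma_sdn_m = 0, sigma_sin_s = 0, delay_s = 0.13) {
  stopifnot(sigma_sdn_m >= 0, sigma_sin_s >= 0, delay_s >= 0)
  structure(list(sigma_sdn_m = sigma_sdn_m, sigma_sin_s = sigma_sin_s,
                 delay_s = delay_s), class = "noise_spec")
}

#' Perturbation event
#'
#' @param onset time (s) at which the event occurs.
#' @param kind `"target_jump"` (controller goal replaced at
#'   `onset + delay`, modelling delayed perception) or `"force_field_on"`
#'   (plant dynamics altered from `onset`; the controller stays naive).
#' @param xstar new goal (hand position, m) for target jumps.
#' @return list of class `perturbation_event`.
#' @export
perturbation_event <- function(onset, kind = c("target_jump",
                                               "force_field_on"),
                               xstar = NULL) {
  kind <- match.arg(kind)
  stopifnot(onset >= 0, kind != "target_jump" || !is.null(xstar))
  structure(list(onset = onset, kind = kind, xstar = xstar),
            class = "perturbation_event")
}

# per-(system, gamma, eps, grid) cache of the precomputed gain tables
.lti_cache <- new.env(parent = emptyenv())

lti_tables <- function(sys, gamma, eta, Tmax) {
  key <- paste(class(sys$spec)[1],
               paste(signif(unlist(sys$spec[sapply(sys$spec, is.numeric)]), 10),
                     collapse = "_"),
               signif(gamma, 10), signif(eta, 10), signif(Tmax, 10),
               sep = "|")
  hit <- .lti_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- as.integer(ceiling(Tmax / eta))
  V <- disc_gramian(sys, eta, gamma)
  Eeta <- expm_dense(sys$A * eta)
  pre <- lti_precompute_cpp(sys$A, sys$B, 1 / gamma, eta, N, V, Eeta)
  # zero-order-hold input matrix int_0^eta e^{As} B ds
  n <- sys$n
  Cblk <- rbind(cbind(sys$A, sys$B), matrix(0, ncol(sys$B), n + ncol(sys$B)))
  Eb <- expm_dense(Cblk * eta)
  out <- list(pre = pre, Ad = Eb[1:n, 1:n, drop = FALSE],
              Bd = Eb[1:n, (n + 1):(n + ncol(sys$B)), drop = FALSE],
              N = N)
  .lti_cache[[key]] <- out
  out
}

#' Simulate one closed-loop trial
#'
#' Receding-horizon control at every step (linear plants) or every 10 ms
#' with warm-started solves (arm), Euler-Maruyama integration at `dt`,
#' multiplicative control noise, additive observation noise with sensory
#' delay, and optional perturbation events. Target jumps reach the
#' controller only at `onset + delay_s` (delayed perception); a force field
#' acts on the plant but never enters the controller's model.
#'
#' @param plant a plant spec.
#' @param task a [task_params()]; for the arm `xstar` is a hand position.
#' @param internal an [internal_params()].
#' @param noise a [noise_spec()].
#' @param x0 initial state (padded to the plant dimension).
#' @param events list of [perturbation_event()]s (arm only).
#' @param horizon_max simulation length (s); must exceed the movement.
#' @param dt integration/control step (s).
#' @param Tmin,Tmax prospective-duration bracket for the controller (s).
#' @param replan_every,refresh_every arm-controller budgets (steps): plan
#'   re-solve cadence and golden-section duration-refresh cadence.
#' @return list of class `trial` with `trace` (data.frame, one row per step)
#'   and `outcome` (list: `duration`, `endpoint`, `moved`, `finished`,
#'   `T_plan`, `utility_plan`).
#' @export
simulate_trial <- function(plant, task, internal, noise = noise_spec(),
                           x0 = NULL, events = list(),
                           horizon_max = 3, dt = 1e-3,
                           Tmin = 0.05, Tmax = 3,
                           replan_every = 10L, refresh_every = 10L) {
  nmax <- as.integer(round(horizon_max / dt))
  d <- as.integer(round(noise$delay_s / dt))
  if (inherits(plant, "planar_arm_spec")) {
    sim_trial_arm(plant, task, internal, noise, x0, events, nmax, dt, d,
                  Tmin, Tmax, replan_every, refresh_every)
  } else {
    if (length(events)) stop("perturbation events are supported for the arm")
    sim_trial_lti(plant, task, internal, noise, x0, nmax, dt, d, Tmin, Tmax)
  }
}

sim_trial_lti <- function(plant, task, internal, noise, x0, nmax, dt, d,
                          Tmin, Tmax) {
  sys <- lti_system(plant)
  tb <- lti_tables(sys, internal$gamma, dt, Tmax)
  n <- sys$n
  pad <- function(x) { y <- numeric(n); y[seq_along(x)] <- x; y }
  x0 <- if (is.null(x0)) numeric(n) else pad(x0)
  xs <- goal_state(plant, task)
  res <- lti_sim_cpp(tb$pre, tb$Ad, tb$Bd, sys$H, x0, xs,
                     internal$rho * task$r, internal$eps, dt, d,
                     noise$sigma_sdn_m, noise$sigma_sin_s, nmax,
                     as.integer(round(Tmin / dt)))
  tr <- as.data.frame(res$trace)
  names(tr) <- c("t", paste0("x", 1:n), paste0("xhat", 1:n), "u",
                 "T_go", "utility")
  speed <- abs(tr$x2)
  end <- detect_movement_end(tr$t, speed)
  outcome <- list(duration = end$duration,
                  endpoint = if (end$moved) tr$x1[end$index] else tr$x1[1],
                  moved = end$moved, finished = end$moved && end$settled,
                  T_plan = tr$T_go[1], utility_plan = tr$utility[1])
  structure(list(trace = tr, outcome = outcome, plant = plant), class = "trial")
}

sim_trial_arm <- function(plant, task, internal, noise, x0, events, nmax,
                          dt, d, Tmin, Tmax, replan_every, refresh_every) {
  pad <- function(x) { y <- numeric(12); y[seq_along(x)] <- x; y }
  x0 <- pad(x0)
  xs <- goal_state(plant, task)
  jump_step <- -1L; xs2 <- xs; field_from <- -1L
  for (ev in events) {
    if (ev$kind == "target_jump") {
      jump_step <- as.integer(round((ev$onset + noise$delay_s) / dt))
      xs2 <- goal_state(plant, task_params(ev$xstar, task$r))
    } else if (ev$kind == "force_field_on") {
      field_from <- as.integer(round(ev$onset / dt))
    }
  }
  res <- arm_sim_cpp(arm_par_list(plant), x0, xs, internal$gamma,
                     internal$eps, internal$rho * task$r, dt, d,
                     noise$sigma_sdn_m, noise$sigma_sin_s, nmax,
                     as.integer(replan_every), as.integer(refresh_every),
                     jump_step, xs2, field_from, Tmin, Tmax)
  tr <- as.data.frame(res$trace)
  names(tr) <- c("t", "theta1", "theta2", "omega1", "omega2",
                 "hand_x", "hand_y", "hand_vx", "hand_vy", "speed",
                 paste0("u", 1:4), "T_go", "utility")
  end <- detect_movement_end(tr$t, tr$speed)
  outcome <- list(duration = end$duration,
                  endpoint = if (end$moved)
                    c(tr$hand_x[end$index], tr$hand_y[end$index])
                  else c(tr$hand_x[1], tr$hand_y[1]),
                  moved = end$moved, finished = end$moved && end$settled,
                  T_plan = res$T_plan, utility_plan = res$utility_plan,
                  J_u_plan = res$J_u_plan)
  structure(list(trace = tr, outcome = outcome, plant = plant), class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  o <- x$outcome
  cat(sprintf("<trial> duration %.3f s, endpoint (%s), %s\n", o$duration,
              paste(signif(o$endpoint, 4), collapse = ", "),
              if (o$finished) "finished" else "unfinished"))
  invisible(x)
}

#' Movement end from a speed profile
#'
#' The movement ends at the last downward crossing of the speed threshold
#' (3 cm/s) after which speed stays below threshold for at least the hold
#' window (or to the end of the trace). The hold window guards against
#' counting mid-movement dips in multi-peaked profiles.
#'
#' @param time time grid (s).
#' @param speed endpoint speed (m/s).
#' @param threshold speed threshold (m/s), default 0.03.
#' @param hold hold window (s), default 0.05.
#' @return list: `duration` (s), `index` of the end sample, `moved` (speed
#'   ever exceeded threshold), `settled` (a qualifying crossing was found).
#' @export
detect_movement_end <- function(time, speed, threshold = 0.03, hold = 0.05) {
  n <- length(speed)
  stopifnot(length(time) == n, n > 1)
  if (!any(speed >= threshold))
    return(list(duration = 0, index = 1L, moved = FALSE, settled = TRUE))
  dt <- time[2] - time[1]
  hsteps <- max(1L, as.integer(round(hold / dt)))
  below <- speed < threshold
  cross <- which(!below[-n] & below[-1]) + 1L
  for (ci in rev(cross)) {
    upto <- min(n, ci + hsteps)
    if (all(below[ci:upto]))
      return(list(duration = time[ci], index = ci, moved = TRUE,
                  settled = TRUE))
  }
  list(duration = time[n], index = n, moved = TRUE, settled = FALSE)
}

#' One receding-horizon controller step
#'
#' Re-solves the optimal-duration problem from the current state estimate
#' and returns the first control increment of the resulting open-loop
#' optimum (deterministic in its inputs).
#'
#' @param plant plant spec.
#' @param xhat current state estimate.
#' @param task,internal task and internal parameters.
#' @param Tmin,Tmax duration bracket (s).
#' @param dt grid step (s).
#' @return list: `u` (control vector), `T` (re-planned duration), `utility`,
#'   `status`.
#' @export
controller_step <- function(plant, xhat, task, internal,
                            Tmin = 0.05, Tmax = 3, dt = 1e-3) {
  if (inherits(plant, "planar_arm_spec")) {
    od <- arm_optimal_duration(plant, xhat, task, internal,
                               bracket = c(Tmin, Tmax), eta = dt)
    if (od$status != "ok")
      return(list(u = numeric(4), T = NA_real_, utility = od$utility,
                  status = od$status))
    cache <- new.env();
    sol <- solve_finite_horizon_arm(plant, xhat, goal_state(plant, task),
                                    od$T, internal$gamma, internal$eps,
                                    eta = dt, cache = cache)
    list(u = sol$control[1, ], T = od$T, utility = od$utility, status = "ok")
  } else {
    od <- optimal_duration(plant, xhat, task, internal,
                           bracket = c(Tmin, Tmax))
    if (od$status == "no_viable_action")
      return(list(u = 0, T = od$T, utility = od$utility, status = od$status))
    sys <- lti_system(plant)
    n <- sys$n
    pad <- function(x) { y <- numeric(n); y[seq_along(x)] <- x; y }
    xs <- goal_state(plant, task)
    k <- 1 / internal$gamma
    W <- disc_gramian(sys, od$T, internal$gamma)
    EA <- expm_dense(sys$A * od$T)
    dd <- xs - EA %*% pad(xhat)
    u <- as.numeric(exp(-k * od$T) * t(sys$B) %*% t(EA) %*% solve(W, dd))
    list(u = u, T = od$T, utility = od$utility, status = od$status)
  }
}

#' Delayed-observation Kalman filter step (linear plants)
#'
#' Reference implementation of the estimator used in the closed loop: a
#' Kalman filter runs at the delayed time (observation `y_t = H x(t-Delta) +
#' noise`), and the current estimate is bridged with the stored controls.
#' Process noise follows the signal-dependent motor noise at the buffered
#' control.
#'
#' @param est estimator state: list with `xd` (corrected estimate at the
#'   delayed time), `P` (its covariance), `ubuf` (matrix of the `d` controls
#'   applied since), as produced by [kalman_init()].
#' @param control the control applied this step (appended to the buffer).
#' @param observation observation vector `H x(t - Delta) + noise`.
#' @param model list with `Ad`, `Bd`, `H` (discrete-time system).
#' @param noise a [noise_spec()].
#' @param dt step (s).
#' @return updated estimator state; field `xhat` holds the current-time
#'   estimate.
#' @export
kalman_step <- function(est, control, observation, model, noise, dt = 1e-3) {
  d <- nrow(est$ubuf)
  ubuf <- rbind(est$ubuf, matrix(control, nrow = 1))
  uold <- ubuf[1, ]
  # predict the delayed estimate one step with the oldest buffered control
  xd <- as.numeric(model$Ad %*% est$xd + model$Bd %*% uold)
  su <- noise$sigma_sdn_m * abs(uold[1])
  P <- model$Ad %*% est$P %*% t(model$Ad) +
    su^2 * (model$Bd %*% t(model$Bd))
  P <- (P + t(P)) / 2
  # correct with the (delayed) observation
  H <- model$H
  Robs <- noise$sigma_sin_s^2 * diag(nrow(H))
  S <- H %*% P %*% t(H) + Robs
  if (noise$sigma_sin_s > 0) {
    K <- P %*% t(H) %*% solve(S)
    xd <- xd + as.numeric(K %*% (observation - H %*% xd))
    P <- (diag(length(xd)) - K %*% H) %*% P
    P <- (P + t(P)) / 2
  } else {
    xd[seq_len(nrow(H))] <- observation
    P[] <- 0
  }
  ubuf <- ubuf[-1, , drop = FALSE]
  # bridge to current time with the stored controls
  xhat <- xd
  for (i in seq_len(nrow(ubuf)))
    xhat <- as.numeric(model$Ad %*% xhat + model$Bd %*% ubuf[i, ])
  list(xd = xd, P = P, ubuf = ubuf, xhat = xhat)
}

#' Initialize the delayed Kalman estimator
#'
#' @param x0 known initial state.
#' @param n state dimension.
#' @param d delay in steps.
#' @param m control dimension.
#' @return estimator state for [kalman_step()].
#' @export
kalman_init <- function(x0, n = length(x0), d, m = 1) {
  list(xd = x0, P = matrix(0, n, n),
       ubuf = matrix(0, d, m), xhat = x0)
}
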