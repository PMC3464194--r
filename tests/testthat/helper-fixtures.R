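# shared fixtures: printed cohort statistics and small parameter sets

marmoset_cond <- data.frame(A = c(0.35, 2.45), r = c(1, 3),
                            mean = c(0.75, 1.84), sem = c(0.061, 0.082))
tamarin_cond <- data.frame(A = c(0.35, 2.45), r = c(1, 3),
                           mean = c(0.66, 1.32), sem = c(0.047, 0.050))

fig2_internal <- function() internal_params(vigor = 1, gamma = 2)

arm_fixture <- function(object = "IIIa", posture_deg = c(75, 75)) {
  spec <- planar_arm(object)
  theta0 <- deg2rad(posture_deg)
  list(spec = spec, theta0 = theta0,
       x0 = c(theta0, rep(0, 10)),
       hand0 = hand_kinematics(spec, theta0)$hand)
}

# Simpson quadrature of the discounted squared control along a trajectory
disc_effort_quadrature <- function(traj, gamma, eps = 1) {
  u2 <- rowSums(traj$control^2) * exp(-traj$time / gamma)
  n <- length(u2)
  stopifnot(n %% 2 == 1)  # even number of intervals
  h <- traj$time[2] - traj$time[1]
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  eps * sum(w * u2) * h / 3
}
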