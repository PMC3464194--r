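# Closed-loop simulation, estimator, movement-end detection.

test_that("movement-end detection follows the documented threshold rule", {
  t <- seq(0, 2, by = 1e-3)
  # bell profile crossing down through 3 cm/s at ~0.8 s
  sp <- 0.5 * exp(-((t - 0.4) / 0.18)^2)
  cross <- max(which(sp >= 0.03))
  end <- detect_movement_end(t, sp)
  expect_true(end$moved)
  expect_equal(end$duration, t[cross + 1], tolerance = 2e-3)
  # all-zero speed: no movement
  z <- detect_movement_end(t, rep(0, length(t)))
  expect_false(z$moved); expect_equal(z$duration, 0)
  # multi-peaked profile with a sub-threshold dip: take the final descent,
  # cross-checked against a brute-force scan over all downward crossings
  sp2 <- 0.3 * exp(-((t - 0.3) / 0.1)^2) + 0.25 * exp(-((t - 0.9) / 0.12)^2)
  end2 <- detect_movement_end(t, sp2)
  below <- sp2 < 0.03
  scan <- which(!below[-length(t)] & below[-1]) + 1L
  hold <- 50L
  keep <- scan[vapply(scan, function(ci)
    all(below[ci:min(length(t), ci + hold)]), TRUE)]
  expect_equal(end2$index, max(keep))
  expect_gt(end2$duration, 0.9)   # after the second peak
})

test_that("zero-noise closed loop reproduces the open-loop optimum", {
  ip <- fig2_internal(); tk <- task_params(0.35, 1)
  tr <- simulate_trial(point_mass(), tk, ip, noise_spec(delay_s = 0),
                       horizon_max = 3.5)
  cf <- closed_form_duration(0.35, 1, 1, 2)
  expect_lt(abs(tr$outcome$T_plan - cf$T), 2e-3)
  ol <- solve_finite_horizon_linear(lti_system(point_mass()), c(0, 0),
                                    c(0.35, 0), cf$T, 2)
  i <- seq_len(min(nrow(tr$trace), length(ol$time)))
  expect_lt(max(abs(tr$trace$x1[i] - ol$state[i, 1])), 1e-3)
  # the 3 cm/s stopping threshold cuts the terminal creep: within 2 mm
  expect_lt(abs(tr$outcome$endpoint - 0.35), 2e-3)
  # delay alone must not change the zero-noise trajectory
  tr2 <- simulate_trial(point_mass(), tk, ip, noise_spec(delay_s = 0.13),
                        horizon_max = 3.5)
  expect_lt(max(abs(tr2$trace$x1[i] - ol$state[i, 1])), 1e-3)
})

test_that("controller step is deterministic and near-zero at the goal", {
  ip <- fig2_internal(); tk <- task_params(0.35, 1)
  a <- controller_step(point_mass(), c(0.35, 0), tk, ip)
  expect_lt(abs(a$u), 1e-6)
  b1 <- controller_step(point_mass(), c(0.1, 0.2), tk, ip)
  b2 <- controller_step(point_mass(), c(0.1, 0.2), tk, ip)
  expect_identical(b1$u, b2$u)
  # matches the first instant of the open-loop optimum from the same state
  sol <- solve_finite_horizon_linear(lti_system(point_mass()), c(0.1, 0.2),
                                     c(0.35, 0), b1$T, ip$gamma)
  expect_equal(b1$u, sol$control[1, 1], tolerance = 1e-2)
})

test_that("replanning extends the horizon after a target jump (arm)", {
  af <- arm_fixture("IIIa", c(15, 120))
  ip <- internal_params(vigor = 1 / 300, gamma = 0.5)
  tk <- task_params(af$hand0 + c(0, 0.15), 40)
  ev <- list(perturbation_event(0.1, "target_jump",
                                xstar = af$hand0 + c(0.05, 0.15)))
  tr <- simulate_trial(af$spec, tk, ip, noise_spec(), x0 = af$x0,
                       events = ev, horizon_max = 1.5)
  jidx <- round((0.1 + 0.13) / 1e-3)
  # duration-to-go right after the perceived jump exceeds the pre-jump one
  expect_gt(tr$trace$T_go[jidx + 15], tr$trace$T_go[jidx - 5])
})

test_that("delayed Kalman filter tracks exactly without noise", {
  sys <- lti_system(point_mass())
  tb <- rewardctl:::lti_tables(sys, gamma = 2, eta = 1e-3, Tmax = 3)
  model <- list(Ad = tb$Ad, Bd = tb$Bd, H = sys$H)
  d <- 20
  nz <- noise_spec(0, 0, d * 1e-3)
  est <- kalman_init(c(0, 0), d = d)
  x <- c(0, 0); xh_hist <- list(); x_hist <- list(x)
  us <- 0.5 * sin(seq(0, 3, length.out = 300))
  for (j in seq_along(us)) {
    x <- as.numeric(model$Ad %*% x + model$Bd %*% us[j])
    x_hist[[j + 1]] <- x
    if (j == d) est$ubuf <- matrix(us[1:d], ncol = 1)
    if (j > d) {
      y <- as.numeric(sys$H %*% x_hist[[j + 1 - d]])
      est <- kalman_step(est, us[j], y, model, nz)
      expect_lt(max(abs(est$xhat - x)), 1e-10)
    }
  }
})

test_that("uninformative observations reduce the filter to prediction", {
  sys <- lti_system(point_mass())
  tb <- rewardctl:::lti_tables(sys, 2, 1e-3, 3)
  model <- list(Ad = tb$Ad, Bd = tb$Bd, H = sys$H)
  nz_wide <- noise_spec(0.5, 1e6, 0)       # K ~ 0
  est <- kalman_init(c(0, 0), d = 0)
  xpred <- c(0, 0)
  set.seed(2)
  for (j in 1:100) {
    u <- 1
    est <- kalman_step(est, u, c(rnorm(1), rnorm(1)), model, nz_wide)
    xpred <- as.numeric(model$Ad %*% xpred + model$Bd %*% u)
  }
  expect_lt(max(abs(est$xhat - xpred)), 1e-3)
})

test_that("filter covariance matches a Monte-Carlo ensemble", {
  sys <- lti_system(point_mass())
  tb <- rewardctl:::lti_tables(sys, 2, 1e-3, 3)
  model <- list(Ad = tb$Ad, Bd = tb$Bd, H = matrix(c(1, 0), 1, 2))
  nz <- noise_spec(sigma_sdn_m = 0.5, sigma_sin_s = 0.01, delay_s = 0)
  nrep <- 400; nstep <- 150; u <- 2
  err <- matrix(NA_real_, nrep, 2)
  set.seed(9)
  Pfinal <- NULL
  for (r in seq_len(nrep)) {
    x <- c(0, 0)
    est <- kalman_init(c(0, 0), d = 0)
    for (j in seq_len(nstep)) {
      un <- u * (1 + nz$sigma_sdn_m * rnorm(1))
      x <- as.numeric(model$Ad %*% x + model$Bd %*% un)
      y <- x[1] + nz$sigma_sin_s * rnorm(1)
      est <- kalman_step(est, u, y, model, nz)
    }
    err[r, ] <- est$xhat - x
    Pfinal <- est$P
  }
  emp <- apply(err, 2, var)
  expect_equal(emp[1], Pfinal[1, 1], tolerance = 0.25)
  expect_equal(emp[2], Pfinal[2, 2], tolerance = 0.25)
  expect_lt(abs(mean(err[, 1])), 3 * sd(err[, 1]) / sqrt(nrep))
})

test_that("identical seeds give identical noisy traces", {
  ip <- internal_params(vigor = 100, gamma = 2)
  tk <- task_params(0.2, 1)
  nz <- noise_spec(1, 0.001, 0.13)
  set.seed(123)
  t1 <- simulate_trial(filtered_point_mass(), tk, ip, nz, horizon_max = 1.5,
                       Tmin = 0.25)
  set.seed(123)
  t2 <- simulate_trial(filtered_point_mass(), tk, ip, nz, horizon_max = 1.5,
                       Tmin = 0.25)
  expect_identical(t1$trace, t2$trace)
  set.seed(124)
  t3 <- simulate_trial(filtered_point_mass(), tk, ip, nz, horizon_max = 1.5,
                       Tmin = 0.25)
  expect_false(identical(t1$trace$x1, t3$trace$x1))
})

test_that("events are rejected for plants without event support", {
  expect_error(simulate_trial(point_mass(), task_params(0.3, 1),
                              fig2_internal(),
                              events = list(perturbation_event(
                                0.1, "force_field_on"))),
               "arm")
})
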