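# Gradient-based arm solver.

test_that("Hamiltonian basics and control gradient", {
  af <- arm_fixture()
  ip <- internal_params(vigor = 1 / 300, gamma = 0.5)
  x <- c(af$theta0, rep(0.01, 10))
  expect_equal(hamiltonian(af$spec, x, rep(0, 12), rep(0, 4), ip, t = 0.1),
               0)
  # dH/du = 2 eps e^{-t/gamma} u + lambda_e / tau  vs central differences
  lam <- runif(12, -1, 1); u <- runif(4, -0.2, 0.4); tt <- 0.2
  anly <- 2 * ip$eps * exp(-tt / ip$gamma) * u + lam[9:12] / af$spec$tau
  h <- 1e-6
  for (j in 1:4) {
    dj <- (hamiltonian(af$spec, x, lam, u + h * (1:4 == j), ip, tt) -
             hamiltonian(af$spec, x, lam, u - h * (1:4 == j), ip, tt)) /
      (2 * h)
    expect_lt(abs(dj - anly[j]), 1e-6)
  }
})

test_that("already at the goal: zero control and zero effort", {
  af <- arm_fixture()
  xs <- c(af$theta0, rep(0, 10))
  sol <- solve_finite_horizon_arm(af$spec, xs, xs, T = 0.4, gamma = 0.5)
  expect_lt(sol$J_u, 1e-8)
  expect_lt(max(abs(sol$control)), 1e-3)
})

test_that("solver reaches the target and satisfies stationarity", {
  af <- arm_fixture()
  tgt <- af$hand0 + c(0.07, -0.07)
  sol <- solve_finite_horizon_arm(af$spec, af$x0, tgt, T = 0.45,
                                  gamma = 0.5)
  expect_true(sol$converged)
  expect_lt(sol$term_err, 1e-3)
  # Pontryagin stationarity at the solution: small control gradient
  expect_lt(sol$grad_norm, 1e-4)
  # deterministic given identical inputs
  sol2 <- solve_finite_horizon_arm(af$spec, af$x0, tgt, T = 0.45,
                                   gamma = 0.5)
  expect_identical(sol$J_u, sol2$J_u)
})

test_that("faster movements cost more effort", {
  af <- arm_fixture()
  tgt <- af$hand0 + c(0.08, -0.05)
  s1 <- solve_finite_horizon_arm(af$spec, af$x0, tgt, T = 0.5, gamma = 0.5)
  s2 <- solve_finite_horizon_arm(af$spec, af$x0, tgt, T = 0.4, gamma = 0.5)
  expect_gt(s2$J_u, s1$J_u)
})

test_that("small-amplitude solution matches the linearized plant", {
  af <- arm_fixture()
  # linearize the arm about rest by central differences
  f0 <- function(x, u) rewardctl:::arm_state_derivative(af$spec, x, u)
  x0 <- af$x0; n <- 12; h <- 1e-6
  A <- matrix(0, n, n); B <- matrix(0, n, 4)
  for (j in 1:n)
    A[, j] <- (f0(x0 + h * (1:n == j), rep(0, 4)) -
                 f0(x0 - h * (1:n == j), rep(0, 4))) / (2 * h)
  for (j in 1:4)
    B[, j] <- (f0(x0, h * (1:4 == j)) - f0(x0, -h * (1:4 == j))) / (2 * h)
  sysl <- structure(list(A = A, B = B, n = n), class = "lti_system")
  # 1 cm movement
  tgt <- af$hand0 + 0.01 * c(1, -1) / sqrt(2)
  ths <- arm_inverse_kinematics(af$spec, tgt)
  xs <- c(ths, rep(0, 10))
  T <- 0.22; gam <- 0.5
  # the arm terminal contract pins hand/joint position and velocity;
  # muscle states are free on both sides of the comparison
  lin <- solve_finite_horizon_linear(sysl, x0 - x0, xs - x0, T, gam,
                                     constrained = 1:4)
  nl <- solve_finite_horizon_arm(af$spec, x0, xs, T, gam,
                                 max_iter = 6000, tol_term = 2e-4,
                                 muscle_rest = FALSE)
  nlin <- min(nrow(lin$control), nrow(nl$control))
  d <- lin$control[1:nlin, ] - nl$control[1:nlin, ]
  rms <- sqrt(mean(d^2)) / sqrt(mean(lin$control[1:nlin, ]^2))
  expect_lt(rms, 0.05)
})

test_that("native duration search is consistent with the generic one", {
  af <- arm_fixture()
  tk <- task_params(af$hand0 + c(0.05, -0.05), 40)
  ip <- internal_params(vigor = 1 / 300, gamma = 0.5)
  od <- arm_optimal_duration(af$spec, af$x0, tk, ip, bracket = c(0.05, 2))
  expect_equal(od$status, "ok")
  # utility at the reported duration from an independent full-accuracy solve
  sol <- solve_finite_horizon_arm(af$spec, af$x0, rewardctl:::goal_state(af$spec, tk),
                                  od$T, ip$gamma, max_iter = 3000)
  u_check <- ip$rho * 40 * exp(-od$T / ip$gamma) - sol$J_u
  expect_equal(od$utility, u_check, tolerance = 2e-2)
  # nearby durations are no better
  for (dT in c(-0.03, 0.03)) {
    s <- solve_finite_horizon_arm(af$spec, af$x0, rewardctl:::goal_state(af$spec, tk),
                                  od$T + dT, ip$gamma, max_iter = 3000)
    expect_lt(ip$rho * 40 * exp(-(od$T + dT) / ip$gamma) - s$J_u,
              od$utility + 1e-3)
  }
})
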