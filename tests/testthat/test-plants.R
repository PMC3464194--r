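test_that("point-mass derivative matches a finite-difference oracle", {
  pm <- point_mass()
  expect_equal(point_mass_derivative(pm, c(0, 0), 0), c(0, 0))
  expect_equal(point_mass_derivative(pm, c(0, 1), 0), c(1, 0))
  # u = 2 N, m = 1 kg: integrate and differentiate the velocity numerically
  h <- 1e-4
  v <- 0; p <- 0
  for (i in 1:100) {
    d <- point_mass_derivative(pm, c(p, v), 2)
    p <- p + h * d[1]; v <- v + h * d[2]
  }
  expect_equal(v / (100 * h), 2, tolerance = 1e-10)
  expect_error(point_mass_derivative(pm, c(0, 0), c(1, 2)))
})

test_that("muscle filter is a unit-DC-gain critical cascade", {
  fp <- filtered_point_mass(tau = 0.04)
  eq <- muscle_filter_derivative(fp, 0, 0, 0)
  expect_equal(eq$da, 0); expect_equal(eq$de, 0)
  # step response settles at 1
  a <- 0; e <- 0; h <- 1e-4
  for (i in 1:10000) {
    d <- muscle_filter_derivative(fp, a, e, 1)
    a <- a + h * d$da; e <- e + h * d$de
  }
  expect_equal(a, 1, tolerance = 1e-6)
  # impulse response (t/tau^2) exp(-t/tau) peaks at t = tau
  a <- 0; e <- 1 / fp$tau   # unit impulse loaded into excitation
  tpk <- 0; apk <- -Inf
  for (i in 1:4000) {
    d <- muscle_filter_derivative(fp, a, e, 0)
    a <- a + h * d$da; e <- e + h * d$de
    if (a > apk) { apk <- a; tpk <- i * h }
  }
  expect_lt(abs(tpk - fp$tau), 5e-4)
  # linearity
  expect_equal(muscle_filter_derivative(fp, 1, 2, 3)$de +
                 muscle_filter_derivative(fp, 4, 1, -1)$de,
               muscle_filter_derivative(fp, 5, 3, 2)$de)
})

test_that("arm inertia matrix is SPD across the workspace", {
  for (obj in c("IIIa", "IIIb")) {
    spec <- planar_arm(obj)
    for (t1 in seq(0, pi, length.out = 5))
      for (t2 in seq(0, pi, length.out = 7)) {
        M <- rewardctl:::arm_inertia(spec, c(t1, t2))
        expect_equal(M, t(M))
        expect_true(min(eigen(M, symmetric = TRUE)$values) > 0)
      }
  }
})

test_that("muscle torques are linear with the documented gains", {
  spec <- planar_arm("IIIa")
  expect_equal(muscle_torques(spec, rep(0, 4)), c(0, 0))
  expect_equal(muscle_torques(spec, c(1, 0, 0, 0)), spec$Amom[, 1] * 700)
  a1 <- runif(4); a2 <- runif(4)
  expect_equal(muscle_torques(spec, a1 + a2),
               muscle_torques(spec, a1) + muscle_torques(spec, a2))
})

test_that("hand kinematics and Jacobian are consistent", {
  spec <- planar_arm("IIIa")
  expect_equal(hand_kinematics(spec, c(0, 0))$hand, c(spec$l1 + spec$l2, 0))
  expect_equal(hand_kinematics(spec, c(pi / 2, 0))$hand,
               c(0, spec$l1 + spec$l2), tolerance = 1e-12)
  th <- c(0.7, 1.2); h <- 1e-6
  J <- hand_kinematics(spec, th)$jacobian
  for (j in 1:2) {
    dp <- (hand_kinematics(spec, th + h * (1:2 == j))$hand -
             hand_kinematics(spec, th - h * (1:2 == j))$hand) / (2 * h)
    expect_lt(max(abs(J[, j] - dp)), 1e-6)
  }
  # inverse kinematics round trip (elbow-positive branch)
  tgt <- c(0.25, 0.35)
  thr <- arm_inverse_kinematics(spec, tgt)
  expect_gt(thr[2], 0)
  expect_equal(hand_kinematics(spec, thr)$hand, tgt, tolerance = 1e-10)
  expect_error(arm_inverse_kinematics(spec, c(1, 1)), "workspace")
})

test_that("arm dynamics: rest equilibrium and energy balance", {
  spec <- planar_arm("IIIb")
  expect_equal(arm_dynamics(spec, c(0.5, 1.1), c(0, 0), c(0, 0)), c(0, 0))
  # energy audit: with no field, d/dt (0.5 w' M w) = torque power
  th <- c(0.4, 1.3); om <- c(0.5, -0.3); tq <- c(1.2, 0.4)
  h <- 1e-6
  ke <- function(th, om)
    0.5 * as.numeric(t(om) %*% rewardctl:::arm_inertia(spec, th) %*% om)
  # half-step central difference along the exact flow
  st <- function(s) { # integrate for time s with small RK4 steps
    x <- c(th, om); n <- 40; hh <- s / n
    f <- function(x) c(x[3:4], arm_dynamics(spec, x[1:2], x[3:4], tq))
    for (i in seq_len(n)) {
      k1 <- f(x); k2 <- f(x + hh / 2 * k1); k3 <- f(x + hh / 2 * k2)
      k4 <- f(x + hh * k3)
      x <- x + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x
  }
  xp <- st(h); xm <- st(-h)
  dke <- (ke(xp[1:2], xp[3:4]) - ke(xm[1:2], xm[3:4])) / (2 * h)
  expect_equal(dke, sum(tq * om), tolerance = 1e-5)
})

test_that("C++ and R arm derivatives agree (with and without field)", {
  spec <- planar_arm("IIIb")
  x <- c(0.3, 1.2, 0.4, -0.2, runif(8, -0.1, 0.2))
  u <- runif(4, -0.3, 0.5)
  for (field in c(FALSE, TRUE)) {
    dR <- rewardctl:::arm_state_derivative(spec, x, u, field)
    dC <- as.numeric(arm_dyn_cpp(rewardctl:::arm_par_list(spec), x, u, field))
    expect_equal(dC, dR, tolerance = 1e-12)
  }
})

test_that("plant spec validation rejects bad parameters", {
  expect_error(point_mass(-1))
  expect_error(filtered_point_mass(tau = 0))
  expect_s3_class(planar_arm("IIIa"), "planar_arm_spec")
})
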