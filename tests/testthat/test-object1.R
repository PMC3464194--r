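# Closed-form point-mass results: discounted effort, optimal duration,
# parameter identification.

test_that("closed-form effort matches quadrature along the optimal path", {
  sol <- solve_finite_horizon_linear(lti_system(point_mass()),
                                     c(0, 0), c(0.35, 0), T = 0.75,
                                     gamma = 2, dt = 1e-4)
  expect_lt(abs(disc_effort_quadrature(sol, 2) - sol$J_u) / sol$J_u, 1e-6)
  expect_equal(sol$J_u, point_mass_effort(0.75, 0.35, 2), tolerance = 1e-9)
})

test_that("effort reduces to the undiscounted minimum-effort cost", {
  # gamma -> Inf limit of the double integrator: 12 A^2 m^2 / T^3
  expect_equal(point_mass_effort(0.75, 0.35, 1e9), 12 * 0.35^2 / 0.75^3,
               tolerance = 1e-6)
  expect_equal(point_mass_effort(1.2, 0.5, 1e9, m = 2),
               12 * 0.5^2 * 4 / 1.2^3, tolerance = 1e-6)
})

test_that("effort is strictly decreasing in duration", {
  Ts <- seq(0.2, 5, by = 0.1)
  ju <- vapply(Ts, point_mass_effort, 0, A = 1, gamma = 2)
  expect_true(all(diff(ju) < 0))
})

test_that("closed-form duration agrees with dense grid search", {
  Tg <- seq(0.005, 30, by = 5e-4)
  for (A in c(0.35, 1.40, 2.45)) for (r in c(1, 3))
    for (vg in c(0.5, 1, 50)) for (gam in c(0.5, 2, 4)) {
      u <- point_mass_utility(Tg, A, r, vg, gam)
      cf <- closed_form_duration(A, r, vg, gam)
      if (cf$viable) {
        expect_lt(abs(cf$T - Tg[which.max(u)]), 2e-3)
      } else {
        # below the viability bound the utility is negative everywhere
        expect_true(all(u < 0))
      }
    }
})

test_that("optimal duration increases with amplitude", {
  Ts <- vapply(seq(0.2, 2.4, by = 0.2),
               function(A) closed_form_duration(A, 1, 5, 2)$T, 0)
  expect_true(all(diff(Ts) > 0))
})

test_that("no stationary duration exists below the viability bound", {
  # vigor * r <= A^2 m^2 / gamma^3 has no interior optimum
  cf <- closed_form_duration(A = 2, r = 1, vigor = 0.4, gamma = 1)
  expect_false(cf$viable)
  cf2 <- closed_form_duration(A = 2, r = 1, vigor = 10, gamma = 1)
  expect_true(cf2$viable)
  # A = 0: take the reward immediately
  cf0 <- closed_form_duration(0, 2, 3, 1)
  expect_equal(cf0$T, 0)
  expect_equal(cf0$utility, 6)
})

test_that("duration depends on (vigor, gamma) only; utility scales with eps", {
  a <- closed_form_duration(1, 2, 5, 1.5, eps = 1)
  b <- closed_form_duration(1, 2, 5, 1.5, eps = 7)  # rho and eps both x7
  expect_equal(a$T, b$T)
  expect_equal(7 * a$utility, b$utility)
})

test_that("identification round-trips generated durations", {
  vg <- 1; gam <- 2
  T1 <- closed_form_duration(0.35, 1, vg, gam)$T
  T2 <- closed_form_duration(2.45, 3, vg, gam)$T
  id <- identify_parameters(c(0.35, 1, T1), c(2.45, 3, T2))
  expect_true(id$ok)
  expect_equal(id$vigor, vg, tolerance = 1e-6)
  expect_equal(id$gamma, gam, tolerance = 1e-6)
})

test_that("identification reproduces the printed marmoset means", {
  id <- identify_parameters(c(0.35, 1, 0.75), c(2.45, 3, 1.84))
  expect_true(id$ok)
  f1 <- closed_form_duration(0.35, 1, id$vigor, id$gamma)$T
  f2 <- closed_form_duration(2.45, 3, id$vigor, id$gamma)$T
  expect_lt(abs(f1 - 0.75), 1e-6)
  expect_lt(abs(f2 - 1.84), 1e-6)
})

test_that("identification agrees with brute-force 2-D grid minimization", {
  id <- identify_parameters(c(0.35, 1, 0.75), c(2.45, 3, 1.84))
  err <- function(lv, lg) {
    vg <- exp(lv); gam <- exp(lg)
    a <- closed_form_duration(0.35, 1, vg, gam)
    b <- closed_form_duration(2.45, 3, vg, gam)
    if (!a$viable || !b$viable) return(Inf)
    (a$T - 0.75)^2 + (b$T - 1.84)^2
  }
  ctr <- c(log(30), log(1)); wid <- c(2, 2)
  for (stage in 1:5) {   # zooming log-grid
    lv <- seq(ctr[1] - wid[1], ctr[1] + wid[1], length.out = 21)
    lg <- seq(ctr[2] - wid[2], ctr[2] + wid[2], length.out = 21)
    E <- outer(lv, lg, Vectorize(err))
    ij <- which(E == min(E), arr.ind = TRUE)[1, ]
    ctr <- c(lv[ij[1]], lg[ij[2]]); wid <- wid / 8
  }
  expect_lt(abs(exp(ctr[1]) - id$vigor) / id$vigor, 1e-3)
  expect_lt(abs(exp(ctr[2]) - id$gamma) / id$gamma, 1e-3)
})

test_that("infeasible duration ratios are flagged, not fabricated", {
  # tamarin means sit just below the sqrt(A2/A1) (r1/r2)^(1/4) boundary
  id <- identify_parameters(c(0.35, 1, 0.66), c(2.45, 3, 1.32))
  expect_false(id$ok)
})
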