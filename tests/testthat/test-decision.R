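# Utility-based choice and the synthetic-cohort pipeline.

test_that("option utility: monotonicity in distance and reward", {
  ip <- fig2_internal()
  expect_equal(as.numeric(option_utility(0, 2, ip)), ip$vigor * 2 * ip$eps)
  u <- vapply(seq(0.35, 2.45, by = 0.35),
              function(A) as.numeric(option_utility(A, 3, ip)), 0)
  expect_true(all(diff(u) < 0))
  ur <- vapply(1:4, function(r) as.numeric(option_utility(1, r, ip)), 0)
  expect_true(all(diff(ur) > 0))
})

test_that("indifference point: reference case and grid cross-check", {
  ip <- fig2_internal()
  # equal rewards: farther is always worse, crossover at the reference
  same <- indifference_point(ip, c(0.35, 3), 3, range = c(0.35, 2.45))
  expect_equal(same, 0.35, tolerance = 1e-3)
  # the documented example: reference (r=1, 0.35 m), test r=3
  xpt <- indifference_point(ip, c(0.35, 1), 3)
  expect_true(is.finite(xpt))
  expect_gt(xpt, 0.35); expect_lt(xpt, 2.45)
  # bisection equals the sign change on a 1 mm grid
  u_ref <- as.numeric(option_utility(0.35, 1, ip))
  Ag <- seq(0.35, 2.45, by = 1e-3)
  ug <- vapply(Ag, function(A) as.numeric(option_utility(A, 3, ip)), 0)
  flip <- Ag[min(which(ug <= u_ref))]
  expect_lt(abs(xpt - flip), 2e-3)
  # no crossing inside a too-small range
  expect_true(is.na(indifference_point(ip, c(0.35, 1), 3,
                                       range = c(0.35, 0.7))))
})

test_that("softmax choice probabilities behave", {
  expect_equal(choice_probability(2, 2, 1), 0.5)
  expect_gt(choice_probability(2, 1, 1e-6), 1 - 1e-9)
  set.seed(5)
  for (i in 1:20) {
    j <- rnorm(2); b <- runif(1, 0.1, 3)
    expect_equal(choice_probability(j[1], j[2], b) +
                   choice_probability(j[2], j[1], b), 1)
  }
})

test_that("cohort sampling honors the printed statistics", {
  spec <- cohort_spec(marmoset_cond, N = 4, n = 200, label = "m")
  set.seed(10)
  d <- sample_cohort(spec)
  expect_equal(nrow(d), 200)
  se1 <- marmoset_cond$sem[1] * 2 / sqrt(200)
  expect_lt(abs(mean(d$T1) - 0.75), 3 * marmoset_cond$sem[1] * 2 / sqrt(200) +
              1e-9)
  expect_true(all(d$T1 > 0 & d$T2 > 0))
  # degenerate spread: all pairs equal the means
  tiny <- cohort_spec(transform(marmoset_cond, sem = 1e-12), n = 5)
  expect_equal(unname(as.matrix(sample_cohort(tiny))),
               matrix(rep(c(0.75, 1.84), each = 5), 5),
               tolerance = 1e-9)
  # seed reproducibility
  set.seed(3); a <- sample_cohort(spec)
  set.seed(3); b <- sample_cohort(spec)
  expect_identical(a, b)
})

test_that("zero-variance cohorts reduce to the mean-duration monkey", {
  tiny_m <- cohort_spec(transform(marmoset_cond, sem = 1e-12), n = 3,
                        label = "marmoset0")
  tiny_t <- cohort_spec(transform(tamarin_cond, sem = 1e-12), n = 3,
                        label = "tamarin0")
  set.seed(1)
  z <- stevens_pipeline(tiny_m, tiny_t)
  id <- identify_parameters(c(0.35, 1, 0.75), c(2.45, 3, 1.84))
  expect_equal(z$marmoset$monkeys$vigor[1], id$vigor, tolerance = 1e-6)
  expect_equal(z$marmoset$monkeys$gamma[1], id$gamma, tolerance = 1e-6)
  # the mean marmoset prefers the large reward strictly below 2.10 m only
  expect_equal(z$marmoset$reversal, 2.10, tolerance = 1e-9)
  # mean tamarin sits below the identifiability boundary -> boundary monkey,
  # which prefers the large reward at every distance
  expect_equal(z$tamarin$n_boundary, 3)
  expect_true(is.na(z$tamarin$reversal))
})

test_that("vigor and discount dissociate choice shift and speed", {
  ref <- internal_params(vigor = 50, gamma = 2)
  lowv <- internal_params(vigor = 16, gamma = 2)
  lowg <- internal_params(vigor = 50, gamma = 1)
  ref_ip <- indifference_point(ref, c(0.35, 1), 3, range = c(0.35, 40))
  lowv_ip <- indifference_point(lowv, c(0.35, 1), 3, range = c(0.35, 40))
  lowg_ip <- indifference_point(lowg, c(0.35, 1), 3, range = c(0.35, 40))
  # both shifts favor the small/near option...
  expect_lt(lowv_ip, ref_ip)
  expect_lt(lowg_ip, ref_ip)
  # ...but with opposite effects on movement duration
  T_ref <- closed_form_duration(1, 1, 50, 2)$T
  expect_gt(closed_form_duration(1, 1, 16, 2)$T, T_ref)  # low vigor: slower
  expect_lt(closed_form_duration(1, 1, 50, 1)$T, T_ref)  # low gamma: faster
})

test_that("identified parameter clouds of the two species are separable", {
  set.seed(21)
  # the published parameter clouds show identified animals, so use the
  # resampling route here (boundary monkeys all collapse onto one gamma)
  z <- stevens_pipeline(monkey_cohort("marmoset", 60),
                        monkey_cohort("tamarin", 60),
                        unidentifiable = "resample")
  X <- rbind(cbind(log(z$marmoset$monkeys$vigor),
                   log(z$marmoset$monkeys$gamma)),
             cbind(log(z$tamarin$monkeys$vigor),
                   log(z$tamarin$monkeys$gamma)))
  y <- rep(0:1, each = 60)
  # accuracy of the best linear boundary: scan projection directions and
  # take the best threshold along each
  acc <- 0
  for (ang in seq(0, pi, length.out = 361)) {
    p <- X %*% c(cos(ang), sin(ang))
    yo <- y[order(p)]
    cum0 <- cumsum(yo == 0)
    n1_right <- sum(y == 1) - (seq_along(yo) - cum0)
    side_a <- (cum0 + n1_right) / length(y)
    acc <- max(acc, side_a, 1 - side_a)
  }
  expect_gt(acc, 0.9)
})

test_that("pipeline is reproducible and respects the resample option", {
  set.seed(2); a <- stevens_pipeline(monkey_cohort("marmoset", 20),
                                     monkey_cohort("tamarin", 20))
  set.seed(2); b <- stevens_pipeline(monkey_cohort("marmoset", 20),
                                     monkey_cohort("tamarin", 20))
  expect_identical(a$marmoset$monkeys, b$marmoset$monkeys)
  set.seed(2)
  r <- stevens_pipeline(monkey_cohort("marmoset", 20),
                        monkey_cohort("tamarin", 20),
                        unidentifiable = "resample")
  expect_equal(r$marmoset$n_boundary, 0)
  expect_equal(r$tamarin$n_boundary, 0)
})
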