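# Utility-based choice: option utilities, indifference points, softmax
# choice probabilities, and the synthetic-monkey spatial-discounting
# pipeline (cohort sampling + parameter identification + utility analysis).

#' Utility of a reward-at-distance option (point-mass displacement)
#'
#' The maximal discounted utility of travelling an amplitude `A` to collect a
#' reward `r`, for a point-mass mover: `max_T J_inf(T)` in closed form.
#'
#' @param A distance to the reward (m).
#' @param r reward magnitude.
#' @param internal an [internal_params()] (or a list with vigor, eps, gamma).
#' @param m mover mass (kg).
#' @return scalar utility; `-Inf` is never returned — if no duration gives
#'   positive utility the maximal (non-positive) utility is still reported
#'   with attribute `viable = FALSE`.
#' @export
option_utility <- function(A, r, internal, m = 1) {
  stopifnot(A >= 0, r >= 0)
  if (r == 0) return(structure(0, viable = A == 0))
  cf <- closed_form_duration(A, r, internal$vigor, internal$gamma,
                             eps = internal$eps, m = m)
  if (!cf$viable) {
    # utility supremum is 0 at T -> Inf but never attained; report the
    # best over a wide grid for continuity of comparisons
    return(structure(0, viable = FALSE))
  }
  structure(cf$utility, viable = TRUE, T = cf$T)
}

#' Indifference point between a near/small and a far/large option
#'
#' The test distance at which the utility of the large-reward option drops to
#' the reference-option utility, found by bisection to 1 mm.
#'
#' @param internal an [internal_params()].
#' @param reference numeric `c(A, r)` for the reference option.
#' @param test_r reward of the test option.
#' @param range distances (m) within which to search.
#' @param m mover mass (kg).
#' @return the indifference distance (m), or `NA` if the utilities do not
#'   cross within `range`.
#' @export
indifference_point <- function(internal, reference, test_r,
                               range = c(0.35, 2.45), m = 1) {
  u_ref <- as.numeric(option_utility(reference[1], reference[2], internal, m))
  f <- function(A) as.numeric(option_utility(A, test_r, internal, m)) - u_ref
  flo <- f(range[1]); fhi <- f(range[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
  uniroot(f, range, tol = 1e-3)$root
}

#' Two-option softmax choice probability
#'
#' \eqn{p(\mathrm{large}) = 1/(1 + e^{-(J_{large} - J_{small})/\beta})}.
#'
#' @param J_large,J_small option utilities.
#' @param beta temperature (> 0): larger = more random.
#' @return probability of choosing the large option.
#' @export
choice_probability <- function(J_large, J_small, beta) {
  stopifnot(beta > 0)
  1 / (1 + exp(-(J_large - J_small) / beta))
}

#' Cohort specification for synthetic-monkey sampling
#'
#' Printed behavioral summary statistics of a species: mean +/- s.e.m. of
#' displacement duration in two (amplitude, reward) conditions, the number of
#' animals behind the s.e.m. (so sd = sem * sqrt(N)), and the synthetic
#' cohort size.
#'
#' @param conditions data.frame with columns `A` (m), `r`, `mean` (s),
#'   `sem` (s); exactly two rows.
#' @param N animals behind the s.e.m. (default 4).
#' @param n cohort size (default 100).
#' @param label species label.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(conditions, N = 4, n = 100, label = "") {
  stopifnot(nrow(conditions) == 2,
            all(c("A", "r", "mean", "sem") %in% names(conditions)),
            all(conditions$mean > 0), all(conditions$sem > 0), n >= 1)
  structure(list(conditions = conditions, N = N, n = n, label = label),
            class = "cohort_spec")
}

#' Built-in cohort statistics of the two monkey species
#'
#' Mean +/- s.e.m. displacement durations for one reward at 0.35 m and three
#' rewards at 2.45 m.
#'
#' @param species `"marmoset"` or `"tamarin"`.
#' @param n cohort size.
#' @return a [cohort_spec()].
#' @export
monkey_cohort <- function(species = c("marmoset", "tamarin"), n = 100) {
  species <- match.arg(species)
  stats <- switch(species,
    marmoset = data.frame(A = c(0.35, 2.45), r = c(1, 3),
                          mean = c(0.75, 1.84), sem = c(0.061, 0.082)),
    tamarin  = data.frame(A = c(0.35, 2.45), r = c(1, 3),
                          mean = c(0.66, 1.32), sem = c(0.047, 0.050)))
  cohort_spec(stats, N = 4, n = n, label = species)
}

#' Sample duration pairs for a synthetic cohort
#'
#' Draws `n` i.i.d. pairs (T1, T2) from Gaussians with the condition means
#' and sd = sem * sqrt(N). Non-positive draws are resampled; if resampling
#' exceeds 100 * n attempts an error is raised.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `T1`, `T2`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sds <- spec$conditions$sem * sqrt(spec$N)
  out <- matrix(NA_real_, spec$n, 2)
  i <- 0L; tries <- 0L
  while (i < spec$n) {
    if ((tries <- tries + 1L) > 100L * spec$n)
      stop("resampling budget exceeded for cohort '", spec$label, "'")
    d <- rnorm(2, mean = spec$conditions$mean, sd = sds)
    if (any(d <= 0)) next
    i <- i + 1L
    out[i, ] <- d
  }
  data.frame(T1 = out[, 1], T2 = out[, 2])
}

# identify one monkey; infeasible draws handled per `unidentifiable`
.identify_monkey <- function(cond, T1, T2, unidentifiable, gamma_bracket) {
  id <- identify_parameters(c(cond$A[1], cond$r[1], T1),
                            c(cond$A[2], cond$r[2], T2),
                            gamma_bracket = gamma_bracket)
  if (id$ok) return(c(vigor = id$vigor, gamma = id$gamma, boundary = 0))
  if (unidentifiable == "resample") return(NULL)
  # boundary monkey: discount pinned at the bracket top (effectively
  # undiscounted); vigor the geometric mean of the two implied values
  gam <- gamma_bracket[2]
  v <- sqrt(.vigor_implied(gam, cond$A[1], cond$r[1], T1) *
              .vigor_implied(gam, cond$A[2], cond$r[2], T2))
  c(vigor = v, gamma = gam, boundary = 1)
}

#' Spatial-discounting cohort pipeline
#'
#' For each species: sample a synthetic cohort of duration pairs, identify
#' (vigor, gamma) per monkey from the closed-form amplitude/duration law,
#' compute the utility of the large-reward option at each grid distance and
#' of the small-reward reference, and report the preference-reversal
#' distance: the smallest grid distance at which the cohort-median
#' large-option utility no longer exceeds the reference utility.
#'
#' Duration pairs whose ratio falls below the identifiability boundary admit
#' no (vigor, gamma) root. With `unidentifiable = "boundary"` (default) such
#' monkeys are assigned the top of the gamma bracket — an effectively
#' undiscounted animal, which prefers the large reward at every distance;
#' with `"resample"` they are redrawn (this truncates the cohort toward
#' steep discounters and shifts the reversal distance down).
#'
#' @param marmoset,tamarin [cohort_spec()]s (defaults: [monkey_cohort()]).
#' @param grid test distances (m) for the large-reward option.
#' @param unidentifiable `"boundary"` or `"resample"`.
#' @param gamma_bracket identification bracket (s).
#' @return list of class `stevens_result`, one element per species: a list
#'   with `monkeys` (data.frame: T1, T2, vigor, gamma, boundary, u_ref and
#'   one utility column per grid distance), `median_diff` (per distance),
#'   `reversal` (m, or NA if none), and `indifference` (per-monkey, m).
#' @export
stevens_pipeline <- function(marmoset = monkey_cohort("marmoset"),
                             tamarin = monkey_cohort("tamarin"),
                             grid = seq(0.35, 2.45, by = 0.35),
                             unidentifiable = c("boundary", "resample"),
                             gamma_bracket = c(1e-2, 1e3)) {
  unidentifiable <- match.arg(unidentifiable)
  run_species <- function(spec) {
    cond <- spec$conditions
    ref <- c(cond$A[1], cond$r[1])
    rows <- vector("list", spec$n)
    i <- 0L; tries <- 0L
    while (i < spec$n) {
      if ((tries <- tries + 1L) > 100L * spec$n)
        stop("resampling budget exceeded for cohort '", spec$label, "'")
      d <- rnorm(2, mean = cond$mean, sd = cond$sem * sqrt(spec$N))
      if (any(d <= 0)) next
      par <- .identify_monkey(cond, d[1], d[2], unidentifiable, gamma_bracket)
      if (is.null(par)) next
      i <- i + 1L
      internal <- internal_params(vigor = par[["vigor"]],
                                  gamma = par[["gamma"]])
      u_ref <- as.numeric(option_utility(ref[1], ref[2], internal))
      u_l <- vapply(grid, function(A)
        as.numeric(option_utility(A, cond$r[2], internal)), numeric(1))
      # continuous indifference point (distance where preference flips)
      f <- function(A) as.numeric(option_utility(A, cond$r[2], internal)) - u_ref
      ip <- if (f(grid[1]) <= 0) grid[1] else {
        hi <- max(grid)
        while (f(hi) > 0 && hi < 100) hi <- hi * 2
        if (f(hi) > 0) Inf else uniroot(f, c(grid[1], hi), tol = 1e-3)$root
      }
      rows[[i]] <- c(T1 = d[1], T2 = d[2], par, u_ref = u_ref,
                     setNames(u_l, paste0("u_", round(100 * grid))),
                     indifference = ip)
    }
    monkeys <- as.data.frame(do.call(rbind, rows))
    diffs <- monkeys[paste0("u_", round(100 * grid))] - monkeys$u_ref
    med <- apply(diffs, 2, median)
    idx <- which(med <= 0)
    list(monkeys = monkeys,
         median_diff = setNames(med, paste0(round(100 * grid), "cm")),
         reversal = if (length(idx)) grid[min(idx)] else NA_real_,
         indifference = monkeys$indifference,
         n_boundary = sum(monkeys$boundary))
  }
  structure(list(marmoset = run_species(marmoset),
                 tamarin = run_species(tamarin), grid = grid),
            class = "stevens_result")
}

#' @export
print.stevens_result <- function(x, ...) {
  for (sp in c("marmoset", "tamarin")) {
    r <- x[[sp]]$reversal
    cat(sprintf("%-9s reversal: %s  (boundary monkeys: %d)\n", sp,
                if (is.na(r)) "none within grid" else
                  sprintf("%.0f cm", 100 * r),
                x[[sp]]$n_boundary))
  }
  invisible(x)
}
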