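# Controlled objects: point mass, muscle-filtered point mass, two-joint
# planar arm. All dynamics are deterministic continuous-time; noise and
# discretization live in the closed-loop simulator.

#' Point-mass plant (Object I)
#'
#' A unit-dimensional inertial point driven directly by force, \eqn{m\ddot p = u}.
#' State is (position, velocity).
#'
#' @param m mass in kg (default 1, as in the reference simulations).
#' @return an object of class `point_mass_spec`.
#' @export
point_mass <- function(m = 1) {
  stopifnot(is.numeric(m), length(m) == 1, is.finite(m), m > 0)
  structure(list(m = m), class = c("point_mass_spec", "plant_spec"))
}

#' Muscle-filtered point-mass plant (Object II)
#'
#' A point mass driven through a critically-cascaded second-order linear
#' filter (a minimalist muscle model): \eqn{\dot e = (u - e)/\tau},
#' \eqn{\dot a = (e - a)/\tau}, \eqn{m\ddot p = g\,a}. State is
#' (position, velocity, activation, excitation).
#'
#' @param m mass in kg.
#' @param tau muscle time constant in seconds (default 0.04).
#' @param g activation-to-force gain (default 1).
#' @return an object of class `filtered_point_spec`.
#' @export
filtered_point_mass <- function(m = 1, tau = 0.04, g = 1) {
  stopifnot(m > 0, tau > 0, is.finite(g))
  structure(list(m = m, tau = tau, g = g),
            class = c("filtered_point_spec", "plant_spec"))
}

# Default moment-arm matrix (m): the source prints only a placeholder, so
# the muscle set is reconstructed on the principle that muscular strength is
# matched to the inertia it moves: the torque-gain matrix G = Amom * Fmax
# satisfies G G' = q^2 M(theta_ref), giving one biarticular antagonist pair
# (shoulder + elbow coupling, like biceps/triceps long heads) and one
# single-joint elbow pair. With any other (e.g. purely single-joint) muscle
# set the effort metric is dominated by actuator asymmetry and movement
# durations decouple from the limb's inertial anisotropy, contradicting the
# reported direction/duration/inertia covariation. Reference posture
# (75, 75) deg; gain scale q = 48 puts peak activations in a natural range.
.default_Amom <- function(p, Fmax, theta2_ref = deg2rad(75), q = 48) {
  Mref <- .arm_inertia_params(p, theta2_ref)
  L <- t(chol(Mref))
  G <- q * cbind(L[, 1], -L[, 1], L[, 2], -L[, 2])
  sweep(G, 2, Fmax, "/")
}

.arm_inertia_params <- function(p, theta2) {
  ct <- cos(theta2)
  m11 <- p$I1 + p$I2 + p$m1 * p$c1^2 +
    p$m2 * (p$l1^2 + p$c2^2 + 2 * p$l1 * p$c2 * ct)
  m12 <- p$I2 + p$m2 * (p$c2^2 + p$l1 * p$c2 * ct)
  m22 <- p$I2 + p$m2 * p$c2^2
  matrix(c(m11, m12, m12, m22), 2, 2)
}

# Velocity-dependent curl force field (N s/m): hand force F = D v,
# perpendicular to velocity and energy-neutral. The original robot-handle
# study's printed matrix has a positive (anti-damping) eigendirection with a
# ~65 ms doubling time; under a naive controller with 130 ms sensory delay
# that field is unstabilizable and trials never terminate, so the curl
# variant standard in that literature is used as the default.
.default_D <- function() matrix(c(0, -4, 4, 0), 2, 2)

#' Two-joint planar arm plant (Object III)
#'
#' A shoulder/elbow planar arm actuated by two antagonist muscle pairs, each
#' muscle a second-order linear filter with time constant `tau`. Joint torques
#' are `Amom %*% (Fmax * a)`. Two published parameter sets are built in:
#' `"IIIa"` (target-jump study) and `"IIIb"` (force-field study). State is
#' (theta[2], omega[2], a[4], e[4]), angles in radians.
#'
#' @param object `"IIIa"` or `"IIIb"`, or `NULL` when all segment parameters
#'   are given explicitly.
#' @param l1,l2 segment lengths (m).
#' @param I1,I2 segment moments of inertia (kg m^2).
#' @param m1,m2 segment masses (kg).
#' @param c1,c2 center-of-mass distances from the proximal joint (m).
#' @param Fmax maximal muscle forces (N), length 4.
#' @param Amom 2 x 4 moment-arm matrix (m).
#' @param tau muscle time constant (s).
#' @param D 2 x 2 hand-velocity force-field matrix (N s/m); used only when a
#'   simulation switches the field on.
#' @return an object of class `planar_arm_spec`.
#' @export
planar_arm <- function(object = c("IIIa", "IIIb"), l1 = NULL, l2 = NULL,
                       I1 = NULL, I2 = NULL, m1 = NULL, m2 = NULL,
                       c1 = NULL, c2 = NULL,
                       Fmax = c(700, 382, 572, 449),
                       Amom = NULL, tau = 0.04,
                       D = .default_D()) {
  if (is.null(l1)) {
    object <- match.arg(object)
    p <- switch(object,
      IIIa = list(l1 = .30, l2 = .33, I1 = .025,  I2 = .045,
                  m1 = 1.4, m2 = 1.1, c1 = .11,  c2 = .16),
      IIIb = list(l1 = .33, l2 = .34, I1 = .0141, I2 = .0188,
                  m1 = 1.93, m2 = 1.52, c1 = .165, c2 = .19))
  } else {
    object <- "custom"
    p <- list(l1 = l1, l2 = l2, I1 = I1, I2 = I2,
              m1 = m1, m2 = m2, c1 = c1, c2 = c2)
  }
  if (is.null(Amom)) Amom <- .default_Amom(p, Fmax)
  stopifnot(all(unlist(p) > 0), length(Fmax) == 4, all(Fmax > 0),
            all(dim(Amom) == c(2, 4)), tau > 0, all(dim(D) == c(2, 2)))
  structure(c(p, list(Fmax = as.numeric(Fmax), Amom = unname(Amom),
                      tau = tau, D = unname(D), object = object)),
            class = c("planar_arm_spec", "plant_spec"))
}

#' @export
print.plant_spec <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# state dimension of each plant
state_dim <- function(spec) UseMethod("state_dim")
#' @export
state_dim.point_mass_spec <- function(spec) 2L
#' @export
state_dim.filtered_point_spec <- function(spec) 4L
#' @export
state_dim.planar_arm_spec <- function(spec) 12L

control_dim <- function(spec) UseMethod("control_dim")
#' @export
control_dim.point_mass_spec <- function(spec) 1L
#' @export
control_dim.filtered_point_spec <- function(spec) 1L
#' @export
control_dim.planar_arm_spec <- function(spec) 4L

#' Point-mass state derivative
#'
#' @param spec a [point_mass()] spec.
#' @param state numeric (p, v).
#' @param control scalar force (N).
#' @return numeric (dp, dv).
#' @export
point_mass_derivative <- function(spec, state, control) {
  stopifnot(inherits(spec, "point_mass_spec"),
            length(state) == 2, length(control) == 1)
  c(state[2], control / spec$m)
}

#' Muscle-filter derivative
#'
#' The cascade \eqn{\dot e = (u - e)/\tau}, \eqn{\dot a = (e - a)/\tau};
#' unit DC gain, impulse-response peak at \eqn{t = \tau}.
#'
#' @param spec a [filtered_point_mass()] or [planar_arm()] spec (supplies tau).
#' @param a,e activation and excitation vectors (same length as `u`).
#' @param u control vector.
#' @return list with elements `da` and `de`.
#' @export
muscle_filter_derivative <- function(spec, a, e, u) {
  stopifnot(spec$tau > 0, length(a) == length(e), length(e) == length(u))
  list(da = (e - a) / spec$tau, de = (u - e) / spec$tau)
}

# inertia matrix M(theta); textbook two-link planar form, I about the com
arm_inertia <- function(spec, theta) {
  ct <- cos(theta[2])
  m11 <- spec$I1 + spec$I2 + spec$m1 * spec$c1^2 +
    spec$m2 * (spec$l1^2 + spec$c2^2 + 2 * spec$l1 * spec$c2 * ct)
  m12 <- spec$I2 + spec$m2 * (spec$c2^2 + spec$l1 * spec$c2 * ct)
  m22 <- spec$I2 + spec$m2 * spec$c2^2
  matrix(c(m11, m12, m12, m22), 2, 2)
}

# velocity-dependent (Coriolis/centripetal) matrix C(theta, omega)
arm_coriolis <- function(spec, theta, omega) {
  h <- spec$m2 * spec$l1 * spec$c2 * sin(theta[2])
  matrix(c(-h * omega[2], -h * (omega[1] + omega[2]),
           h * omega[1], 0), 2, 2, byrow = TRUE)
}

#' Joint torques from muscle activations
#'
#' `T = Amom %*% (Fmax * a)`; linear in the activation vector.
#'
#' @param spec a [planar_arm()] spec.
#' @param a activation 4-vector.
#' @return torque 2-vector (N m).
#' @export
muscle_torques <- function(spec, a) {
  stopifnot(inherits(spec, "planar_arm_spec"), length(a) == 4)
  as.numeric(spec$Amom %*% (spec$Fmax * a))
}

#' Planar-arm forward kinematics
#'
#' Shoulder at the origin, x rightward, y forward; angles in radians.
#'
#' @param spec a [planar_arm()] spec.
#' @param theta joint angles (shoulder, elbow), rad.
#' @param omega joint velocities, rad/s (default zero).
#' @return list with `hand` (m), `velocity` (m/s) and the 2 x 2 `jacobian`.
#' @export
hand_kinematics <- function(spec, theta, omega = c(0, 0)) {
  stopifnot(inherits(spec, "planar_arm_spec"), length(theta) == 2)
  s1 <- sin(theta[1]); c1 <- cos(theta[1])
  s12 <- sin(theta[1] + theta[2]); c12 <- cos(theta[1] + theta[2])
  hand <- c(spec$l1 * c1 + spec$l2 * c12, spec$l1 * s1 + spec$l2 * s12)
  J <- matrix(c(-spec$l1 * s1 - spec$l2 * s12, -spec$l2 * s12,
                spec$l1 * c1 + spec$l2 * c12,  spec$l2 * c12),
              2, 2, byrow = TRUE)
  list(hand = hand, velocity = as.numeric(J %*% omega), jacobian = J)
}

#' Inverse kinematics for the planar arm
#'
#' Returns the elbow-positive solution (elbow angle in (0, pi)), matching the
#' initial postures used throughout (e.g. (75, 75) deg).
#'
#' @param spec a [planar_arm()] spec.
#' @param hand target hand position (m).
#' @return joint angles (rad).
#' @export
arm_inverse_kinematics <- function(spec, hand) {
  r2 <- sum(hand^2)
  c2 <- (r2 - spec$l1^2 - spec$l2^2) / (2 * spec$l1 * spec$l2)
  if (c2 > 1 || c2 < -1) stop("hand target outside the arm workspace")
  th2 <- acos(c2)                      # elbow-positive branch
  th1 <- atan2(hand[2], hand[1]) -
    atan2(spec$l2 * sin(th2), spec$l1 + spec$l2 * cos(th2))
  c(th1, th2)
}

#' Planar-arm joint accelerations
#'
#' \eqn{\ddot\theta = M(\theta)^{-1} (T + W\dot\theta - C(\theta,\dot\theta)\dot\theta)}
#' with the optional velocity-dependent force field mapped to joint space as
#' \eqn{W = J^\top D J}.
#'
#' @param spec a [planar_arm()] spec.
#' @param theta,omega joint angles (rad) and velocities (rad/s).
#' @param torques net muscle torque 2-vector (N m).
#' @param field_on logical; apply the hand-velocity force field `spec$D`.
#' @return joint acceleration 2-vector (rad/s^2).
#' @export
arm_dynamics <- function(spec, theta, omega, torques, field_on = FALSE) {
  stopifnot(length(theta) == 2, length(omega) == 2, length(torques) == 2)
  M <- arm_inertia(spec, theta)
  tau_net <- torques - as.numeric(arm_coriolis(spec, theta, omega) %*% omega)
  if (field_on) {
    J <- hand_kinematics(spec, theta)$jacobian
    tau_net <- tau_net + as.numeric(t(J) %*% spec$D %*% J %*% omega)
  }
  as.numeric(solve(M, tau_net))
}

# full 12-state derivative (R reference; the solver uses the C++ twin)
arm_state_derivative <- function(spec, x, u, field_on = FALSE) {
  theta <- x[1:2]; omega <- x[3:4]; a <- x[5:8]; e <- x[9:12]
  dd <- arm_dynamics(spec, theta, omega, muscle_torques(spec, a), field_on)
  mf <- muscle_filter_derivative(spec, a, e, u)
  c(omega, dd, mf$da, mf$de)
}

#' Direction-dependent apparent (effective) endpoint inertia
#'
#' The effective mass felt at the hand when pushing in direction `angle`:
#' \eqn{1 / (e^\top J M^{-1} J^\top e)}.
#'
#' @param spec a [planar_arm()] spec.
#' @param theta posture (rad).
#' @param angle movement direction (rad, 0 = +x).
#' @return scalar effective mass (kg).
#' @export
apparent_inertia <- function(spec, theta, angle) {
  J <- hand_kinematics(spec, theta)$jacobian
  Minv <- solve(arm_inertia(spec, theta))
  e <- c(cos(angle), sin(angle))
  1 / as.numeric(t(e) %*% J %*% Minv %*% t(J) %*% e)
}

deg2rad <- function(deg) deg * pi / 180
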