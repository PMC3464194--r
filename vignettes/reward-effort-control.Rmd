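---
title: "A discounted reward/effort model of decision making and motor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discounted reward/effort model of decision making and motor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardctl)
```

## The model

A goal is a rewarded state: position `x*` with reward magnitude `r`. The
value of reaching it in a prospective duration $T$ from the current state is

$$J_\infty(T) \;=\; \rho\, r\, e^{-T/\gamma} \;-\;
  \epsilon \int_0^T e^{-s/\gamma}\, \lVert u(s)\rVert^2\, ds ,$$

where the integral is evaluated at the *optimal* finite-horizon control
driving the plant to rest at `x*` in exactly $T$ seconds. The first term is
the discounted reward; the second the discounted effort $J_u(T)$. Because
effort falls and discounting deepens as $T$ grows, their difference
typically has a single interior maximum: the emergent movement duration
$T^*$, with $J_\infty(T^*)$ the option's utility. One objective therefore
serves decision making (compare utilities across options), kinematics
(duration, speed profiles), and online control (re-solve from the current
state estimate each step and apply the first control increment —
receding-horizon control). Removing the $e^{t/\gamma}$ prefactor makes the
criterion independent of current time, so the policy is stationary and
re-planning from any on-path state reproduces the original plan; that
time-consistency is what makes the zero-noise closed loop coincide with the
open-loop optimum, and it is why the utility used at decision time equals
the discounted reward minus the effort actually spent executing the chosen
action.

### Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `r` | reward units | task | reward magnitude at the goal |
| `rho` | utility / reward | — | subjective value of reward |
| `eps` | utility / effort | 1 | subjective cost of effort |
| `vigor = rho/eps` | — | — | the only ratio behavior depends on |
| `gamma` | s | task | discount time constant; smaller = steeper |
| `tau` | s | 0.04 | muscle filter time constant |
| `Delta` (`delay_s`) | s | 0.13 | sensory feedback delay |
| `eta` (`dt`) | s | 0.001 | integration/control grid |
| `sigma_sdn_m` | — | 0/1 | multiplicative motor noise per step |
| `sigma_sin_s` | obs. units | 0/0.001 | additive observation noise |

Scaling `rho` and `eps` jointly rescales utilities and leaves $T^*$ and all
choices unchanged (tested). Lower vigor shifts choices toward low-effort
options *and* slows movements; lower `gamma` shifts choices the same way
but *speeds* movements — the central dissociation the tests assert.

## Solvers

**Linear plants (point mass, muscle-filtered point mass).** The Pontryagin
system with discounted quadratic effort is linear; writing $\nu$ for the
terminal costate, $k = 1/\gamma$, and the discounted controllability Gramian
$W(T)=\int_0^T e^{-ks} e^{As} B B^\top e^{A^\top s}\, ds$,

$$u^*(t) = -\tfrac{e^{kt}}{2\epsilon} B^\top e^{A^\top (T-t)}\nu, \qquad
  \nu = -2\epsilon e^{-kT} W(T)^{-1} d, \qquad
  J_u(T) = \epsilon\, e^{-kT}\, d^\top W(T)^{-1} d,$$

with $d = x^* - e^{AT}x_0$. This "backward" parametrization stays bounded
for marginally stable plants (the forward-costate form overflows for the
muscle-filtered plant beyond a few seconds). The state path is evaluated in
closed form on the grid, so the boundary condition holds to solver roundoff
(`boundary_error` ~ 1e-14). For the double integrator the Gramian reduces
to exponential moments, giving an analytic duration law: $T^*$ solves
$\mathrm{vigor}\cdot r = \Psi(T)$ with

$$\Psi(T) = A^2 m^2\!\left[\frac{J_0}{D} +
 e^{-kT}\frac{(J_1 - T J_0)^2}{k D^2}\right],\quad
 J_n = \int_0^T s^n e^{-ks} ds,\ D = J_2 J_0 - J_1^2 .$$

$\Psi$ is decreasing with $\Psi(\infty) = A^2m^2/\gamma^3$: an interior
optimum exists iff $\mathrm{vigor}\cdot r$ exceeds that bound, otherwise
"no viable action". In the undiscounted limit $J_u \to 12 A^2 m^2/T^3$, the
classical minimum-effort cost, which the tests verify.

**Parameter identification.** Given two (amplitude, reward, duration)
conditions, stationarity yields vigor explicitly per condition at any
`gamma`, reducing identification to one root in $\log\gamma$ (more robust
than the nested bracketing one might first try). The undiscounted limit
fixes a feasibility boundary: identification requires
$T_2/T_1 > \sqrt{A_2/A_1}\,(r_1/r_2)^{1/4}$ (≈ 2.0103 for the cohort task).

**Arm.** The two-joint planar arm (12 states: two joints, four
muscle-filter actuators) is solved by gradient descent on the discretized
problem: forward Euler rollout, exact discrete adjoint for the gradient,
Barzilai–Borwein steps with backtracking, and terminal equality constraints
by quadratic penalty with ×10 continuation until the hand-space terminal
error is below 1 mm / 5 mm s⁻¹. Warm starts carry both the control path and
the penalty stage across neighboring horizons, which makes the
golden-section duration search and receding-horizon replanning tractable.
Replanning runs every 10 ms with a duration refresh (narrow golden section)
on the same cadence — the desk-scale profile; the control grid stays at
1 ms.

## Closed loop

The estimator is a delayed-observation Kalman filter: observations are the
position and velocity of the controlled object delayed by `Delta`; a filter
runs at the delayed time (process noise from the signal-dependent motor
noise at the buffered control) and the current estimate is bridged with the
stored controls. For the arm the same structure is implemented with the
observation substituted at the delayed time (the printed observation noise,
1e-3, makes the optimal gain ≈ 1) and nonlinear forward re-prediction — the
re-prediction always uses the unperturbed model, so a force field acting on
the plant is invisible to the controller. Target jumps reach the controller
at `onset + Delta` (delayed perception).

Movement end follows the velocity-threshold rule (3 cm/s) with a 50 ms hold
window: the movement ends at the last downward threshold crossing after
which speed stays below threshold for the hold window, which skips
mid-movement dips of multi-peaked profiles.

### Numerical and design choices

* **Motor noise convention.** The printed `sigma_SDNm = 1` is interpreted
  per integration step, `u(1 + sigma * xi)` at 1 ms, as in the cited
  discrete-time optimal-feedback-control models. Under a
  $\sqrt{\eta}$-scaled SDE convention the same number injects ~31× the
  control per step and every trial diverges, so that reading is untenable.
* **Terminal-correction floor.** As the state nears the goal the remaining
  effort vanishes and the discounted reward alone favors $T \to 0$: the
  re-planned duration collapses to the bracket minimum and the gains grow
  without bound, so under multiplicative noise the loop sustains jitter at
  the stopping threshold. Noisy Object II simulations therefore use a
  0.25 s floor on the prospective duration (`Tmin`), below every planned
  movement duration in the studied conditions (0.37–0.90 s); zero-noise
  simulations keep 0.05 s.
* **Muscle rectification.** Activations are left linear (they may
  transiently go negative). A hard non-negativity clamp makes the dynamics
  nondifferentiable exactly at the rest state about which the
  linearization cross-check is evaluated; with antagonist pairs and a
  quadratic effort cost the optimal activations are near-antisymmetric
  anyway.
* **Moment arms.** The source prints no moment-arm matrix. Conventional
  single-joint arms make the direction/duration anisotropy track
  shoulder-torque demand and decouple it from the limb's inertial
  anisotropy, contradicting the reported covariation. The default muscle
  set instead matches strength to load: the torque-gain matrix
  `G = Amom %*% diag(Fmax)` satisfies $GG^\top \propto M(\theta_{\rm ref})$
  at the (75°, 75°) reference posture, which requires one biarticular
  antagonist pair (all arms 1.2–6.2 cm). Under this metric the
  direction/duration profile follows the endpoint effective mass
  (Spearman ≈ 0.88 over 12 directions).
* **Force field.** The field matrix is also unprinted. The saddle matrix
  of the original robot-handle study has an anti-damping eigendirection
  (~65 ms doubling time) that a naive controller with a 130 ms sensory
  delay cannot stabilize — simulated trials orbit indefinitely. The
  default is the energy-neutral viscous curl field of the same literature,
  at a gain where the delayed naive loop converges while showing the
  signature curved paths, terminal hooks and multi-peaked speed profiles.
* **Unidentifiable cohort draws.** Duration pairs below the feasibility
  boundary admit no (vigor, gamma); the cohort analysis assigns them the
  top of the gamma bracket — an effectively undiscounted animal that
  prefers the large reward at every tested distance. Resampling them away
  instead (available as `unidentifiable = "resample"`) truncates the
  cohort toward steep discounters and moves the marmoset reversal one grid
  step early (175 cm instead of the printed 210 cm). The printed tamarin
  means sit just *below* the boundary (2.000 vs 2.0103), so roughly half
  of tamarin draws are boundary animals — consistent with tamarins never
  reversing preference within the grid.
* **Cohort summary.** The reversal distance uses the cohort median of the
  per-monkey utility difference at each grid distance; the median monkey's
  indifference point sits close to the 175 cm grid point, which is why the
  handling of unidentifiable draws can move the grid-quantized answer.

## What the synthetic cohort does and does not establish

The generator emulates exactly the published pipeline: Gaussian duration
pairs (sd = s.e.m. × √4) around printed species means, deterministic
identification, zero-noise Object I utilities. It does not emulate real
locomotion (no trial-to-trial control noise in the displacement itself, no
within-animal variability structure, no learning), so a green cohort test
establishes that the *model pipeline* reproduces the published population
statistic, not that the model fits individual animals.

## Known limitations

* The controller applies the deterministic optimum in receding horizon;
  gains are not noise-adapted (no LQG synthesis), per the model's scope.
* The arm replans every 10 ms rather than every step, a documented
  desk-scale compromise; zero-noise trajectories are unaffected
  (time-consistency) and perturbed trials change only at the millisecond
  scale.
* Golden-section duration search assumes a unimodal utility curve; a
  25-point pre-scan guards against violations, which were never observed.
* The boundary handling of unidentifiable cohort draws is a modelling
  choice at a genuine knife edge (see above); both handlings are
  implemented.
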