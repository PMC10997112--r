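---
title: "Walking stability with PD foot-placement control: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking stability with PD foot-placement control: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkstab)
```

## The walking system

`walkstab` analyzes a *walking system*: a linearized single-link inverted
pendulum (point-mass body on a rigid, massless leg) whose foot placement
is chosen at each step by a proportional-derivative feedback law. Between
steps the center of mass (CoM) state $(x, v)$ evolves as

$$\dot x = v, \qquad \dot v = \omega^2 (x - p),$$

where $p$ is the contact point and $\omega = \sqrt{g/l}$ the pendulum
eigenfrequency ($g = 9.81\,\mathrm{m\,s^{-2}}$, $l$ the effective leg
length). The solutions are hyperbolic cosines and sines, which the
package uses directly: **propagation is always closed-form**, and a
numerical ODE integrator appears only as an independent oracle in the
test suite, never in the library path. A step is an instantaneous shift
of $p$ — no collision, no energy loss, no swing-leg or double-support
dynamics. These are the model's deliberate simplifications; it describes
one horizontal direction at a time, and two instances (one *progressive*,
one *alternating*) compose into planar walking.

### Time and parity conventions

Time $t = 0$ is a midstance. Steps occur at $t = (n + \tfrac12) T_\mathrm{step}$
and midstances at $t = n T_\mathrm{step}$; the controller senses the CoM
state relative to the contact point, $(q_n, v_n)$ with $q = x - p$, at
midstance $n$ and realizes the placement at the following step event. The
alternating offset sign starts at $(-1)^0 = +1$ for step 0; which
physical side that labels is arbitrary and only a convention. All
quantities are SI (m, s) throughout; cadence (steps/min) and leg length
are converted once on input ($T_\mathrm{step} = 60/\mathrm{cadence}$,
$\omega = \sqrt{g/l}$).

The velocity solution is implemented as
$v(t) = (x_0 - p)\,\omega \sinh(\omega t) + v_0 \cosh(\omega t)$ — the
exact time-derivative of the position solution, verified against the
ODE oracle. Similarly, in the transition matrix and orbit formulas the
terms pairing with $b_d$ (which carries seconds) read $2s/\omega$, and
those pairing with $b_p$ read $s\omega$; dimensional analysis fixes the
grouping, and the package validates it by reproducing the published
spectral norm of the constant-XCoM-offset controller (0.21) and the
stable/unstable derivative-gain quartet (see below).

### Event handling

`simulate_walker()` is event-driven: the state is re-anchored at step
events and perturbations, and evaluated in closed form at arbitrary
sample times, so the sampling interval `dt` affects only the output grid,
never the computed states (asserted to $10^{-12}$ in the tests).
Coincident events resolve in a fixed, documented order: perturbation,
then midstance bookkeeping, then the step, then sampling. A perturbation
scheduled exactly at a step event therefore reaches the controller's
input; one scheduled exactly at a midstance is part of the state that
midstance records.

## Periodic orbits and the step-to-step map

With $c = \cosh(\omega T_\mathrm{step}/2)$,
$s = \sinh(\omega T_\mathrm{step}/2)$, the midstance reference states are

$$q^\mathrm{ref} = 0,\quad v^\mathrm{ref} = \frac{b_o}{2s/\omega - b_d}
\quad\text{(progressive, period } T_\mathrm{step}),$$
$$q_n^\mathrm{ref} = \frac{(-1)^n b_o}{2c - b_p},\quad v^\mathrm{ref} = 0
\quad\text{(alternating, period } 2T_\mathrm{step}).$$

The denominators vanish on the lines $b_d = 2s/\omega$ and $b_p = 2c$
respectively. With $b_o \neq 0$ no periodic orbit of this structure
exists there, so `periodic_orbit()` raises an explicit singular-orbit
error (condition class `walkstab_singular_orbit`) rather than returning
infinities; with $b_o = 0$ the rest solution is returned. This is a
deliberate reading of a formal "every system has a periodic orbit"
statement that silently excludes these measure-zero lines.

`midstance_map()` composes half-step flow, placement, and half-step flow
exactly. Its Jacobian at the reference state is the transition matrix

$$A = \begin{pmatrix} c^2 + s^2 - c\,b_p & (2s/\omega - b_d)\,c \\
(2c - b_p)\,s\,\omega & c^2 + s^2 - s\,\omega\,b_d \end{pmatrix},$$

identical for both stepping modes and independent of $b_o$ (tested by
sweeping $b_o$ and the mode). Deviations propagate as
$\delta_{n+1} = A\,\delta_n$ — the per-step recursion, not a map from
$\delta_0$ — and the orbit is asymptotically stable iff the spectral norm
$\rho(A) < 1$. Eigenvalues come from the characteristic polynomial in
closed form (quadratic formula; modulus $\sqrt{\det A}$ for a complex
pair), which keeps boundary cases exact where an iterative factorization
would round.

**Stability tolerance.** `stability_report()` reports
`stable = rho < 1 - 1e-12` and flags `|rho - 1| <= 1e-12` as `marginal`:
a marginal orbit (eigenvalue on the unit circle) is not asymptotically
stable, and the tolerance keeps points constructed exactly on a boundary
line from flipping verdicts through rounding.

## The stability region and cadence

The three inequalities $2c - b_p > 0$, $2s/\omega - b_d < 0$ and
$b_d < b_p c/(\omega s)$ delimit a triangle in the $(b_p, b_d)$ plane
with vertices $(2s^2/c,\, 2s/\omega)$, $(2c,\, 2s/\omega)$ and
$(2c,\, 2c^2/(\omega s))$. On the triangle's **edges** $\rho(A) = 1$
exactly: an eigenvalue $-1$ on $b_p = 2c$ (since $A_{11} = s^2 - c^2$),
$+1$ on $b_d = 2s/\omega$ (since $A_{22} = c^2 - s^2$), and a
unit-determinant pair on the diagonal edge. On the *full* infinite lines
only the pinned eigenvalue survives — the other can exceed 1 in
magnitude — so boundary-calibration tests sample the edge segments. The
inequality verdict and the eigenvalue verdict agree everywhere off the
boundary (property-tested on $10^4$ random parameter tuples).

`region_grid()` samples $\rho$ on a rectangular grid (default
$b_p \in [0, 3.5]$, $b_d \in [0, 1.6]$, $351 \times 161$ points — chosen
to resolve the triangle for human-scale parameters; no canonical axes
exist, so these defaults are the package's own). `region_vs_cadence()`
projects the triangle onto the gain axes as cadence varies:
$b_p \in [2s^2/c,\, 2c]$ and $b_d \in [2s/\omega,\, 2c^2/(\omega s)]$.

**A caution on monotonicity.** Three of the four interval endpoints
decrease monotonically with increasing cadence, matching the qualitative
prediction that slower walking demands higher gains. The upper $b_d$
limit $2c^2/(\omega s)$ does **not**: $\mathrm{d}(c^2/s)/\mathrm{d}T$
has the sign of $2s^2 - c^2$, so the endpoint is unimodal in cadence
with a minimum where $\omega T_\mathrm{step}/2 = \operatorname{arsinh}(1)$
(about 106 steps/min for $\omega = 3.13\,\mathrm{s^{-1}}$, inside the
usual 60–140 range). It is higher at 60 than at 140 steps/min, but dips
in between. The test suite asserts the true unimodal law; a blanket
"all four endpoints are monotone" check is knowingly left failing as a
record of this property.

At fixed $T_\mathrm{step}$, increasing leg length (decreasing $\omega$)
grows the triangle: its area is $2/(c\,\omega\,s)$, increasing as
$\omega$ falls (tested over $l \in [0.7, 1.3]$ m).

### The constant-XCoM-offset special case

Placing each foot at a fixed offset from the extrapolated center of mass
($\mathrm{XCoM} = q + v/\omega$) corresponds to $b_p = c + s$,
$b_d = (c+s)/\omega$. Algebraically $\det A = 0$ at these gains — one
deadbeat eigenvalue — and $\rho(A) \approx 0.21$ for
$\omega = 3.13\,\mathrm{s^{-1}}$, $T_\mathrm{step} = 0.5$ s. These gains
satisfy all three inequalities across the tested step-time range.

## Gain estimation by regression

`estimate_gains()` fits ordinary least squares of the placement
displacement $\Delta p_n = p_{n+1} - p_n$ on the midstance state:
`delta_p ~ q + v` (progressive) or `delta_p ~ parity + q + v`
(alternating). Under the control law the slopes identify $b_p$ and $b_d$
directly, and the parity coefficient (or intercept) identifies $b_o$.

Choices worth stating:

* **Regressand.** Absolute placement, displacement, and
  placement-relative-to-CoM differ only by terms linear in the same
  regressors; $\Delta p$ makes the slopes equal the gains with no
  post-transformation. The identification is validated by parameter
  recovery on synthetic walkers rather than by symbolic derivation.
* **Parity regressor.** Alternating data are handled with an explicit
  $(-1)^n$ column rather than sign-folding odd steps — equivalent under
  the model and easier to diagnose.
* **Diagnostics.** Adjusted $R^2$ is the headline statistic, with
  single-predictor (position-only, velocity-only) adjusted $R^2$
  alongside; per-slope standard errors are reported and no p-value
  machinery is attached, since exactly one model is fit per dataset.
* **Degeneracy.** Noise-free on-orbit data have zero regressor variance;
  the fit aborts with a singular-design error naming the collinear
  columns instead of returning NA slopes.
* A minimum of 3 (progressive) or 4 (alternating) steps matches the
  parameter count; adjusted $R^2$ is undefined at the minimum and can be
  negative for small samples — both are allowed and surface as-is.

### What noise does and does not bias

With additive motor noise on the realized placement, the regression error
is independent of the regressors, so OLS is unbiased and consistent
(recovery is tested at $n$ = 200/1000/5000 across seeds). The same holds —
perhaps counterintuitively — for *sensory* noise on the controller's
inputs when the regression uses the true states: the sensed-noise term
lands in the residual, independent of the current regressors, and the
slopes stay consistent (verified over 30 seeds). Classical attenuation
toward zero appears only when the **recorded regressors** themselves
carry measurement error, as when a pelvis-marker proxy stands in for the
CoM; the test suite demonstrates exactly that variant. Real-data
concerns — marker-based CoM approximation, functional midstance
detection — are out of scope: midstance here is the model's temporal
midpoint.

## Synthetic gait

`generate_noisy_walk()` iterates the exact step dynamics from the
deterministic periodic orbit, adding per-step Gaussian noise
$\varepsilon_n \sim \mathcal N(0, \sigma_p^2)$ to the realized placement
and, optionally, sensory noise to the controller's inputs only. The
recorded states always satisfy the closed-form dynamics exactly; a noisy
placement shifts the next midstance deviation by
$-\varepsilon_n (c,\ \omega s)^\top$, so the stationary deviation
covariance solves the discrete Lyapunov equation
$\Sigma = A \Sigma A^\top + Q$ — used as an oracle in the tests. The
model itself prescribes no noise magnitudes; the package's fixture
defaults ($\sigma_p = 0.01$ m, i.e. centimeter-scale placement
variability) are conventions chosen to resemble human step-width
variability, stated here once and not tuned thereafter.

Reproducibility: a dataset is a pure function of (parameters, noise
spec, seed, n_steps). Motor and sensory channels draw from separately
seeded streams, and draws are consumed regardless of whether a channel's
SD is zero, so toggling one channel never shifts another's sequence.
Unstable parameters under noise abort with a divergence error (default
guard $|q| > 10$ m) reporting the step reached.

`perturbation_experiment()` reproduces the canonical protocol: start all
systems on a shared orbit, apply an instantaneous CoM offset at a stated
time, track the midstance deviation norm. For the example alternating
walker ($\omega = 3.13$, $b_p = 2.5$, $b_o = 0.02$,
$T_\mathrm{step} = 0.5$) with a $+1$ cm position offset at $t = 1$ s,
derivative gains $\{0.6, 1.1\}$ converge back to the orbit while
$\{0.3, 1.5\}$ diverge — monotonically for 0.3 (real dominant
eigenvalue, $\rho \approx 1.74$), oscillating for 1.5 (complex pair,
$\rho \approx 1.32$) — and the asymptotic decay ratio of the stable case
matches $\rho \approx 0.857$.

A step table records one row per step — index, midstance time, exact
$(q, v)$, contact point, next placement, $\Delta p$, parity. A
simulation over $N$ step periods yields $N$ records (midstances
$0 \ldots N-1$, each paired with the following placement).

## Problem sizes and scope

The shipped tests run the full pipeline at deliberately modest sizes —
noisy walks of 200–20 000 steps, $10^4$-point random parameter sweeps,
grids up to $351 \times 161$ — all closed-form work that completes in
seconds. Passing them shows the machinery is internally consistent and
recovers its own generating parameters; it does **not** show that human
walking obeys a constant-step-time PD law, that midstance is the right
sensing instant in slow walking, or anything about robustness to large
perturbations: $\rho(A)$ is a local, asymptotic quantity, and the package
deliberately offers no degree-of-stability measure or
viability/capturability analysis. Processing real motion-capture data is
likewise out of scope.
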