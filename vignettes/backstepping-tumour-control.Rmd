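---
title: "Methods: positive-input backstepping control of tumour growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positive-input backstepping control of tumour growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioctrl)
```

## Model and assumptions

The plant couples tumour volume $x$ (mm$^3$) and inhibitor serum level $y$
(mg/kg):

$$\dot x = a x - b x y, \qquad \dot y = -c y + u(t),$$

with proliferation rate $a$ (1/day), inhibition efficacy $b$ (kg/mg/day) and
clearance $c$ (1/day). The model assumes zero-order pharmacokinetics — the
input $u$ (mg/kg/day) acts directly on the serum level — and no carrying
capacity: an untreated tumour grows without bound at rate $a$. The plane
$x = 0$ is invariant (eradication is absorbing), and for $u \ge 0$ the state
quadrant $x, y \ge 0$ is forward-invariant. Default rates are the mouse-model
values $a = 0.27$, $b = 0.0074$, $c = \ln 2 / 3.9$ (drug half-life 3.9 days);
$c$ is always stored at full floating precision, never as a rounded literal.

## The control law

Backstepping treats the inhibitor level as a virtual control for the tumour
equation. Setting the set-point $y^\ast = k$ turns the tumour dynamics into
$\dot x = -(bk - a)x - bxe$ with tracking error $e = y - k$, so any gain
$k > a/b$ yields a positive net decay rate $d = bk - a$. The real input that
makes $e \to 0$ is

$$u(t) = \bar c k + \bar b \bar x(t)^2,$$

written with the *nominal* rates $\bar b, \bar c$ (the controller cannot know
the true plant) and the *measured* volume $\bar x$. Two structural properties
matter:

* **positivity** — a positive constant plus a square, so
  $u \ge \bar c k > 0$ for any real (even negative, noise-corrupted)
  measurement; no saturation or clipping is involved, and none is modelled
  because no physiological ceiling is specified;
* **output feedback** — only the tumour volume is measured; no
  inhibitor-level sensor or observer is needed.

`backstepping_controller()` validates $k > \bar a/\bar b$ at construction
(about 36.49 mg/kg at the default rates). Whether the *true* plant also
satisfies the condition is a separate diagnostic, `gain_margin()`, which
flags rather than fails: the robustness sweep deliberately explores
violations.

## Exponential stability and its envelopes

With $V = \tfrac12 x^2 + \tfrac12 e^2$, the closed loop gives
$\dot V = -d x^2 - c e^2$ exactly — the cross terms $\pm b x^2 e$ cancel —
hence $\dot V \le -\gamma V$ with $\gamma = 2\min\{d, c\}$ and

$$V(t) \le V(0) e^{-\gamma t}, \qquad
  |x(t)|, |e(t)| \le \beta e^{-\gamma t/2},$$

where the theory requires $\beta \ge \sqrt{x(0)^2 + e(0)^2}$; the package
uses exactly that value, the tightest valid envelope amplitude.
`check_decay()` certifies the three envelopes at every trajectory sample with
relative slack $10^{-6}$ and an absolute floor of $10^{-12}$ for near-zero
states. $\dot V$ is evaluated *analytically* at the samples; finite
differences would be dominated by differencing noise on the stiff initial
layer. At the reference configuration the constants are $d = 0.174$,
$\gamma = 0.348$/day and $\beta \approx 10000.18$.

## Robustness envelope

When the true rates deviate from nominal, the error dynamics see the lumped
disturbance $u_d(t) = -(c-\bar c)e + (b-\bar b)x^2$ (the rate $a$ never
enters: the law is structurally independent of it). Along a trajectory with
$|u_d| \le \delta_d$,

$$\dot V = -d x^2 - \bar c e^2 + e\,u_d
  \le -\bar\gamma \lVert X\rVert^2 + \delta_d \lVert X\rVert,
  \qquad \bar\gamma = \min\{d, \bar c\},$$

with $X = (x, e)$. Passing to $W = \sqrt V$ and applying the comparison
lemma, with $\lVert X \rVert = \sqrt{2V} = \sqrt2\,W$:

$$\dot W \le -\bar\gamma W + \tfrac{\delta_d}{\sqrt2}
  \;\Rightarrow\;
  \lVert X(t)\rVert \le \lVert X(0)\rVert e^{-\bar\gamma t}
  + \frac{\delta_d}{\bar\gamma}\bigl(1 - e^{-\bar\gamma t}\bigr).$$

The disturbance gain is $\delta_d/\bar\gamma$. A gain tightened by a further
factor $1/2$ is sometimes quoted for this bound, but it is **not** an
invariant of these trajectories: with the clearance rate 10–90 % *below*
nominal, simulated error norms exceed the halved envelope by up to ~56 %,
while the $\delta_d/\bar\gamma$ envelope above holds with equality only at
$t = 0$ for every stable perturbation in the sweep. `bibo_envelope()`
therefore implements the gain as derived. Two further instantiation choices:

* $\delta_d$ is taken as the empirical supremum of $|u_d|$ along the realized
  trajectory — the tightest checkable instance of the region-based
  assumption;
* $\bar\gamma$ uses the true-plant $d$ and the nominal clearance $\bar c$,
  matching the perturbed error dynamics (the $-\bar c e^2$ term comes from
  the law, the $-d x^2$ term from the plant).

The norm $\lVert X\rVert$ mixes mm$^3$ and mg/kg; the envelope is checked in
those raw units, as the theory states it, rather than after any
normalisation.

## Measurement models

* **Sinusoidal noise**: $\bar x(t) = x(t) + A\sin(\omega t)$ with the
  reference amplitude $A = 30$ mm$^3$ and $\omega = 0.1$ rad per time unit.
  The formula is applied literally with $t$ in days. Negative noisy
  measurements pass through unclamped — the law squares them. Note that the
  squared sinusoid biases the mean dose upward, so under persistent noise
  the inhibitor level settles *above* the set-point; only input positivity
  is asserted for noisy runs.
* **Sampled feedback**: the volume is measured every `sample_period` days
  (reference: 3 days), starting at $t = 0$, and held (zero-order hold), so
  $u$ is piecewise constant. The simulator integrates piecewise between
  measurement updates so each dose discontinuity lands on an integrator
  restart.

## Numerical choices

* **Stiffness.** With $x_0 = 10^4$ mm$^3$ the initial dose is
  $\approx 7.4\times10^5$ mg/kg/day and $y$ traverses decades within
  $10^{-3}$ day. The integrator is adaptive `lsoda` (switching to BDF on
  the stiff layer) with `rtol = atol = 1e-8` and the initial step capped at
  $10^{-6}$ day. Explicit fixed-step solvers either stall or smear the
  boundary layer.
* **Cross-validation.** The suite checks the adaptive solution against the
  closed forms for $\dot y = -cy + u$ and $\dot x = (a - by)x$ (relative
  error $\le 10^{-8}$ over 50 days) and against an independent fixed-step
  classical Runge–Kutta integration at $h = 10^{-4}$ day over the first two
  days (relative error $\le 10^{-5}$). The Runge–Kutta comparison for $x$ is
  restricted to samples where $x$ exceeds $10^{-3}$ mm$^3$: beyond the
  boundary layer $x$ falls *below the absolute tolerance* (reaching
  $\sim10^{-40}$ by day 2), where no relative statement about the adaptive
  solution is meaningful.
* **Grid robustness.** Halving the output spacing and tightening both
  tolerances tenfold changes the terminal state by $< 10^{-6}$ relative.
  This is asserted at $x_0 = 100$ mm$^3$, where the terminal volume stays
  orders of magnitude above `atol`; from $x_0 = 10^4$ the transient drives
  $x$ below the tolerance floor within half a day, and terminal $x$ is
  solver noise at *any* horizon.
* **Eigenvalue reporting.** The extended (virtual-input) system
  $(\dot x, \dot y, \dot u) = (ax - bxy, -cy + u, -vu)$ has an
  upper-triangular Jacobian; eigenvalues are read off the diagonal exactly,
  reported sorted by descending real part, and compared with a dense
  eigensolver in the tests. Printed comparisons are made after rounding to 4
  decimals (reference tables print truncated values: the tumour-row value
  $0.26999$ prints as $0.2699$ truncated, $0.2700$ rounded).
* **Steady-state metrics.** Means over the final 10 % of the horizon with a
  flatness flag (spread below 1 % of the mean magnitude, or below `atol` for
  near-zero signals). The decay-rate metric is a log-linear least-squares
  fit over the post-peak samples above the `atol` floor; on boundary-layer
  runs it reflects the fast transient (tens per day), not the asymptotic
  $d$ — both behaviours are real, and the metric is reported, not asserted.

## Reference scenarios and the sweep

`builtin_scenarios()` fixes the study conditions: initial state
$x_0 = 10^4$ mm$^3$, $y_0 = 0$, gain $k = 60$, 100-day horizon, output every
0.1 day. The uncertainty sweep applies fractional perturbations
$\delta \in \{\pm0.1, \ldots, \pm1.0\}$ to each rate individually and to all
three jointly. Grid points with $\delta = -1$ would zero a rate and are
reported as infeasible rather than simulated; points where the true plant
violates the gain condition ($bk \le a$, e.g. $a$ perturbed $+70\,\%$ or
more) are simulated and *flagged* unstable — there the loop settles at a
nonzero tumour volume instead of eradication, which is the theory's
prediction, not a failure of the software. The transient tumour overshoot of
the continuous-time loop is far smaller than figures produced by fixed-step
real-time simulators of the same loop; the metric is computed and reported
but not asserted against any printed percentage.

These deterministic scenarios *are* the synthetic data of this package: they
emulate idealised therapy (perfect actuation, exact model structure,
sinusoidal or sampled measurement corruption). They do not emulate
stochastic physiological variability, inter-dose pharmacokinetics, model
mismatch beyond rate scaling, or actuator limits — so passing envelopes here
certify the mathematics and the numerics, not clinical performance.

## Problem sizes

The default test suite and the acceptance script integrate 100–150-day
horizons at 0.1-day output spacing (1001–1501 samples) and an 80-point
perturbation grid (76 simulated runs); the full suite completes in a few
seconds on one CPU.

## Known limitations

* The error-norm envelope mixes units (mm$^3$ vs mg/kg); scaling either
  state rescales $\beta$, $\delta_d$ and the envelopes coherently but
  changes their numeric values.
* No input saturation: with a large initial tumour the commanded first dose
  is physiologically implausible. The theory places no ceiling on $u$, and
  imposing one would void the global guarantees.
* The sinusoid frequency of the noisy scenario is interpreted per day
  (literal formula); an alternative per-second reading would make the noise
  essentially quasi-static over a run.
* Zero-order pharmacokinetics and the absence of carrying-capacity dynamics
  are inherited from the model, not design choices of this package.
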