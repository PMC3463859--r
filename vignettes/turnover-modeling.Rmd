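---
title: "Turnover modeling of beta-amyloid lowering: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turnover modeling of beta-amyloid lowering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abetapkpd)
```

## The model and its assumptions

Aβ homeostasis in a compartment is modeled as a balance between zero-order
generation and first-order clearance. With the state expressed as a percent
of the concurrent vehicle control, and a drug that inhibits generation
through a sigmoidal concentration–effect term,

$$\frac{dA}{dt} = K_{in}\left[1 - \frac{I_{max}\,C(t)^\gamma}
{IC_{50}^\gamma + C(t)^\gamma}\right] - k_{out}\,A,
\qquad A(0) = 100,$$

and because the vehicle steady state is by construction 100%,
$K_{in} = 100\% \times k_{out}$. The model therefore has four free
parameters per compartment/analyte: $k_{out}$ (1/h), $I_{max}$ (fraction,
bounded at 1 — the mechanisms modeled are purely inhibitory, generation
cannot be inverted), $IC_{50}$ (in the drive's concentration unit), and
$\gamma$ (dimensionless).

Assumptions worth stating plainly:

* **Percent-of-control state.** Absolute Aβ levels are never simulated; the
  model lives on the normalized scale because that is the scale on which
  treated data are analyzed (each treated value divided by the mean of the
  concurrent vehicle animals in the same time × compartment × analyte
  stratum). Normalization removes non-specific drift shared with vehicle.
* **Caller-specified drive.** The concentration $C(t)$ driving the effect
  may be plasma, brain, or CSF concentration depending on what was
  measured; the package treats the drive as an opaque function of time and
  $IC_{50}$ inherits its unit, unchecked.
* **Independent compartments.** Brain and CSF are fit independently by
  default, each with its own four parameters; no brain→CSF transit is
  modeled. A shared-potency joint fit (`fit_turnover_shared()`, common
  $I_{max}/IC_{50}/\gamma$, per-compartment $k_{out}$) expresses the
  hypothesis that the two compartments see the same intrinsic drug effect
  and differ only in clearance kinetics.
* **No tolerance, rebound, or circadian baseline dynamics.**

The intrinsic exposure–response relationship
$R_{gen}(C) = 1 - I_{max} C^\gamma / (IC_{50}^\gamma + C^\gamma)$ contains
no $k_{out}$ and no PK; it is the natural compound-level summary. At
periodic steady state under repeated dosing, mass balance forces the
time-weighted average of $A$ over one period to equal
$100 \times \langle R_{gen} \rangle$, which is why the intrinsic curve also
predicts steady-state average lowering.

## Parameters that matter, defaults, and why

| Parameter | Unit | Default / typical | Notes |
|---|---|---|---|
| `kout` | 1/h | fit; mouse CSF Aβ40 ≈ 1.42, mouse brain Aβ42 ≈ 0.49 | governs onset/offset speed; offset half-time is $\ln 2 / k_{out}$ |
| `imax` | – | often fixed at 1 | full inhibitors (GSI-type); estimable for partial ones |
| `ic50` | drive unit | fit | choose the starting value near the drive's scale |
| `gamma` | – | free; fixable at 1 | steepness; weakly identified in shallow designs |
| allometric `a`, `b` | 1/h at 1 kg, – | fit; literature CSF Aβ40 values 0.415 and −0.36 | log–log OLS |

Fitting is done on transformed scales — $\log k_{out}$, logit $I_{max}$,
$\log IC_{50}$, $\log \gamma$ — so the constraints hold smoothly without
hard box bounds; an estimate pushed beyond ±15 on a transformed scale is
flagged as pinned.

## Numerical choices

* **Integration.** The default integrator is `deSolve::lsoda`
  (stiff-capable, adaptive) at `rtol = 1e-8`, `atol = 1e-10`, with the
  drive evaluated continuously, never staircased — accuracy during the
  hysteresis phase is the point. A second method (`"grid"`) takes exact
  exponential-integrator steps for the linear ODE assuming the inhibition
  term is piecewise linear on a refined grid (default spacing 0.05 h).
  It is the workhorse inside estimation, where thousands of trajectory
  evaluations are needed; both methods are tested against the analytic
  constant-concentration solution
  $A(t) = 100(1-I) + 100\,I\,e^{-k_{out}t}$.
* **Periodic steady state** is declared when the maximum absolute
  difference between successive periods falls below 0.01 percentage
  points, with a cap of 200 periods (an error beyond that); the period
  average uses a 2000-interval trapezoid.
* **Loss scale.** Residuals are formed on the percent scale by default,
  with a log-scale option. The observation model the generator uses is
  multiplicative lognormal, for which the log scale is the matched choice;
  the percent scale is retained as the default because it is what the
  field plots and because the choice must be explicit either way in the
  `fit_spec()`.
* **Multistart.** Five Levenberg–Marquardt runs from jittered transformed
  starts (Normal, SD 0.3, sub-seeds derived from the spec's seed); the best
  converged loss wins, and near-tied losses (<1%) with >10% parameter
  spread are flagged as possible multimodality.
* **Interpolated drives.** A tabulated drive carries a single explicit
  interpolation tag (`linear` or `loglinear`) rather than any automatic
  rise/decline switching — reproducibility over cleverness. Log-linear
  interpolation falls back to linear across zero concentrations.
  Extrapolation beyond the table is off by default; when enabled, times
  past the last node decay log-linearly at the final segment's rate.
* **Degenerate inputs.** Vehicle-only data raise an unidentifiability
  error; a treated stratum without concurrent vehicle raises an error
  naming the stratum; a single treated sampling time warns and proceeds —
  deliberately, so that the degeneracy of single-time-point dose–response
  designs shows up as exploded confidence intervals rather than being
  hidden (the test suite demonstrates a >5-fold relative CI inflation
  against a time-course design of the same size).

## What the synthetic generator emulates — and what it does not

`generate_study()` is the generative twin of the analysis model: per-animal
lognormal baselines (between-animal CV default 20% — a placeholder typical
of biomarker assays, not a literature value), model-predicted
percent-of-control at the animal's single destructive sampling time,
multiplicative lognormal observation noise with an optional additive floor,
and per-time-point concurrent vehicle groups. A repeated-sampling mode
(shared baseline across times) emulates dog/monkey/human CSF designs.
Sub-seeds are derived by hashing each animal's (dose, time, replicate)
coordinates, so extending a design never reshuffles existing animals'
draws.

With suitable truth configurations the generator reproduces the four
qualitative complexities seen in real programs — hysteresis loops,
deeper CSF than brain lowering at matched times with a dose-widening gap,
divergent brain/CSF time courses, and progressively blunted profiles as
$k_{out}$ follows the allometric law toward larger species — and the test
suite asserts each directionally.

What it does **not** emulate: assay matrix effects, quantification-limit
censoring beyond the additive floor, transgenic overexpression kinetics,
active transport between compartments, and any drug effect on clearance.
Passing tests on generated data therefore validate the estimation
machinery and the model's internal consistency, not the model's adequacy
for any particular real compound.

## Estimation design choices

* **Naive pooled fitting.** All animals' normalized values enter as
  independent observations. Destructive sampling yields one observation
  per animal per measure, so there is no within-animal information that a
  mixed-effects model could exploit at this granularity; pooled nonlinear
  least squares is the simplest estimator the data support.
* **Uncertainty.** Asymptotic SEs come from the numeric Jacobian at the
  optimum (delta method back to natural scales; Wald intervals built on
  the transformed scale so they respect constraints and contain the point
  estimate). The case bootstrap resamples animals within
  dose × time × compartment × analyte strata and **re-runs the
  normalization inside every replicate**: the concurrent-vehicle
  denominator is itself an estimate, and freezing it would leave its
  sampling error out of the intervals (in calibration runs this single
  choice moves 90% CI coverage from ~0.60 to ~0.92).
* **Problem sizes.** The recovery and calibration exercises in the tests
  use the 1–100 mg/kg five-dose ladder with eight sampling times over
  0.5–9 h and 3–4 animals per cell — a deliberately informative design
  with wide dynamic-range coverage and sampled onset and offset phases,
  the kind of time-course study this framework argues for over
  single-time-point dose–response designs. The stochastic calibration
  uses 100 replicate studies with 60 bootstrap resamples each.

## Allometry

`fit_power_law()` is ordinary least squares of $\log k_{out}$ on
$\log BW$ — standard allometric practice, exactly recoverable on noiseless
power-law data and equivariant under rescaling of body weight. Species
body weights are always inputs, never defaults. One honest wrinkle: the
literature CSF Aβ40 law ($0.415 \times BW^{-0.36}$) evaluated at a 25 g
mouse gives 1.57/h, while the directly fitted mouse value is 1.42/h —
about 10% apart. That is expected scatter around an allometric regression,
and the package reports both rather than forcing agreement.

## Known limitations

* The intrinsic-curve overlap comparison defaults to the $R_{gen}$ scale
  over each curve's 0–50% lowering band (200 log-spaced grid points from
  `min(ic50)/100` to `max(ic50) × 100`); comparison on observed-lowering
  scale is available but the original analyses' exact convention is not
  recoverable.
* Hysteresis summaries use the shoelace area of the time-ordered polygon;
  with sparse or noisy sampling the orientation tag can flip for loops
  near the degeneracy tolerance (default $10^{-6}$ of the bounding-box
  area).
* Parametric PK here (the Bateman one-compartment profile) is scaffolding
  for synthetic studies and regimen prediction, not a fitted PK model;
  programs with real concentration data should supply tabulated drives.
* No Bayesian or mixed-effects estimation, and no model selection beyond
  fixing/freeing $I_{max}$ and $\gamma$.
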