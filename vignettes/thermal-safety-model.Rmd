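---
title: "A lumped thermal-safety model for laser lithotripsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped thermal-safety model for laser lithotripsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lithotherm)
```

## The physical model and its assumptions

During laser lithotripsy the fibre deposits essentially all of its optical
power `W` as heat into the fluid filling the working space (a calyx or the
renal pelvis), while irrigation at flow rate `Q` and inflow temperature
`T_in` continuously exchanges fluid and the vessel wall conducts heat to
the surroundings at `T_0`.  `lithotherm` models the *volume-averaged*
temperature `T(t)` by a single energy balance,

$$\rho c V \frac{dT}{dt} = W\,1_{\mathrm{on}}(t)
  + \rho c Q\,(T_{\mathrm{in}} - T) - \beta\,(T - T_0),$$

with three modelling assumptions:

* **Perfect mixing.** Internal mixing is fast relative to wall losses, so
  a single temperature characterises the vessel.  In the in-vitro setting
  this is supported by two thermocouples at different positions reading
  the same signal; it means the model predicts a *lower bound* on the
  maximum local temperature and cannot resolve hot spots near the fibre
  tip.
* **Linear exchange.** Irrigation enters as an advective exchange term at
  the inflow temperature and wall loss as Newton cooling toward the bath.
  Both are linear in `T`, so the solution within any constant-power phase
  is a single exponential: rise while firing, decay after switch-off.
* **Constant properties.** `ρ` and `c` are fixed at their 25 °C water
  values; temperature dependence of fluid properties and any flow–
  temperature coupling are outside scope (those require spatially resolved
  CFD).  The fluid conductivity `k` is carried in `fluid_properties()` for
  configuration fidelity but does not enter the lumped solution, which
  parameterises all wall transport through `β`.

Within a phase of constant power the solution relaxes toward
$T^\star = (W + \rho c Q T_{\mathrm{in}} + \beta T_0)/(\rho c Q + \beta)$
with time constant $\tau = \rho c V/(\rho c Q + \beta)$: the equilibrium
temperature is independent of the vessel volume, while the time needed to
approach it is proportional to the volume.  This is why a small calyx both
heats and cools much faster than the whole collecting system, reaching
higher temperatures for the same firing time.  `temperature_at()`
propagates the phase solutions in closed form across arbitrary on/off
schedules ("operator duty cycle"), exactly continuous at every switch; at
a switch instant the left phase's endpoint is used, which continuity makes
observationally irrelevant.

The degenerate configuration `Q = 0, β = 0` has no steady state: all heat
stays in the vessel and the temperature rises linearly at `W/(ρcV)`.
`heat_load()` signals this as an error ("unbounded heating") while
`temperature_at()` handles it via the linear branch.

## Parameters, units and defaults

| Parameter | Meaning | Units (interface) | Default |
|---|---|---|---|
| `volume_ml` | vessel volume `V` | mL | preset (5.89 / 38.3) |
| `flow_ml_min` | irrigation rate `Q` | mL/min | 0 |
| `tin_c` | irrigation temperature | °C | `t0_c` |
| `t0_c` | bath/initial temperature | °C | preset (37 / 22) |
| `beta_w_per_c` | wall-loss coefficient `β = h·s` | W/°C | preset (1.15 / 1.36) |
| `k, rho, c` | fluid properties | SI | water at 25 °C |

Interfaces accept clinical units and convert to SI (m³, m³/s, W) on
ingestion; keeping the internals strictly SI avoids unit bugs, and the
offset-invariance of the linear model makes °C safe throughout.  `β` is
the product of a heat-transfer coefficient and an exchange area; the two
are never needed separately.  The Set A preset uses the least-squares
value 1.15 W/°C (fits near 1.14 have also been reported for the same
vessel; the difference is within the fit uncertainty).

## Thermal dose and its integration policy

Dose is accumulated as equivalent minutes at 43 °C,
$t_{43} = \int R^{43-T(t)}\,dt$ with `R` = 0 / 0.25 / 0.5 on the branches
`T ≤ 37`, `37 < T < 43`, `T ≥ 43` °C (branch points inclusive exactly as
written).  A curve held at 43 °C therefore accrues dose at 1 min/min, and
every degree above 43 doubles the rate.  The conventional damage threshold
is `t43 = 120` min.

Whether the cooldown after switch-off should count toward the dose is a
genuine policy choice; `lithotherm` integrates from laser-on over the full
curve *including* the decay, because the zero-`R` branch makes the natural
stopping rule exact: integration ends where the decay first reaches 37 °C
(located in closed form), beyond which the integrand is identically zero.
When the post-laser steady state itself exceeds 37 °C the integral does
not converge; it is then cut at a configurable horizon (default ten
off-phase time constants past the last off time) and flagged
`truncated = TRUE`, marking the value as a lower bound rather than
silently reporting convergence.

Numerics: analytic curves are integrated by adaptive quadrature per
constant-power phase (relative tolerance 1e-8), with each phase split at
its 37 °C and 43 °C crossings so the integrand is smooth on every piece
(it is continuous at 43 °C but jumps at 37 °C).  Sampled traces use the
composite trapezoid rule on the dose rate at the samples — appropriate for
0.1 s thermocouple data, and exact for constant curves.

## Safe firing time

`safe_firing_time()` returns the largest single-burst firing time whose
curve stays at or below the threshold.  The on-phase steady state
classifies three regimes:

* `T* ≤ 37 °C` (**no-dose**): the dose is identically zero and
  `tf_safe = Inf`.  This is the white region of the `T_in × Q` safety
  maps, and because `T*` is volume-independent the region is the same for
  every vessel size.
* `37 < T* < 43 °C` (**sub-43**): dose accrues at below 1 min/min, so
  `tf_safe` is finite but can be very large.
* `T* ≥ 43 °C` (**supra-43**): dose accrues super-linearly; `tf_safe` is
  minutes-scale.

Because `t43` is non-decreasing in the firing time, the solver brackets by
geometric growth and bisects to 1e-3 s; the bracket's monotonicity is
asserted as it grows.  The bracket is capped at 24 h: a sub-43 regime that
has not reached 120 equivalent minutes after a full day of uninterrupted
firing is reported as `tf_safe = Inf` with `capped = TRUE`.  This keeps
"effectively unbounded" distinguishable from the exactly dose-free
`no-dose` regime — the two differ in kind (a deep sub-43 plateau at, say,
38 °C accrues dose at ~0.001 min/min and would need weeks to cross the
threshold), and reporting the cap as a finite number would suggest a
precision the model does not have.  A truncated (non-convergent) dose that
is still below threshold at the cap additionally warns.

## Fitting the wall-loss coefficient

`β` is the only parameter not fixed by the experiment design, so
`fit_beta()` performs one-dimensional bounded least squares: the pooled
squared residuals between the analytic solution and one or more traces are
minimised over `β ∈ [1e-3, 1e2]` W/°C (`optimize()`, tolerance 1e-6).
Choices made where the design was open:

* **Fit window.** The rise phase, laser-on to laser-off, which is where
  `β` controls the curve in the canonical `Q = 0` design; configurable to
  include the decay.
* **Objective.** Unweighted least squares — thermocouple noise is assumed
  homoscedastic, as no noise model is reported for such data.
* **Pooling.** Multiple probes/runs enter with equal weight; for aligned
  grids this is provably equivalent to fitting the pointwise mean trace.
* **Safeguards.** A 41-point logarithmic scan first verifies the objective
  actually varies (flat ⇒ non-identifiability error, e.g. a trace with no
  temperature dynamics) and is unimodal before the local minimisation;
  estimates at the search bound warn.  The standard error is
  curvature-based, `se² = 2·σ̂²/(d²RSS/dβ²)`, the Gauss–Newton variance of
  a one-parameter nonlinear fit.

## Synthetic data: what it does and does not emulate

`generate_run()`/`generate_grid()` sample the analytic model on the
experimental timing (0.1 s sampling; 20 s irrigation-only, 60 s firing,
20 s decay) and add i.i.d. Gaussian noise, default σ = 0.2 °C — a
plausible T-type thermocouple precision, recorded here as an assumption
since no noise model accompanies such recordings.  The default grid
mirrors the validation design: powers {10, 40} W × flows {0, 20, 40}
mL/min × 5 runs.  Per-run sub-seeds derive deterministically from the
master seed, cell and run index, so any subset regenerates bit-identically.

The generator does *not* emulate probe-placement effects, spatial
gradients, flow-rate jitter between runs, or drift — so passing recovery
tests demonstrates correctness of the estimator under the stated noise
model, not robustness to every artefact of real thermocouple data.  In
particular the reported experimental flow rates are ranges (e.g.
14–15 mL/min); an option to jitter `Q` per run was considered and left
out of the default generator.

## Verification strategy and problem sizes

The analytic solution is verified against an independent numeric twin,
`ode_trace()`: classical fixed-step RK4 (via `deSolve`) restarted at every
power switch so discontinuities never fall inside a step.  The twin
converges at fourth order and agrees with the closed form to ~1e-13 °C on
the experiment-scale cases.  The test suite exercises, among others:
oracle agreement on 100 random configurations and schedules over 0–200 s
(RK4 step 0.01 s, well below the ≥ 2 s relaxation times the generator
produces); quadrature versus dense trapezoid integration of the dose;
solver self-consistency (dose at the returned `tf_safe` within 0.1 min of
threshold); and a 200-repetition Monte-Carlo recovery study of `β` at
σ = 0.2 °C with 5 runs per repetition.  These sizes keep the full suite
around two minutes on one CPU while leaving the statistical assertions
comfortably powered.

## Known limitations

* One temperature per vessel: no hot-spot prediction near the fibre tip;
  the model is a lower bound on local maxima.
* `β` must be calibrated per vessel (or, in vivo, per tissue
  configuration); it is not predicted from first principles.
* Constant fluid properties; no coupling of flow to temperature.
* The dose model is the standard piecewise-`R` CEM43 form with the
  120-min threshold; no tissue-specific Arrhenius variants.

```{r example}
cfg <- preset_config("setA", flow_ml_min = 20, tin_c = 28)
heat_load(cfg, 40)
safe_firing_time(cfg, 40)
```
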