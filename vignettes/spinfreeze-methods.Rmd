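---
title: "spinfreeze: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinfreeze: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinfreeze)
```

## The physical picture

During spin freezing a glass vial rotating at thousands of rpm holds its
aqueous fill as a thin annulus against the inner wall while a cold gas jet
cools the outer wall. Because heat leaves through the curved shell, the
freezing front travels centripetally inward, not upward from a shelf. The
process has four phases: the liquid cools until primary ice nucleation; the
exothermic nucleation flash warms the product back to the equilibrium
freezing temperature `Teq`; crystal growth converts the remaining water at a
slowly falling wall temperature; and once all water is frozen the solid
cools to the final temperature.

`spinfreeze` models the *outer vial wall* temperature. The product
temperature is not a single number — during growth the liquid sits at `Teq`
while the ice layer below it is already colder — but any product-layer
temperature follows from the wall value and the conduction relations, and the
wall is what an infrared camera verifies.

## Model structure

One energy balance drives everything. Heat flow is Newton cooling over the
wetted shell of diameter `D` and heat-exchange height `H`:

$$\dot Q = \pi h D H (T_{v,o} - T_{gas}), \qquad h = h_a \dot V + h_b .$$

The affine map from volumetric flow rate to heat transfer coefficient is an
empirical calibration; it absorbs the rig geometry, rotation speed, nozzle
distance and gas properties, and is only trusted over the calibrated flow
range.

Time stepping is explicit forward Euler with the heat flow evaluated at the
previous step, `T(i) = T(i-1) - Q(i-1)\,dt/C`, exactly as the scheme is
usually written for logger-rate steps (`dt = 0.5` s by default, matching the
reference logger). Stability is unproblematic: the step contraction factor
`pi h D H dt / C` stays below 0.02 for all physical configurations here, and a
step-size-robustness test checks that halving `dt` moves phase-aligned
profiles by less than 0.1 K.

Radial conduction uses the hollow-cylinder (shell) resistance
`ln(r_{out}/r_{in}) / (2\pi k H)` — across the glass during every phase, and
across the growing ice annulus during crystal growth, where the liquid side is
pinned at `Teq` and the ice thickness follows from the booked ice mass through
the annulus geometry.

### Nucleation

Nucleation is a stochastic event and is an *input*: the simulation triggers it
when the inner wall reaches the configured `nucleation_temperature`. At high
flux the liquid layer supports a radial gradient, so only the annulus outside

$$r_{sc} = r_{v,i}\, e^{-2\pi k_{ice} H (T_{eq}-T_{v,i})/\dot Q}$$

is subcooled at the trigger; the sensible heat released in warming the system
back to `Teq` freezes the mass fraction
`chi_nuc = C_w (Teq - Tnuc) / (dHf V_nucl rho_w)` of that zone instantly.
During growth the front first sweeps the pre-nucleated zone, where each unit
of removed latent heat books `(1 + chi_nuc)` units of ice.

Two guards that the bare formulas need in a spinning vial:

* the fill is a hollow annulus, so `r_sc` is clamped below by the liquid core
  radius and the nucleated volume is capped at the liquid volume — without the
  clamp the exponential formula can claim more liquid than exists;
* `chi_nuc >= 1` (deep supercooling into a tiny nucleated zone) aborts with a
  diagnostic instead of silently truncating.

### Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| `wall_height` (H) | 0.060 | m | liquid-covered (heat-exchange) height. The symbol is sometimes read as the full vial height; we interpret it as the wetted height and configure it explicitly, since a 3 mL fill does not wet a whole 10 mL vial in general. |
| `nucleation_temperature` | 272.15 | K | inner-wall trigger, mid-range of the −2…0 °C inner-wall nucleation temperatures observed on the reference rig. The trigger can be switched to the outer wall for replaying outer-wall-reported data. |
| `dt` | 0.5 | s | the rig logger interval; also the published scheme's step. |
| `final_temperature` | 223.15 | K | end of solid cooling (−50 °C). |
| calibration `(ha, hb)` | 71.11e3, 32.05 | J/(m⁵K), W/(m²K) | the reference rig's regression (RMSE 4.3058, RMSECV 5.6293, 8 runs), shipped as `default_calibration()`. |
| vial constants | see `vial_system()` | SI | a documented profile for a 10 mL type-I tubular vial plus handbook water/ice constants; nominal values are not critical (the model is exercised with explicit parameters), they make fixtures runnable. |

Temperatures are kelvin everywhere internally; files and the CLI speak °C and
L/min, converted only at the I/O boundary.

## Calibration of h(V̇)

`calibrate_heat_transfer()` reproduces the constant-flow calibration
procedure: locate the crystal-growth window on the measured wall temperature;
take the mean heat flow as `Qbar = m_water dHf / t_cryst` (all latent heat
removed at a constant mean rate — the slight sensible cooling of the ice
during growth is neglected); form per-timepoint coefficients
`h = Qbar / (pi D H (T_wall - T_gas))` from lag-corrected measurements; average
them per run; and regress the per-run means on flow by ordinary least squares,
with RMSE over runs and RMSECV by leave-one-out.

**Window detection.** The published description ("a marked drop" ends the
plateau) needs an operational detector. Raw one-step thresholds fail at
realistic noise (at σ = 2 K a one-step difference has σ = 2.8 K — any fixed
1 K rise threshold fires immediately), so the detector estimates the local
slope by a rolling 21-sample linear fit, finds the first *persistent*
crossing from a cooling slope to a plateau slope (±0.4 K/s) and the first
persistent return, and refines both instants jointly on the raw series with a
three-piece-linear changepoint fit (descent | plateau | drop; sharing the
plateau between both breakpoints lowers endpoint variance). A narrow
second refinement pass runs only when the fit residual shows the trace is
effectively noiseless, where it recovers the exact grid points. On
simulator-generated noiseless traces the detector is exact at all eight
calibration flows; at σ = 0.5 K roughly nine of ten endpoints land within
three samples of truth (the information-theoretic localization limit for a
slope kink under this noise is of the same order).

**Lag correction.** A thermocouple reading a changing gas temperature lags by
`-Nt dT/dt`. The default derivative is a second-order finite difference; the
calibration pipeline uses a 5-sample local-linear derivative instead, because
at `Nt = 2 s`, `dt = 0.5 s` the two-point stencil multiplies channel noise by
2.8 into the corrected series and the resulting `1/ΔT` convexity bias inflates
recovered coefficients by about a percent.

**A structural bias worth knowing about.** The procedure books the *full*
latent heat against the detected window, but the fraction frozen in the
nucleation flash consumed sensible heat already inside the system, not gas
cooling. Self-recovery studies on simulator-generated fixtures therefore
carry an inherent +4–6% level bias at 1 K supercooling (exactly zero as the
supercooling goes to zero — the package's oracle-equivalence test). Real
calibrations carry the same structural bias. The bias varies slightly and
deterministically with flow because the nucleation trigger quantizes to the
time grid.

## Uncertainty propagation

Seven inputs are uncertain: the heat transfer coefficient (half-width = the
calibration RMSE, applied as an additive offset to the calibration
prediction — not as slope/intercept perturbations, since the RMSE measures the
uncertainty of `h` itself), vial diameter, vial mass, fill mass, flow rate,
`Teq` and `Tgas` (the last two at ±2 K, the accuracies of the infrared camera
and the thermocouple). Ranges are uniform on nominal ± half-width by default
(a normal option with σ = half-width/2 exists); the input distribution family
is a modelling choice, not a measured fact.

Sampling uses a Sobol low-discrepancy sequence (hand-rolled Gray-code
construction with Joe–Kuo direction numbers, since no installed package
provides one; it is verified bit-exact against an independent quasi-random
oracle in the tests). An optional seeded random digital shift (XOR)
decorrelates replicate designs while preserving equidistribution; the seed is
recorded in all output metadata. The initial all-zero point is skipped.

One simulation runs per sample; profiles are aligned on the nominal run's
grid, with early-finishing runs padded at their final temperature (the
interval must be defined over the nominal run's full duration; truncation
would shorten it). The 95% prediction interval takes the
`ceiling(0.025 n)`-th and `floor(0.975 n)`-th order statistics per timepoint
— samples 250 and 9750 at n = 10 000. Failed sampled runs are excluded and
counted; more than 1% failures aborts.

One sampling subtlety: perturbing `Teq` with the nucleation trigger held at a
fixed absolute temperature can make the trigger *warmer* than the sampled
`Teq`, an unphysical configuration. Sampled runs therefore preserve the
configured supercooling degree (`Tnuc = Teq_sampled − 1 K` by default), which
also keeps the nucleation fraction stable across samples.

## Global sensitivity analysis

Total-order indices follow the Saltelli sampling design (`A`, `B`, and `AB_i`
with column `i` of `A` replaced from `B`) with the Jansen estimator
`ST_i = mean((f_A - f_{AB_i})^2) / (2 Var f)`, the variant recommended for
total-order effects; small negative estimates are clipped to zero before
normalized percentage shares are formed (raw values are retained in the
report). The model output is the outer-wall temperature at one representative
timepoint per phase — by default the nominal run's phase midpoints; a sampled
run whose phase differs at that instant is evaluated at its own phase
midpoint, so every output is phase-consistent. Base N defaults to 1024 for
desk-scale analysis and tests (Monte-Carlo error comfortably below the
percentage-point granularity of the shares), 8192 for reports.

**The vial-mass uncertainty default.** In liquid cooling
`T = T_{gas} + (T_0-T_{gas})e^{-hADt/C}`, the sensitivities to `ln h` and
`ln C` are equal in magnitude at every timepoint, so the variance-share ratio
of vial mass to `h` is `(c_{p,vial} u_{m}/C_w)^2 / (u_h/h)^2` regardless of
where the output is evaluated. A vial-mass half-width of 0.5 g would
therefore force the vial mass above 5% of the output variance at high flows
for any plausible 10 mL vial — incompatible with the observed dominance of
{h, Tgas, Teq} (≥96% combined) and the negligible role of geometry and mass
tolerances on the reference rig. The shipped default uses 0.05 g (a weighing
tolerance); the larger value is one config edit away, and the acceptance
tests document what happens under the shipped budget.

## Open-loop inversion

`flow_schedule()` computes the flow schedule imposing a target profile
(liquid cooling at `Cr`, growth of duration `t_cryst`, solid cooling at
`Cr`): the required per-phase heat flows are `Q = Cr C_w`, the growth-phase
mean flow, and `Q = Cr C_i`; the target trajectory is generated by running
the *same* phase machine under these prescribed flows; then
`h = Q/(\pi D H (T_{target}-T_{gas}))` and `V̇ = (h-h_b)/h_a` per timestep.
Because inversion and simulator share every equation, a forward replay of the
unclamped schedule reproduces the target to round-off — the package's
round-trip test asserts the liquid and solid cooling rates to 1% and the
crystallization duration to one step.

Two design choices make the round trip exact rather than approximate:

* the growth-phase heat flow defaults to the *scheme's effective latent
  energy* divided by the target duration
  (`duration_mode = "effective"`). The nominal balance
  `Qbar = m_water dHf / t_cryst` ignores the mass frozen in the nucleation
  flash and finishes a few percent early at realistic supercooling;
  `"nominal"` is available for exactly that behaviour.
* the schedule row at the nucleation event carries the coefficient targeted
  at the *pre-event* wall state, because the phase machine evaluates the
  event (trigger, nucleated-zone geometry, post-event recompute) with the
  flux at the trigger.

Bounded operation (`bounds = c(lo, hi)`) clamps and flags; a required
coefficient at or below the calibration intercept is then an error (negative
flow). The *unclamped* schedule instead represents sub-intercept requirements
as negative flows flagged `extrapolated` — mathematically consistent and
required for round-trip verification under a constant cold gas, where the
entire liquid phase of a gentle profile needs less cooling than the zero-flow
intercept provides. Physically realizable operation under such a profile
needs gas that starts warm, which is exactly what the rig's warm-up transient
provides; an exponential warm-up gas model is available in the fixture
generator and as a time-varying gas input.

## The synthetic-data generator

`generate_fixtures()` emulates the two experiment families: constant-flow
calibration runs (default: the rig's eight flows, 20–69 L/min) and
imposed-profile runs (default: 20 °C/min, 150 s, 20 °C/min). Traces are
simulator outputs plus seeded, independent, additive Gaussian noise per
channel — σ = 2 K on wall and gas temperatures, 1% relative on flow,
mirroring the instrument accuracies. Identical seeds give byte-identical
fixtures; a truth file echoes the generating coefficients and phase times.

What the generator does *not* emulate: flow-dependent gas temperatures (the
real rig's gas is warmer at low flows — the constant −60 °C default sits
mid-range of its −40…−90 °C span, and an exponential warm-up option exists),
autocorrelated sensor noise, IR-camera radiometric effects, vial-to-vial
variability of nucleation, and drift. A green recovery test therefore
establishes that the *procedures* invert the *model* faithfully under
idealized noise — not that the model describes any particular rig; the
packaged verification table of rig measurements is checked only as ordering
properties (higher flow → shorter crystallization, faster cooling) for the
same reason.

## Numerical choices and degenerate inputs

* Euler with previous-step flux, per the printed scheme; energy bookkeeping is
  therefore a left Riemann sum, and the conservation tests assert the
  scheme's own discrete identity (exactly, to 1e-9 relative) rather than a
  trapezoid approximation of it.
* Phase-change times quantize to the grid; step-size robustness is asserted
  phase-aligned, and on fitted rates for the solid phase, whose entry state
  inherits an O(dt) offset decaying with its own time constant.
* The growth step caps the ice mass at the fill mass; the capping step books
  only the remaining mass.
* Ice-layer conduction diverges as the thickness approaches the inner radius;
  the geometry cannot reach it (the annulus empties first), and the
  closed-form step rejects out-of-range thickness explicitly.
* `simulate_freezing()` refuses configurations whose gas never falls below
  the nucleation trigger (the wall asymptotes to the gas temperature, naming
  the limiting gas temperature), and aborts on `max_steps` otherwise.
* A trace grid may wobble by up to 2% before parsing fails; within tolerance
  it is accepted with a warning.

## Known limitations

* Material constants are scalars; no temperature dependence.
* Pure-water fill: no solute depression of `Teq`, no glass-transition logic.
* One-dimensional radial energy balance; no axial fields, no radiation.
* `h` is calibrated, not predicted; the calibration is only valid for the rig
  conditions under which it was measured.
* Nucleation is an input; the package neither predicts nor controls it.
* The self-calibration bias discussed above is inherent to the published
  procedure and shows up in any recovery study at realistic supercooling.
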