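---
title: "A hybrid circuit/agent-based model of pressure ulcer formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid circuit/agent-based model of pressure ulcer formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulcersim)
```

`ulcersim` couples a lumped-parameter circuit model of skin blood flow to a
stochastic grid model of epithelial damage, inflammation and healing, and
uses the coupled system to ask how long a cyclic external pressure can be
left in place before skin tissue is predicted to ulcerate — and how that
tolerance differs between able-bodied subjects and subjects with chronic
spinal cord injury (SCI), whose skin vasculature is stiffer and more
resistive.

## The circuit model of reactive hyperemia

Skin perfusion is represented by a two-compartment RC circuit: an input
pressure source `V(t)` (mmHg) feeds current through an arterial resistance
`R1` into a compliant compartment (`C1`, shunted by a large `R4`), which
drains through `R2` into a second compartment (`C2`, drained by `R3`). The
current `I2` through `R2` is the model's skin blood flow, the quantity a
laser-Doppler flowmeter reports (in arbitrary perfusion units). Only two
state currents are needed; the other four branch currents follow
algebraically from Kirchhoff's laws:

```
I4 = (V - R1 I1)/R4            I3 = (V - R1 I1 - R2 I2)/R3
I5 = I1 - I2 - I4              I6 = I2 - I3
dI1/dt = (dV/dt - I5/C1)/R1    dI2/dt = (I5/C1 - I6/C2)/R2
```

Under a constant input the system is linear with a stable 2x2 coefficient
matrix, so the resting flow has the closed form

```
I2,rest = V0 / (R2 + R3 + R1 (1 + (R2 + R3)/R4))
```

and the post-occlusion response is the bi-exponential
`I2(t) = I2,rest + a e^{p1 t} + b e^{p2 t}` with `p1, p2` the (negative)
eigenvalues.

**The release jump.** One modeling decision deserves emphasis. The state
variables `I1, I2` are currents, but the physically continuous quantities
are the two compartment voltages. When the input pressure steps by `dV`
(occlusion release, or a pressure cycle edge), the current through `R1`
jumps instantaneously by `dV/R1`, while `I2` stays continuous.
`step_response()` therefore solves the post-release problem with
`I1(0+) = V0/R1`, `I2(0+) = 0` (drained compartments, pressure restored).
This convention is what produces the reactive-hyperemia overshoot: with the
fitted control circuit the response peaks at 2.36x resting flow about 21 s
after release, while the stiff, high-resistance SCI circuit peaks at only
1.22x. Had we instead imposed `I1(0+) = 0`, both responses would rise
monotonically with no overshoot at all — contradicting the measured
post-occlusion traces the parameters were fitted to. The numeric
integrator realizes the same physics by feeding the forward difference
`(V(t+dt) - V(t))/dt` into the `dV` term, which converges to the `dV/R1`
jump at first order in `dt` (and is exercised as such in the tests).

`integrate_flow()` is a fixed-step classical RK4 scheme; on constant
pressure segments it agrees with the closed form to better than `1e-6`
relative over four minutes and is fourth-order accurate. Repeated
eigenvalues (a measure-zero case never approached by the fitted regimes)
are rejected with an error rather than handled with the `t e^{pt}` branch.

## Calibration of the circuit

`fit_group()` reproduces the group-fitting pipeline:

1. zero-phase (forward-backward) Butterworth low-pass filtering, default
   4th order with a 0.2 Hz cutoff — low enough to suppress cardiac and
   myogenic flowmotion, high enough to preserve the minutes-scale
   hyperemia shape; the record is mean-removed and reflection-padded so
   the DC level is preserved exactly;
2. cropping to the first 240 s after release (the peak and its decay carry
   all the identifiable information; later data add none);
3. averaging across the group's subjects on a common 4 Hz grid (linear
   interpolation; 4 Hz is far above the post-filter bandwidth);
4. minimizing the plain sum of squared residuals between the averaged
   trace and the closed-form `I2(t)` by multistart Nelder-Mead. Starts
   are drawn uniformly inside the bound box from a seeded generator
   (default 1000 starts; the tests use 20-30, which suffice on synthetic
   data); bounds (0.01-200, with the shunt floor `R4 >= 190`) are
   enforced through a logistic reparameterization so every evaluated
   point is feasible. Convergence tolerance is `1e-8` relative with at
   most 2000 simplex iterations per start.

The input pressure is not fitted: 85 mmHg for the control group, 75 mmHg
for SCI. The SCI fit additionally caps the compliance upper bounds at the
control best-fit values (`sci_bounds_from_control()`), encoding the
independently observed stiffening of post-SCI vessels.

A caution on identifiability: the observable is a bi-exponential curve
with four effective degrees of freedom, fitted over six parameters. Raw
parameter recovery is therefore not meaningful and not claimed; recovery
is asserted (and tested) on identifiable derived quantities — the resting
flow and the time-to-peak — plus the curve itself.

## The tissue model

The grid (default 40x40 cells, toroidal) carries one epithelial agent per
cell, blood vessels every 4th cell, wandering macrophages, and three
diffusible fields — oxygen, TNF-a (aggregate pro-inflammatory signal) and
TGF-b (aggregate pro-healing signal). Fields update synchronously: each
cell keeps `1 - diffusion_frac` of its content, spreads the rest equally
over its 8 Moore neighbors, and then everything evaporates by a fixed
fraction. One tick integrates `dt_ode = 1` s of circuit time; a tick is
the model's unit of time and the pressure interval `tp` is counted in
ticks.

Per tick, in fixed order: vessels (advance the shared circuit state one
RK4 step, release oxygen, spawn macrophages, die if their 8 neighbors are
dead), macrophages (chemotax toward TNF-a, secrete TNF-a and TGF-b, age
out), epithelium (pressure damage, TNF-a damage, TNF-a secretion when
damaged, oxygen-dependent healing, death at zero health — irreversible),
then the fields. The square-wave schedule applies pressure for `tp` ticks
(input pressure at `v_min = 40` mmHg), releases it for `tp` ticks
(`v_max = V0`), and repeats, pressure-on first.

Three rule refinements, each with a physiological reading, turned out to
be structurally necessary and are worth recording:

* **Damage lag** (`t_damage_lag`, default 41 ticks). Pressure damage
  begins only after the pressure has been applied continuously for the
  lag. Tissue tolerates brief ischemic episodes — this is the entire
  premise of patient turning schedules. Mechanically, the lag is also
  what makes harm monotone in `tp`: without it, rapid cycling (where
  perfusion hovers in the mid-range and hyperemic repair is never
  triggered) is spuriously the most lethal regime.
* **Perfusion gating and saturation of oxygen delivery**
  (`theta_perfusion = 0.75`, `sat_perfusion = 3`). A vessel releases
  usable oxygen in proportion to the part of its normalized flow above a
  derecruitment threshold, saturating at a finite multiple of the resting
  release. Flow is normalized by the group's own resting flow because
  Doppler flux — and hence the fitted current scale — is in arbitrary
  per-group units; raw currents are not comparable across groups. The
  gate and ceiling concentrate oxygen delivery into the post-release
  hyperemic burst, which is precisely the physiological role of reactive
  hyperemia: repaying the oxygen debt of the occlusion. Since the control
  circuit's burst (2.36x rest) clears the gate widely and the SCI burst
  (1.22x) barely does, the fitted hemodynamics — not any group-specific
  tissue parameter — carry the group difference.
* **Chemotaxis sensitivity floor** (`theta_chemotaxis = 0.5`).
  Macrophages follow the steepest TNF-a gradient only above a detectable
  level and random-walk otherwise. Without the floor they climb the
  gradients of their own secretion trails and self-aggregate in resting
  tissue, which makes the TGF-b field patchy and resting tissue
  spuriously fragile at its worst-supplied cells.

Worlds initialize at homeostasis: fields pre-equilibrated by a burn-in
under constant pressure, the macrophage population at its resting size
with ages spread over the lifespan. Starting from an empty grid would
impose an artifactual first-cycle insult (no TGF-b, hence no healing,
for the first macrophage lifespan).

All vessels see the same input pressure and obey the same linear ODE, so
their flow states are identical; the implementation stores the state once
per world and exposes it per vessel in exports.

## How the minimal damaging interval arises

Two mechanisms bound tissue survival, and their interplay is what the
calibration exploits:

* **Depth limit.** During one on-phase a cell loses
  `kd_pressure x (tp - t_damage_lag)` health (healing is negligible
  under pressure because gated oxygen delivery is zero for both groups).
  When that single-phase loss reaches the full health scale, the first
  sustained application kills outright, independent of recovery. With the
  shipped constants this bound sits at `41 + 1/0.006 ≈ 208` ticks.
* **Repair budget.** Between phases, recovery is powered by the hyperemic
  oxygen burst, a per-cycle budget set by the circuit's overshoot. If the
  budget cannot repay the on-phase loss, health ratchets down over
  successive cycles until the TNF-a loop (damaged cells secrete,
  macrophages amplify, above-threshold TNF-a damages) finishes the job.

For the control circuit the burst is large, the repair budget covers every
sub-lethal interval, and the threshold is the depth limit (~208 ticks,
nearly deterministic across seeds). For the SCI circuit the blunted burst
fails much earlier and the threshold is the repair-budget crossing
(~105 ticks). The tissue constants were pinned once so that the
control threshold lands in the published 205-210 band; the SCI runs reuse
them unchanged, and the 105-110 band emerges from the fitted SCI
hemodynamics alone. The rate constants of the inflammation loop
(`k_tnf_secrete`, `kt_tnf`, `theta_tnf`, macrophage rates) are set so the
loop is sub-critical at rest (resting TNF-a stays several-fold below
threshold) and acts as an executor of sustained damage rather than a
threshold-setter.

## The synthetic data generator

`synth_trace()` emulates a post-occlusion Doppler recording: baseline at
resting flow, 20 minutes of occlusion at a biological-zero floor (5% of
rest — occluded Doppler signals never read exactly zero), then the
closed-form release response; on top, three flowmotion sinusoids (0.01,
0.1, 1 Hz, small amplitudes, seeded random phases) standing in for the
endothelial/myogenic/cardiac oscillation bands, and additive Gaussian
noise (10% of rest), clipped at zero. Default sampling is 32 Hz.
`synth_cohort()` draws per-subject circuit parameters log-normally
(mean-preserving, 15% coefficient of variation) around the group circuit,
with SCI compliances capped at the control values.

The generator's purpose is testability: its noiseless limit is exactly
the model being fitted, so it provides ground truth for the calibration
pipeline. What it does *not* emulate — Doppler speckle statistics,
movement artifacts, slow baseline drift, between-session gain changes —
bounds what passing tests say about field data: they validate the
pipeline's correctness, not its robustness to every artifact of real
recordings.

## Reproducibility and problem sizes

Every stochastic component draws from an explicit seed: synthetic traces
and cohorts, multistart draws, and each simulated world, which carries its
own generator state so trajectories are bit-reproducible regardless of
surrounding RNG use. The shipped analyses use a 40x40 grid with 100
vessels, 2000-tick runs, 5 replicate seeds for threshold sweeps (ascending
coarse scan, then bisection to one tick, justified by the monotone-harm
property), and 20-30 multistart points for synthetic-data fits; these
sizes reproduce the published quantities in minutes on one core.

## Known limitations

* The tissue rate constants are not data-calibrated individually; only
  their combination is pinned by the control threshold band. Different
  constant sets could reproduce the same bands.
* The circuit is linear; genuinely nonlinear vasodynamics (myogenic
  autoregulation, flowmotion) enter only as noise in the generator.
* Shear force, reperfusion injury, deeper tissue layers and muscle are
  out of scope, as is any statistical comparison between fitted groups.
* The repeated-eigenvalue circuit response is rejected rather than
  solved; it is never approached by physiological parameter sets.
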