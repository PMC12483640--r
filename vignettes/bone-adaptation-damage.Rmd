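---
title: "Coupled bone adaptation and microdamage dynamics in racehorse subchondral bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled bone adaptation and microdamage dynamics in racehorse subchondral bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equibone)
```

## The model

`equibone` simulates a pocket of subchondral bone in the lateral condyle of
the equine third metacarpal bone (MCIII) under cyclic training loads. Two
state variables evolve in time: the bone volume fraction $f_{BM} \in (0,1]$
(the fraction of tissue volume occupied by mineralized matrix) and the
microdamage life fraction $D^* \in [0,1]$, with $D^* = 1$ denoting failure
of the bone pocket (clinically palmar osteochondral disease rather than
gross fracture).

**Adaptation.** Remodelling acts on the bone–marrow interface. The specific
surface available follows a square-root law,
$$S_v = a\sqrt{1-f_{BM}}\,\bigl[1 - b(1-f_{BM})\bigr],$$
which vanishes at $f_{BM} = 1$: fully dense bone has no internal surface to
remodel. The mass balance is
$$\frac{df_{BM}}{dt} = (A_{OBL} - A_{OCL})\,\alpha\,S_v,$$
where $A_{OBL}$ and $A_{OCL}$ are osteoblast formation and osteoclast
resorption activities (bone thickness per surface per day, mm/day) and
$\alpha$ is the fraction of surface available for remodelling.

**Mechanoregulation.** Osteocytes sense the strain energy density
$\psi = \sigma^2 / 2E$ of uniaxial compression at joint contact pressure
$\sigma$, with tissue stiffness
$E = E_0\,\dot\varepsilon^{\gamma_E} f_{BM}^3$ (stiffness rises with
mineral content and weakly with strain rate). Formation follows an
increasing Hill function of $\psi$ and resorption a decreasing one:
$$A_{OBL} = A_{OBL}^{min} + (A_{OBL}^{max} - A_{OBL}^{min})
  \frac{\psi^{\gamma_B}}{\delta_B^{\gamma_B} + \psi^{\gamma_B}}, \qquad
A_{OCL} = A_{OCL}^{min} + (A_{OCL}^{max} - A_{OCL}^{min})
  \frac{\delta_C^{\gamma_C}}{\delta_C^{\gamma_C} + \psi^{\gamma_C}}.$$
The resorption curve is tuned so that bone at rest (30 MPa, $\psi \approx
0.31$ MPa in race-adapted bone) resorbs about four times faster than bone
in full training (90 MPa, $\psi \approx 2.36$ MPa); with $\delta_C = 1$ MPa
and $\gamma_C = 2$ and the pre-calibration activity bounds the exact ratio
is 4.01.

**Damage.** Damage is a fatigue life fraction. The per-cycle damage comes
from a compressive stress–life power law adjusted by stiffness,
$$N_f^*(\sigma) = 10^{-(\sigma - \sigma_0)/\sigma_1}\,\frac{E}{E_{nom}},
\qquad v_D = 1/N_f^*,$$
with $E_{nom} = E_0 \times 0.9^3 \times 0.36^{0.06} = 1714.1$ MPa the
stiffness of the fatigue test specimens. Damage forms at $D_f' = v_D\,
v_n$ ($v_n$ = loading cycles per day) and is repaired by remodelling,
$$D_r' = \bigl[A_{OBL} + (F_s - 1) A_{OCL}\bigr]\,\alpha S_v \frac{D^*}{f_{BM}},$$
where formation dilutes cracks over new bone volume and resorption removes
cracks preferentially when osteoclasts target them; the specificity factor
$F_s = 5$ means resorption co-localizes with cracks five times more often
than chance, and $F_s = 1$ (untargeted) leaves only the dilution term. Then
$dD^*/dt = D_f' - D_r'$. Two exclusions are deliberate: stiffness does not
degrade with accumulated damage (the transient stiffening over fatigue life
is likewise omitted), and formation is not activated by damage — the
formation law is a function of $\psi$ only.

Parameters live in a single `bone_params()` object. The default preset
`"table2-fitted"` carries the calibrated values ($A_{OBL}^{max} = 0.00603$,
$A_{OCL}^{max} = 0.00358$ mm/day, $\sigma_0 = 139.0$ MPa);
`"table2-initial"` carries the pre-calibration literature values (0.0127,
0.011, 134.2). The four-fold resorption tuning above refers to the initial
preset; simulations default to the fitted one.

```{r params}
p <- bone_params()
rate_bundle(0.9, 0, race_loading(), p)[c("psi", "AOBL", "AOCL", "Df")]
```

## Simulation and numerical choices

`simulate_bone()` integrates the two-equation system with `deSolve`'s
stiff-capable `lsodar` (the right-hand side is compiled C), relative
tolerance $10^{-8}$ and absolute $10^{-10}$ — rates span roughly $10^{-4}$
to $10^{-2}$ per day, and the failure event must be sharply located.
Loading schedules are piecewise constant; integration restarts at every
segment boundary so a loading discontinuity never sits inside a solver
step (the test suite verifies that splitting a constant segment changes
nothing). Failure is detected by the solver's root finder on $D^* - 1$,
which terminates the run at the event rather than at a grid point. The
bone volume fraction is clipped at $1 - 10^{-9}$ (the surface law is
undefined above 1) and clipping is recorded; $D^*$ needs no clipping
because integration stops at 1.

Three conventions are fixed here because no published definition exists:

* **Steady state** means $|df_{BM}/dt| < 10^{-7}$ per day sustained for 50
  consecutive days; `steady_state()` reports the first time the rate
  enters and stays in that band. Steady states at the $f_{BM} \to 1$
  boundary (where no interior formation–resorption balance exists, as
  under the 90 MPa racing proxy) are flagged separately, since there the
  surface — and with it all repair — vanishes.
* **Plateau** in `time_to_failure()` means $dD^*/dt < 10^{-3}$ per day
  sustained over 20 days with $D^* < 1$. Under routine training (81.1 MPa)
  the quasi-steady balance $D_f' = D_r'$ settles near $D^* \approx 0.5$
  and the rate drops below this threshold within a year; under the racing
  proxy the rate never falls below $\approx 8\times10^{-3}$ per day, so
  the dichotomy between the two statuses is sharp. A smaller threshold
  would mainly lengthen the simulated horizon: the slow upward creep of
  the quasi-steady damage as the bone densifies is not a biological
  plateau, and the chosen threshold reports the practically stationary
  regime.
* **The rest loading condition** is 30 MPa with zero damage-relevant
  cycles; its strain rate is back-calculated so that $\psi = 0.31$ MPa at
  $f_{BM} = 0.9$, giving $\dot\varepsilon \approx 0.0225$ s$^{-1}$. This
  reconstructs an anchor that is only printed as a strain energy density.

Degenerate mechanoregulation (formation $\equiv$ resorption for every
$\psi$) makes every $f_{BM}$ stationary; `steady_state()` detects this by
probing the rate at three separated volume fractions and warns instead of
pretending convergence.

## Calibration

`fit_calibration()` re-estimates the three calibrated parameters from a
`calibration_dataset()`: cross-sectional bone volume fractions in a
training arm and a rest arm, plus fracture times. The loss is
$$\mathrm{SSE}_{training} + \mathrm{SSE}_{rest}
  + w\,\bigl(t_{fail}^{sim} - \mathrm{median}(t_{fail}^{obs})\bigr)^2,$$
each arm simulated from its stated initial condition and loading. The
median (not the mean) of the fracture times enters, matching how the
observed fracture data were summarized. The weight $w$ defaults to the
value that makes the two blocks comparable at the initial point, so
neither dominates by units alone. Optimization is derivative-free
(Nelder–Mead in a logit transform of the allowed parameter ranges —
gradients through an event-terminated ODE are unreliable), multi-started
from the pre-calibration values plus seeded random points.

The arm conventions are reconstructions from printed anchors, since the
original fitting configuration is unpublished: the training arm starts at
$f_{BM} = 0.85$ under (81.1 MPa, 0.2974 s$^{-1}$, 43.7 cycles/day), the
rest arm at 0.93 under the rest condition, and the high-workload fracture
simulation at $f_{BM} = 0.9$, $D^* = 0$ under (90 MPa, 0.2974 s$^{-1}$,
43.7 cycles/day). All are arguments, not constants. One consequence is
worth stating plainly: under this reconstructed fracture arm, the
calibrated $\sigma_0 = 139.0$ MPa produces failure at 91 days, so matching
a 133-day median pulls $\sigma_0$ to about 140.7 MPa. The reconstruction
preserves the calibration *procedure* and its self-consistency (fitting to
model-generated data recovers the generating parameters to optimizer
tolerance; with observation noise of sd 0.05 at the real sample sizes the
median relative error across seeds stays under about 6%), not the exact
published arm setup.

## Sensitivity analysis

`prcc_analysis()` draws a Latin hypercube (default $n = 1000$) over the
published ranges of all 20 parameters — the loading variables $\sigma$,
$\dot\varepsilon$, $v_n$ are sampled exactly like the intrinsic ones —
plus an inert dummy variable, simulates 70 days (10 weeks) from unadapted
bone ($f_{BM} = 0.7$, $D^* = 0$), and computes partial rank correlation
coefficients by the linear-residual method on ranks (regress the ranks of
each parameter and of the output on the ranks of all other parameters,
correlate the residuals). Runs that fail before 70 days contribute
$D^* = 1$: failed bone is maximal damage, and discarding those rows would
bias the estimates downward for exactly the parameters that cause failure.
The dummy's PRCC magnitude bounds the noise floor.

`sobol_indices()` implements the Saltelli scheme with two base matrices
and both cross-matrix families, $n_{base}(2d+2)$ model runs (22 528 at the
default base of 512), yielding first-order, total, and closed second-order
indices with percentile-bootstrap confidence intervals. Small negative
index estimates are estimator noise and are reported as-is rather than
clipped. The estimators are validated in the test suite against analytic
variance shares of additive and pure-interaction test functions.

## Training programmes

A programme is a list of phases (rest, pre-training, progressive,
race-fit), each with workouts: speed, distance, performed per day or per
week. `speed_load_map()` translates speed into loading; its default
interpolates joint pressure and strain rate linearly between three printed
anchors — rest (~1.7 m/s, 30 MPa), routine training (14.0 m/s, 81.1 MPa,
0.2974 s$^{-1}$) and the racing proxy (16.0 m/s, 90 MPa) — and treats
stride length as proportional to speed through the one derivable anchor
(6.103 m at 14.0 m/s, which makes 8000 m per 30 days at 14.0 m/s produce
exactly the surveyed 43.7 cycles/day). Every entry is overridable;
speeds outside the anchor range raise an error rather than extrapolate.

Two within-day conventions matter. The ODE needs one loading condition per
day, so a day's segment takes the *highest-speed* workout's pressure and
strain rate while summing cycles across workouts; damage *attribution*
(`attribute_damage()`) instead bills every workout at its own pressure,
using the stiffness trace of the simulation, because per-cycle damage is
additive. To keep these two views consistent, weekly (fast-work) workouts
*replace* the routine daily work on the days they run: if canter strides
stacked onto gallop days they would be billed at gallop pressure in the
ODE, inflating damage roughly five-fold and failing any realistic
programme mid-preparation. Alternating fast-work and routine days is also
how campaigns are actually ridden.

The shipped demonstration programme (`default_programme()`,
`inst/extdata/default_programme.yaml`) is a labelled reconstruction of an
Australian-style campaign — 44 days rest, 28 pre-training (trot), 61
progressive (daily 2 km canter, weekly slow/fast gallop), 61 race-fit
(daily canter, weekly fast gallop and race-speed work), repeated four
times over 776 days. Its fast-work volumes (500 m/week per fast-speed
bin) were chosen once so the campaign exhibits the expected qualitative
behaviour under the default linear speed–load map: damage climbs through
progressive and race-fit training to $D^* \approx 0.8$, repairs only
partially over rest, and the bone does not fail. Note that the linear map
assigns canter (7.5 m/s) about 54 MPa, which supports a steady
$f_{BM} \approx 0.79$; a convex map (plausible, since impact loads rise
steeply at low speeds) would support the higher trained volume fractions
seen in adapted racehorses. Published campaign-level distance totals
depend on unpublished programme tables and are deliberately not
reproduced; the attribution machinery, not the specific programme, is the
deliverable.

## Synthetic data

`synthetic_spec()` and its generators emulate the *structure* of the
calibration data so the whole pipeline is testable without any download:
213 training limbs and 24 resting limbs, each contributing one
cross-sectional observation (a uniformly drawn day in a window, the model
trajectory at that day plus truncated-Gaussian noise of sd 0.05 — chosen
to reflect the marked spread of cross-sectional bone measurements), and
16 fracture times drawn log-normally and rescaled so their median equals
the model's noise-free failure time. The observation-day windows (0–150
days training, 0–120 rest) are spec fields, not facts about the original
data. What passing tests on these data show is that the pipeline is
self-consistent — data generated by the model are recovered by the
calibration — not that the model fits any particular real population;
horse-level covariates (age, sex, surface), per-horse parameters and
longitudinal correlation are intentionally absent.

## Problem sizes

The defaults used throughout the scripts and tests: PRCC at $n = 1000$
samples; Sobol at base 512 with second-order sampling (22 528 runs);
calibration with 2–5 multi-starts; recovery studies over 10 seeds;
solver-oracle comparisons against fixed-step Euler at $10^{-3}$ day over
30-day horizons. A full run of the analysis scripts takes a few minutes on
one core; the compiled right-hand side makes a 70-day simulation cost well
under a millisecond.

## Known limitations

The model is lumped: joint stress, damage and repair are treated as
homogeneous over the condyle, while in reality they are focal. Stiffness
loss near failure, biochemical signalling delays, damage-activated
remodelling and age-varying training are all outside the model's scope.
The speed–load map and the calibration arm conventions are reconstructions
from printed anchors; both are configuration, and conclusions that depend
on them (absolute damage magnitudes per programme, the exact $\sigma_0$
matching a given fracture median) should be read as conditional on that
configuration.
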