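---
title: "A negative-feedback model of GPCR-driven calcium pulses in the AWA neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A negative-feedback model of GPCR-driven calcium pulses in the AWA neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awapulse)
```

## The circuit

The *C. elegans* AWA neuron senses diacetyl through the GPCR ODR-10 and
responds to smooth, rising odor gradients with a train of discrete calcium
pulses whose rate and amplitude track the gradient's first derivative —
and with a single, fully adapting pulse when the odor arrives as a step.
`awapulse` implements a four-variable circuit that captures this coding
scheme with one lumped inhibitory feedback:

$$R_a = \left(1 + e^{-k_1 \log(L/L_0) + k_2 I}\right)^{-1}$$
$$\frac{dS}{dt} = k_3 (R_a - R_t)\, S$$
$$\frac{dC}{dt} = k_4 S - \frac{1}{\tau_c}(C - C_0)$$
$$\frac{dI}{dt} = k_5 (C - C_0) R_a + k_6 R_a - \frac{1}{\tau_I}(1 - R_a) I$$

$R_a$ is the fraction of active receptors: logarithmic in the ligand
concentration $L$ (Weber–Fechner front end, natural log) and shifted
linearly by the lumped inhibition $I$ that stands in for GRK/PKA/PKC/
arrestin-type regulation.  $S$ is a self-amplifying channel switch (TRPV
plus voltage-gated calcium channels collapsed into one variable): it grows
exponentially once $R_a$ crosses the threshold $R_t$ and collapses when
$R_a$ falls back below it.  Calcium $C$ follows the open switch with
first-order removal to its baseline $C_0$.  Inhibition $I$ integrates two
production pathways — one proportional to the calcium excess
(calcineurin/TAX-6-like, rate $k_5$) and one calcium-independent (rate
$k_6$) — and is removed in proportion to the *inactive* receptor fraction.
Feeding the output $C$ back into inhibition of the input stage is an
integral feedback, which guarantees exact adaptation: after a step the
calcium returns to $C_0$ even though the stimulus stays on.  The tax-6
mutant is the same circuit with $k_5 = 0$ (`make_mutant()`).

Because $R_a$ is logarithmic in $L$, the inhibition accumulated by each
pulse raises the ligand level needed for the next one multiplicatively.
The closed form is exposed as `adaptive_threshold()`: the circuit is
equivalent to a threshold model whose firing level grows exponentially with
the accumulated inhibition.  Under a linear ramp this predicts interpulse
intervals that grow geometrically with pulse index and scale inversely with
the ramp slope; under a sigmoidal gradient, pulses concentrate before the
inflection point.

## Default parameters and how they were chosen

The quantitative constants behind the published simulations are not
available in the main text, so the package ships its own calibrated set
(`model_params()`), fixed once by the recorded procedure in
`inst/scripts/calibrate_defaults.R` and not revisited:

| constant | default | units | role |
|---|---|---|---|
| `k1` | 1 | — | receptor log-sensitivity gain |
| `k2` | 10 | 1/I | inhibition coupling |
| `k3` | 200 | 1/s | switch self-amplification |
| `k4` | 4.5 | conc/s | calcium influx per open switch |
| `k5` | 0.04 | 1/(conc·s) | calcium-dependent inhibition (TAX-6) |
| `k6` | 9e-4 | I/s | calcium-independent inhibition |
| `L0` | 1.2e-4 | mM | reference ligand level (assay buffer background) |
| `Rt` | 0.5 | — | switch threshold on $R_a$ |
| `tau_c` | 1 | s | calcium removal time |
| `tau_I` | 1550 | s | inhibition removal time |
| `C0` | 0.1 | conc | baseline calcium |
| `S_floor` | 1e-8 | — | switch floor (see below) |
| `L_min` | 1.2e-4 | mM | ligand floor before the log |

Three closed-form margins organize the calibration; they are worth knowing
when you change constants:

* **Inhibition capacity** $A = k_2 k_6 \tau_I$.  At steady state under a
  constant stimulus, $\mathrm{logit}(R_a^\ast) + A\,R_a^\ast/(1-R_a^\ast)
  = k_1\log(L/L_0)$.  Exact single-pulse adaptation requires
  $R_a^\ast < R_t$, i.e. (with $R_t = 0.5$) $A > k_1\log(L/L_0)$ at the
  largest concentration you intend to test.  The default $A = 13.95$
  covers $10^2\times$ the 1.15 mM assay level.
* **Inhibition drift** $k_2 k_6 R_a$.  The calcium-independent pathway
  slowly raises the adaptive threshold even between pulses; a gradient
  whose logarithmic slope $d\log L/dt$ falls below this drift never fires.
  This bounds $k_2 k_6$ from above if slow ramps are to be coded at all.
* **Refiring margin** $\mathrm{logit}(R_t) - \mathrm{logit}(R_a^\ast)$,
  the amount of inhibition recovery (in $k_2 I$ units) needed before a
  second stimulus elicits a response again.  Habituation probes after a
  2-minute off-interval respond only if
  $\tau_I$ is small enough for that much recovery — this caps $\tau_I$
  from above while the capacity bound pushes $k_2 k_6 \tau_I$ up.

Fast, stereotyped pulses (`k3` large, `k5` large, `tau_c` short) decouple
pulse shape from stimulus drive; that is what makes the gradient pulse
count comfortable (about 10 under the standard gradient), keeps the step
pulse well under the 60 s criterion, and restores the idealized inverse
scaling of ramp intervals with slope (measured ratio 1.97 against the
ideal 2 when the slope is halved).  The cost is a calcium decay
(`tau_c` = 1 s) faster than fluorescence decays measured with GCaMP; the
model targets circuit logic, not indicator kinetics.

Two guards are not part of the biology.  `S_floor` keeps the
multiplicative switch from absorbing at zero so pulses can re-initiate; it
must also keep the resting leak $k_4 \tau_c S_{floor}$ below $10^{-6}$
relative to $C_0$ so the equilibrated state is indistinguishable from
baseline, which forces the small value 1e-8.  `L_min` clamps the ligand
before the logarithm and equals the low odor concentration deliberately
kept in the assay buffer.

## Numerical choices

Integration uses `deSolve::lsoda` with a compiled C right-hand side, a
maximum internal step of 0.5 s (so switch transitions are never stepped
over), relative tolerance 1e-6, absolute tolerance 1e-9, and dense output
on a uniform 0.1 s grid.  The ligand protocol enters as a linearly
interpolated forcing table; step edges are bracketed with points 1e-6 s on
either side so they stay sharp.  State bounds ($S \in [S_{floor}, 1]$,
$C, I \ge 0$) are enforced inside the derivative: outward derivatives
taper linearly to zero across a narrow boundary layer at each clamp.  A
discontinuous projection (zeroing exactly at the bound) stalls the
adaptive integrator with step-size chattering when the switch saturates;
the continuous taper removes that failure mode without touching the
interior dynamics.  `simulate_fixed_step()` provides a fixed-step
fourth-order Runge–Kutta reference used in the tests: the adaptive
solution agrees with the 1 ms reference to well under 1% of the pulse
amplitude.

Pre-equilibration (`equilibrate()`) starts from the closed-form resting
state (switch at floor, calcium at baseline, inhibition from root-finding
on the production/removal balance) and verifies it by simulation until all
derivatives fall below tolerance.

## Pulse detection

Two detector variants mirror how recordings and simulations are scored
(`pulse_criteria()`).  The *experimental* variant accepts a local maximum
whose amplitude exceeds 20% of the trace's maximal fold change and which
decays by at least 70% of its amplitude on both sides before the trace
exceeds the peak again; when nothing qualifies the count falls back to 1
(scoring animals with a single unresolvable transient).  The *simulation*
variant accepts local maxima above 1% of the global maximum.  Both locate
pulse boundaries at the 10% rise and 90% fall of each pulse's amplitude by
linear interpolation, and both treat consecutive maxima with no
intervening drop to the initiation level as one pulse event — a flat-topped
plateau (the tax-6 step response) is a single pulse.  Amplitudes are
measured above the trace minimum, making detection invariant to shifts and
positive rescaling.  An optional absolute `range_floor` (set to 2% of
$C_0$ by the scan helpers) keeps numerically flat traces from yielding
spurious pulses.  Degenerate inputs — constant series in
`normalize_trace()`, non-decaying segments in `fit_decay()`, fewer than
three pulses in `interpulse_growth()` — raise classed errors rather than
returning misleading numbers.

## Robustness scans

`scan_one_at_a_time()` sweeps each constant over 0.1–10-fold of its
default; `scan_joint()` draws all constants except `Rt` independently from
a log-uniform distribution spanning a symmetric 10-fold range
($[x/\sqrt{10},\, x\sqrt{10}]$) and scores two features per set: a single
sub-60 s adapting pulse under the 1.15 mM step, and 3–100 gradient pulses
with more than 55% initiating before the midpoint.  Both criteria are
always computed (no short-circuiting) so per-feature rates are
reportable.  At the shipped defaults the joint pass fraction is about
0.50–0.52 at $n = 1000$.  The margin analysis above explains the ceiling:
a drawn set fails the step feature precisely when its drawn capacity
$A$ falls below $k_1\log(L_{step}/L_0)$, which happens for roughly 29% of
independent $\pm\sqrt{10}$ draws; raising the default $A$ to suppress this
would silence the 2-minute habituation probe (both behaviors share the
same refiring margin), and the gradient feature simultaneously pulls $k_1$
in the opposite direction.  Within this architecture the two-feature pass
fraction and a responsive short-interval probe cannot both be pushed
higher, so the defaults favor the qualitative completeness of the
single-set behaviors.

A related consequence: at these defaults, removing the calcium-independent
pathway ($k_6 = 0$) destroys exact adaptation (the first habituation step
refires every couple of minutes) and halves the gap between the two
probes' responses, but off-interval recovery alone still orders them; the
ordering is not strictly $k_6$-dependent here.

`scan_stimulus_amplitude()` repeats both protocols with only the stimulus
concentration changed; both features hold from 0.01× to 100× of the assay
level (10,000-fold).

## The detailed membrane module

`simulate_detailed()` adds a minimal conductance-based voltage module: the
switch $S$ drives a TRPV-like depolarizing conductance, a voltage-gated
calcium conductance with sigmoidal instantaneous activation carries the
calcium influx, and a delayed-rectifier potassium conductance plus leak
repolarize.  It is a deliberately small stand-in for a full ion-channel
reconstruction — two conductances and one gating variable, calibrated only
for a second-scale upstroke and tens-of-seconds calcium decay — and with
the coupling weight `w = 0` it reduces exactly to the simple model.  It
reproduces the wild-type habituation direction and the tax-6
failure-to-adapt; it is not a quantitative model of AWA excitability.

## What the synthetic data do and do not emulate

`trace_from_trajectory()` converts simulated calcium to fluorescence fold
change $(F - F_0)/F_0 = g\,(C - C_0)/C_0$ with a linear gain ($g = 1$ by
default), sampled at the imaging frame rates (1.4 or 3.3 frames/s), with
seeded multiplicative noise (2%), additive noise (1% of peak) and optional
baseline drift.  `cohort()` adds across-individual parameter jitter
(log-uniform, all constants except `Rt`) so that pulse counts and
amplitudes vary between simulated animals while repeated runs of one
animal differ only by measurement noise — the low in-worm / high
between-worm variability seen in recordings.  Deliberately *not* emulated:
indicator saturation (a Hill nonlinearity), photobleaching, motion
artifacts, and any image-level structure.  Tests passing on these traces
therefore validate the analysis pipeline's logic, not its behavior under
real optical artifacts.

`fixture_pulses()` builds detector ground truth as sums of well-separated
Gaussian bumps with the generating pulse list stored in the trace's
provenance.

## Worked example

```{r example, eval = FALSE}
p <- model_params()
step <- criterion_step_stimulus()        # 1.15 mM step, 60-360 s
traj <- simulate_model(p, step)
detect_pulses(traj, pulse_criteria("simulation",
                                   range_floor = 0.02 * p$C0))
#>   index t_peak amplitude   t_init   t_term duration
#> 1     1   65.7  4.482093 60.27913 68.20246 7.923326

tax6 <- simulate_model(make_mutant(p, "tax-6"), step)
max(tax6$data$C) - p$C0    # larger peak, no adaptation while odor is on
#> [1] 4.5
```

Problem sizes used throughout the test suite: single trajectories of
420–2400 s at 0.1 s output resolution, 1000-set joint scans, 200-fixture
detector comparisons, and 100-seed decay-fit replicates.

## Known limitations

* Trajectories cannot be matched quantitatively to the published figures;
  only the qualitative criteria are reproduced (the published constants
  are not in the main text).
* The calcium removal time constant is faster than measured fluorescence
  decays; decay-time comparisons against GCaMP data need an indicator
  model on top.
* The joint-scan pass fraction depends strongly on the calibration point
  (see above) and lands near 0.5 here versus the published 75%.
* The membrane module is a minimal formulation, not a reconstruction of
  measured AWA currents.
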