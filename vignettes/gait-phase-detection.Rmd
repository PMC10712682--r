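---
title: "Modelling and gait phase detection for a pressure-sensing insole matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and gait phase detection for a pressure-sensing insole matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insoleGait)
```

## The system being modelled

`insoleGait` is a desk-scale model of an instrumented-shoe gait analysis
system built around a force-sensitive-film insole. The physical device is a
matrix of resistive sensing units formed at the crossings of 26 row and 8
column conductive tapes laid over a piezoresistive polymer film, trimmed to
the insole outline so that 174 crossings remain active. Each unit's
resistance falls as normal force is applied; scanning electronics read each
unit in turn at 50 Hz, quantize the amplifier output to 12-bit counts, and
a peak-heuristic algorithm turns the per-frame pressure picture into the
four key gait events — heel contact (HC), forefoot contact (FC), heel off
(HO) and toe off (TO) — and the three stance sub-phases they delimit:
initial contact (IC, HC to FC), flat foot (FF, FC to HO) and push off (PO,
HO to TO).

The package implements each layer as testable software: the resistor
network and its readout, the sensing-material response including its
delayed post-unloading behaviour, a synthetic gait generator with exact
ground truth and a synchronized vertical ground reaction force (vGRF)
trace, the detection algorithm, and the evaluation statistics used to
score detections against force-plate style references.

## Matrix readout and crosstalk

A row/column matrix of resistors is economical in wiring but suffers from
*sneak paths*: current injected at one crossing can return through
neighbouring crossings, so a naive scan underestimates every resistance.
Both readout modes are simulated.

**Naive scan** (`simulate_naive_vout`): the selected row is driven, the
selected column is read across a load resistor, and all other lines float.
The package solves Kirchhoff's current law over the row and column nodes
by a direct dense linear solve — at 34 nodes this is more than adequate —
restricted to the component reachable from the driven row (floating
islands carry no current and would make the system singular). The
apparent resistance `R_f (V_i - V_out) / V_out` is provably no larger
than the true one, and strictly smaller whenever a closed loop of active
units passes through the selected lines. The 2-by-2 uniform 10 kΩ matrix
is the textbook case: the 30 kΩ sneak path in parallel with the selected
unit reads 7.5 kΩ.

**Zero-potential scan** (`simulate_zero_potential_vout`): every unselected
line is switched to ground and the selected column feeds the virtual
ground of a transimpedance amplifier. With all line potentials clamped, no
potential difference exists across any unselected unit, so no parasitic
current flows and the output depends only on the selected unit:

$$ R_{ij} = \frac{V_i}{V_{out}} R_f $$

with excitation `V_i = 3.3 V` and load `R_f = 10 kΩ` by default. Two
amplifier topologies are consistent with the circuit description (sensing
unit in the feedback path, or as the input resistor); the package
implements the one consistent with the inversion identity above — unit as
input resistor, `R_f` as feedback — and reports `|V_out|`, since that
identity is the quantitative contract the rest of the system relies on.
`invert_readout` composed with the scan recovers any positive resistance
field to better than one part in 10^9 before quantization, and to within
one LSB-equivalent after the 12-bit conversion (round-half-up with
saturation; the rounding convention is the package's choice).

## Sensing-unit response model

Bench characterization of this class of force-sensitive film shows an
output voltage that grows almost linearly with applied force, unit-to-unit
diversity in gain and baseline, and a *delayed response*: after a
sustained load is lifted the output keeps rising for about one second
before decaying, attributed to slow mechanical relaxation of the insole
surface. Under brief cyclic loading (0.75–1.25 s per cycle, the range of
walking cadences) no apparent delayed response occurs.

The package models the unit as a conductance linear in force,
`G(F) = g0 + gain · F`, which makes the zero-potential readout voltage
exactly affine in force with slope `V_i R_f · gain`. Defaults
(`g0 = 1e-6 S`, `gain = 1e-5 S/N`) place a ~10 N per-unit load — the upper
end of plantar loading on a 25 mm² area during walking — near the ADC's
full scale. Per-unit diversity is drawn log-normally around the nominal
values with a configurable relative spread (default 0.2), deterministic
given a seed.

No constitutive equation is available for the delayed response, so it is
phenomenological, built to reproduce the two qualitative findings and
nothing more. A creep state charges as `ds/dt = (κF - s)/τ_charge`
(`κ = 1`, `τ_charge = 20 s`) while loaded. At an unloading edge the
transient amplitude is gated by a squared-exponential in the load episode
duration (scale `creep_latch = 2 s`): a multi-second hold releases at full
amplitude — the output continues from its pre-release level, rises by a
charge-dependent fraction over `creep_rise = 1 s`, then decays with
`creep_decay = 2 s` — while a sub-1.25 s cycle releases almost nothing,
and the stored charge recovers quickly (`creep_recover = 0.3 s`) so
cyclic output peaks stay stationary instead of ratcheting upward. With
`κ = 0` the dynamics reduce exactly to the identity. These constants were
fixed once, from the qualitative bench behaviour (a visible ~1 s
post-release rise after a 5 s hold; a post-release transient below 5 % of
the loading peak at 40/60/80 cycles per minute), and are all exposed in
`sensor_params()`.

## The synthetic gait generator

`synth_gait_trial` is the package's study-conditions generator, not a
convenience fixture. It emulates the walking protocol end to end: a 10 s
unloaded capture for zero-offset registration, then `n_cycles` gait
cycles at 40, 60 or 80 strides/min, scanned at 50 Hz through the sensor
and readout models with additive post-ADC Gaussian count noise
(default sd 20, about 0.5 % of full scale).

Within each cycle of duration `T = 60/cadence`, ground-truth events sit at
fixed fractions of the cycle — FC at 8 %, HO at 40 %, TO at 62 % (the
stance fraction) — following textbook norms for the stance sub-phases;
cycle-to-cycle Gaussian jitter (sd 10 ms) perturbs each event. Event times
are snapped to the 20 ms scan clock, so the recorded truth is exactly
realizable at the sampled frames; at 50 Hz this is also the system's
stated temporal resolution. Sub-area force envelopes are raised cosines:
the heel loads from HC and unloads by HO, the forefoot from FC to TO, the
toe from `HO - 0.05 s` to TO (the small lead guarantees the toe trace has
a well-defined minimum after HO), and the arch carries a small fraction of
the forefoot envelope. Creep dynamics are applied at the sub-area envelope
level and scaled per unit — valid because the dynamics are homogeneous in
amplitude — which keeps trial generation vectorized.

The vGRF trace is synthesized directly from the same ground-truth events
rather than as the sum of insole forces, so that the force-plate reference
definitions hold by construction: the double-hump profile crosses 10 N
within one frame of HC and TO, peaks (1.1 × body weight, default 620 N)
exactly at FC and HO, and dips to 0.75 × body weight in mid-stance.

Turning emulation is a modelling choice, not a measured fact: a left step
turn is represented by shifting forefoot load medially (a linear
cross-column weighting), lengthening stance by 5 %, and doubling the
timing jitter. The truth-event ordering contract is unchanged.

What the generator does *not* emulate — and therefore what passing tests
cannot show — includes biomechanically validated pressure distributions,
shoe-ground friction, inter-subject variability, electrode ageing, and
any nonlinearity of real film beyond the affine model. Error statistics
obtained on synthetic trials characterize the algorithmic pipeline, not
the physical device: field measurements with real hardware and force
plates report absolute timing errors of tens of milliseconds, driven by
effects outside this model.

## The detection algorithm

Preprocessing follows the device's conditioning chain: per-unit zero
offsets (means of the unloaded capture) are subtracted, each unit's series
is filtered with a third-order zero-phase low-pass Butterworth at 7 Hz
(forward-backward application; odd-reflection padding suppresses edge
transients), and each sub-area's units are averaged into
`P_heel, P_arch, P_forefoot, P_toe`. Averaging across units is what makes
the algorithm robust to per-unit gain diversity; `P_arch` is computed and
exposed but unused by the event rules. Filtering precedes averaging, per
unit, matching the device's conditioning order.

Cycle segmentation is artifact-defined (a device streams continuously,
and the event rules need per-cycle windows): the summed sub-area output
delimits stance activity against a threshold of 5 % of the trial maximum;
quiet gaps of at least 0.15 s separate cycles, and each activity run is
padded by 3 frames into its neighbouring gaps so the bracketing minima are
visible to the event search.

Within a window, events are found by peak heuristics:

* `t1` — first qualified peak of `P_heel`; **HC** is the minimum
  immediately before `t1`.
* `t2` — first qualified peak of `P_forefoot`; **FC** is the minimum
  immediately before `t2`, constrained after HC.
* **HO** — first minimum of `P_heel` after FC (the heel output starts to
  rise again there when the delayed response is present).
* **TO** — first minimum of `P_toe` after HO.

Numerical choices, all of which matter near the noise floor:

* *Peak qualification.* A peak must rise and fall by at least 5 % of the
  window's peak-to-peak range (a reversal-confirmed scan), rejecting
  noise-induced micro-peaks. Peak plateaus collapse to their first frame.
* *Backward minimum searches* (HC, FC): the nearest turning-point minimum
  before the peak whose depth is within a tolerance of the segment floor.
  The tolerance is four times a robust noise scale estimated from the
  window's quiet samples (median absolute deviation of the near-floor
  decile), so it adapts to the noise level and vanishes on clean data. A
  flat pre-onset plateau therefore yields its last frame — the moment
  loading begins — which is the behaviour the "minimum right before the
  peak" rule intends.
* *Forward minimum searches* (HO, TO): the first frame at which the
  falling output reaches its floor band — where the decrease ends and any
  delayed-response increase can begin. The band is the greater of the
  noise tolerance and 1 % of the window range; the wider floor definition
  compensates for the zero-phase filter rounding the descent corner into
  the flat side. This rule works identically with the creep transient
  present (a genuine rebound minimum) and with creep disabled (a flat
  floor), which is tested under both settings.
* *Failure is explicit.* A missing extremum (flat signal, absent peak)
  yields `NA` for that event and a status string, never a silently wrong
  time; an ordering violation invalidates the whole cycle.
* Event timestamps are frame-aligned; no sub-frame interpolation is
  attempted, matching the 20 ms resolution of the 50 Hz scan.

Phase durations are then differences of event times, and telescope
exactly: `T_IC + T_FF + T_PO = t_TO - t_HC`.

## Evaluation against the vGRF reference

`detect_reference_events` applies the standard force-plate definitions:
HC at the first frame with `Fz > 10 N`, TO at the first frame after
loading with `Fz < 10 N`, FC at the first local maximum of the loading
curve and HO at the second. Peak qualification mirrors the detector's
prominence rule, since "first/second peak" is a visual definition that
needs a formal noise guard.

Per cycle and per event, the relative difference `RD = t_shoe - t_ref`
(positive = detection lags the reference) and absolute difference
`AD = |RD|` are computed; per set, the median error `ME = median(AD)` and,
for phase durations, the percentage difference `%D = AD / t_stance_ref ×
100`. `summarize_errors` aggregates records into the usual report: mean
and sd of AD and RD in frames and milliseconds (converted once, at the
trial's sampling rate), ME, %D, and the detection rate. Cycles with
missing detections are excluded from the error statistics and surfaced
through the detection rate instead — reporting them as arbitrary large
errors would conflate two different failure modes.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on generated data:
readout checks sweep 100 random 174-unit resistance fields; timing
recovery uses noiseless 3-cycle trials at each cadence; the detection-rate
study uses 160 noisy cycles (8 straight and 8 turning trials of 10 cycles
at mixed cadences). These sizes give stable statistics while keeping a
full run in seconds. Every stochastic step — unit diversity, timing
jitter, count noise — flows from explicit integer seeds, and identical
seeds reproduce trials byte-for-byte.

## Known limitations

* The creep model is a two-regime phenomenological construction; it does
  not model material viscoelasticity, temperature or humidity, and the
  growth of unit diversity with dwell time is not represented (diversity
  is a static gain spread).
* The turning mode is an emulation stand-in; no claim is made about real
  medial load migration during turns.
* Swing-phase duration is out of scope (a single force plate cannot
  provide a reference for it), as are real-time operation and wireless
  transport.
* The pin-level multiplexer timing, switch settling and amplifier
  bandwidth of the scanning electronics are not modelled; scans are
  treated as instantaneous per frame.
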