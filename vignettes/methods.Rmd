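---
title: "Methods: from raw plate signals to sway clinimetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw plate signals to sway clinimetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coptools)
```

`coptools` turns raw recordings from a four-sensor balance board (the
*index* device) and a six-component laboratory force plate (the *reference*
device, with the board stacked on top) into center-of-pressure (COP)
trajectories, sway parameters, and the reliability/validity statistics used
to judge whether the cheap device can stand in for the expensive one. This
vignette is the package's own account of how each stage works, which knobs
it exposes, and where its limits are.

## Processing model

A trial moves through five stages:

1. **Calibration** (board only). A zero-load window and a window with a
   known mass centred on the board give each corner sensor a linear map
   `force = gain · (raw − offset)`. A centred mass rests equally on the
   four corners, so the expected per-sensor force is `mass · g / 4`. Sample
   means over the full calibration windows are used; the (low) calibration
   sampling rate is metadata only. The model is a pure per-channel linear
   map — no cross-talk terms — which is the strongest assumption of this
   stage.
2. **Filtering.** Every channel is low-pass filtered with a zero-phase
   Butterworth filter: design order 4, cutoff 10 Hz, applied forward and
   backward. "Order 4" names the design order; the bidirectional magnitude
   response is the square of the single pass (−6 dB at the cutoff). Zero
   phase matters because COP parameters are computed from sample-to-sample
   differences, which phase distortion would bias.
3. **Alignment.** The devices run on separate clocks, so their files share
   no time origin. Both matching series are decimated to the common 20 Hz
   rate and the integer lag maximizing their normalized cross-correlation
   (searched within ±5 s) is rescaled to each native rate by rounding;
   leading samples are trimmed accordingly, and the tails are cut to a
   common duration. The board's matching series is its bottom-left sensor;
   the wrench record exposes no corner sensors, so a *virtual* bottom-left
   force `fz'/4 · (1 − u)(1 − v)` is reconstructed from its COP — the
   closest six-component analogue of matching the two bottom-left sensors.
   Sub-sample alignment is deliberately out of scope: the smallest
   meaningful unit downstream is one native sample.
4. **Segmenting.** Stance onset is the first sample from which the total
   vertical force stays within ±5% of the series median for a continuous
   2 s — a concrete rule standing in for the protocol's informal "first
   stable position". The analysis window is the central 20 s (bipedal) or
   15 s (unipedal) of the post-onset span, at each device's native rate.
   If no stable window exists the segment starts at sample 1 and a warning
   is attached rather than failing the trial.
5. **COP and metrics.** Corner forces invert to COP through the lever
   relation on the sensor spans; the wrench uses the moment equations with
   two stacked-plate corrections (board weight off `fz`, moment arm of
   horizontal forces extended by the board height). Both land in one frame:
   ML = x positive right, AP = y positive anterior, cm, origin at plate
   centre. The six sway parameters follow; the 95% prediction ellipse area
   is always computed on the 20 Hz version of the segment, the other five
   at the segment's native rate (displacement SDs are rate-insensitive;
   velocity and pathlength are reported at the rate they were measured at,
   which keeps the two devices' values comparable to their own published
   conventions).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff_hz` | 10 | Hz | Postural sway carries almost all its power below a few Hz; 10 Hz keeps physiological content and rejects sensor noise. |
| `filter_order` | 4 | — | Design order of the Butterworth filter (even); effective roll-off is doubled by the backward pass. |
| `common_rate_hz` | 20 | Hz | Shared rate for alignment and ellipse area; integer divisor of both device rates (40, 100). |
| `bipedal_segment_s` / `unipedal_segment_s` | 20 / 15 | s | Protocol analysis windows; unipedal trials fail sooner, hence shorter. |
| `board_sensor_span_ml` / `_ap` | 43.3 / 23.8 | cm | Distances between the board's sensor pairs; config values, not constants. |
| `plate_top_offset_cm` | 5.3 | cm | Plate origin to board surface; moment arm of horizontal forces. |
| `board_mass_kg` | 3.9 | kg | Weight correction subtracted from the plate's `fz`. |
| `force_floor_n` | 50 | N | Frames with less total load are an unloaded plate, not a division by ~0. |
| `max_lag_s` | 5 | s | Largest admissible clock offset; a lag estimate at this bound means the recordings do not overlap. |

Clinimetric knobs: the ICC "marginal difference" gate is 0.01 (agreement at
the second decimal) — if ICC(1), ICC(A,1), ICC(C,1) agree within it, only
the one-way form is reported, otherwise both two-way forms with a bias
flag. SEM uses the pooled SD of all `n · k` observations about the grand
mean by default (`sd_source = "session1"` switches to the first session's
SD); which SD a given publication used is often unstated, so the choice is
recorded in every report.

## The sway simulator

`simulate_sway()` draws each COP axis from an exactly discretized
Ornstein–Uhlenbeck process — the simplest stationary process with tunable
low-frequency power concentration — then band-limits it at 4 Hz so that
both device rates resolve it fully. Defaults are fixed at realistic
quiet-stance values: stationary SD 0.17 cm (ML) and 0.42 cm (AP), time
constant 1.5 s (position power concentrated below 1 Hz), 79.4 kg subject,
35 s trials. `render_devices()` inverts the COP formulas exactly —
distributing the subject's weight as `F/4 · (1 ± u)(1 ± v)` over the
corners and building the wrench moments from the same truth — then applies
the imperfections: a 0.65 s start lag, 1 ms timestamp jitter on the board,
white channel noise (0.2 N board / 0.05 N plate), and the board's
characteristic broadband differential ML noise (1.5 N above a 2.5 Hz
corner, injected at sensor level so its propagation through the COP
quotient is exercised). All randomness flows from one seed; equal
configurations reproduce bit-identical recordings.

`simulate_cohort()` scales both axis SDs per subject and session by
`1 + a_i + e_ij` with independent normal subject and session effects, so
the ground-truth scale has intraclass correlation
`σ_a² / (σ_a² + σ_e²)` and test–retest behaviour is known by construction.

What the simulator does *not* emulate: inverted-pendulum biomechanics,
intermittent postural corrections, drifting baselines, sensor saturation,
or clock *skew* (only a constant offset). Pipeline tests passing on it
demonstrate algorithmic correctness — formula inversion, alignment,
segment bookkeeping, statistical identities — not that any physical device
meets its spec.

A note on what closure can promise: a 20 s window of a process with a
1.5 s correlation time contains only a dozen-odd independent stretches, so
a *displacement SD* estimated from one segment carries irreducible sampling
noise of tens of percent. The pipeline-closure checks therefore compare
pipeline output against ground-truth metrics *computed on the same
segment*, where agreement within 1% is achievable; and the cohort-level
test–retest check uses pathlength, whose estimation noise per segment is
small, so zero within-subject variance really does yield an ICC near 1.
This mirrors real posturography, where modest test–retest ICCs reflect
within-subject variability rather than device error.

## Numerical choices

- **Zero-phase filtering** pads with odd-symmetric signal extensions and
  seeds each pass with steady-state initial conditions, so a constant
  series passes through bit-near-exactly (DC error < 1e−9) and edge
  transients never reach the analysis segment.
- **Decimation** keeps every r-th sample starting at the first; no
  interpolation anywhere. Non-integer rate ratios are an error, not a
  resample.
- **Lag ties** break toward the smallest absolute lag; an all-negative
  correlation profile is reported with a sign flag and a warning instead of
  silently choosing a meaningless positive peak.
- **Ellipse degeneracy**: zero variance on an axis gives area 0 with a
  warning; the small-sample F-based prediction factor is used everywhere,
  with its χ² limit (5.9915) documented for large n.
- **ICC edge cases**: zero total variance flags the estimate as undefined
  rather than returning 0/0; negative estimates and CI bounds are reported
  as computed, never truncated; the ICC(A,1) interval uses the
  Satterthwaite degrees-of-freedom approximation.
- **Jitter** is diagnosed (per-recording SD of sampling intervals, with a
  group t-interval) but never corrected; all series are treated as
  uniformly sampled at the nominal rate.
- **Sums of squares** for the ANOVA decomposition are computed explicitly
  (grand mean, row, column, residual) — the tests cross-check them against
  `stats::aov` to 1e−10 on random matrices.

## Problem sizes

The shipped tests and the acceptance script run: 500 random matrices for
the ICC-vs-oracle check; 1000 simulated 30×2 cohorts for ICC(A,1) recovery
and CI coverage; 10⁵ bivariate normal points for the ellipse-area
Monte-Carlo; 10 noise-free trials for metric closure and 100 seeded trials
for lag recovery; 12 simulated participants for the device-comparison
spectra. These sizes give the statistics involved comfortable margins over
their tolerance bands while keeping a full run under a minute.

## Known limitations

- The on-disk dialect (CSV columns, YAML config, JSON reports) is this
  package's own; no vendor binary formats are read.
- Calibration is two-point and per-channel; multi-point curves, cross-talk
  and temperature drift are out of scope.
- Alignment assumes a constant clock offset; skew over a trial is not
  modelled (and is negligible over tens of seconds for these devices).
- Nonlinear sway measures (entropy, diffusion analysis, rambling–trembling)
  and Bland–Altman limits of agreement are not implemented.
- Spectra are compared as curves; the package intentionally attaches no
  test statistic to them.
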