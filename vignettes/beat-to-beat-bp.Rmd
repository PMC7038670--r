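---
title: "Methods: cuff-anchored beat-to-beat blood pressure from piezoelectric pulse waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuff-anchored beat-to-beat blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezobp)
```

## The measurement model

A piezoelectric pulse sensor strapped over the radial artery converts
arterial pressure to voltage linearly, with sensitivity $S$ (mV/mmHg) over
its rated range. An analog front end AC-couples, amplifies (gain $G$) and
band-limits the signal. If $V_{\max,k}$ and $V_{\min,k}$ are the amplified
voltages at the systolic peak and diastolic foot of beat $k$, the chain is
linear, so a *change* in output voltage maps back to a pressure change:

$$\Delta \mathrm{mmHg} = \frac{\Delta V \times 1000}{G \cdot S},$$

the factor 1000 converting amplifier-output volts to sensor-referred
millivolts. Tracking anchors at one oscillometric cuff reading
$(\mathrm{SBP}_0, \mathrm{DBP}_0)$ taken at recording start and accumulates
adjacent-beat voltage changes:

$$\mathrm{SBP}_k = \mathrm{SBP}_0 + \sum_{j<k}
  \frac{(V_{\max,j+1}-V_{\max,j})\times 1000}{G\,S},$$

and likewise for DBP from the foot voltages. The sum telescopes:
$\mathrm{SBP}_k$ depends only on $V_{\max,k}-V_{\max,1}$. This makes the
method *exact* whenever the chain is linear and drift-free — and it makes
every residual baseline drift in the feature voltages integrate directly
into the tracked pressure. Both properties are tested: the bypass
round-trip recovers the simulated truth to machine precision, and the
tracker reports the first-to-last foot-voltage drift as a quality metric
rather than correcting it silently.

At the reference design values ($S = 2$ mV/mmHg, $G = 49.4\,\mathrm{k\Omega}
/ R_G + 1 = 989$ at $R_G = 50\,\Omega$) one sensor-referred millivolt is
0.5 mmHg.

## What the synthetic generator emulates

The generator produces the quantities a bench experiment cannot easily
give: per-beat ground truth.

* **BP trajectories.** Per-beat SBP and DBP follow independent Gaussian
  random walks anchored at the cuff pair, reflected at 70–190 mmHg
  (systolic) and 40–100 mmHg (diastolic) — the physiological span from
  hypotension to hypertension. The default step SD of 0.5 mmHg/beat is the
  package's reference study condition. A random walk is deliberately
  pessimistic: real resting BP is mean-reverting, whereas a walk's
  excursion grows as $\sigma\sqrt{k}$, which stresses the tracker's known
  weakness (below).
* **Pulse morphology.** Each cycle is a fixed template — a dominant
  systolic Gaussian bump plus a dicrotic shoulder — rescaled affinely per
  beat so that the *sampled* maximum and minimum equal that beat's true
  SBP and DBP exactly. A small "foot rise" pedestal keeps the
  late-diastolic tail a margin (5% of pulse amplitude) above the foot, so
  the waveform minimum between two systolic peaks is exactly the
  intervening beat's foot sample. The shape itself is not meant to be
  hemodynamically accurate (no Windkessel physics, no pressure-dependent
  morphology change); only its feature points carry meaning, which is
  precisely what the tracking method consumes. Beats are delimited
  foot-to-foot; a beat's DBP feature is the valley preceding its peak.
* **Disturbances.** Respiratory wander is a sinusoid (default 0.25 Hz,
  15 breaths/min; amplitude 10% of the mean pulse span), optionally plus a
  smoothed random drift; measurement noise is white Gaussian (default 2%
  of span). Motion artifacts, sensor-coupling changes and arrhythmias are
  *not* modeled; passing tests say nothing about those.

Default sampling rate: 500 Hz (peaks resolved to < 2 ms; tests mostly use
250 Hz for speed). Times are in seconds with sample $i$ at $i/f_s$.

## The analog front end

The cascade is modeled in hardware order: first-order AC-coupling
high-pass at 0.03 Hz (the differential two-capacitor coupling is
magnitude-equivalent to one first-order stage), second-order Butterworth
high-pass at 0.05 Hz, gain 989, second-order Butterworth low-pass at 35 Hz
(second order because each filter stage has two RC products; cutoffs are
stored directly since component values are a free choice —
`cutoff_from_components()` maps an RC pair, or two, to its cutoff).

Two views are provided and tested against each other: the analytic
magnitude $|H(f)| = G \cdot |HP_1| \cdot |HP_2| \cdot |LP_2|$ with the
standard Butterworth forms, and a time-domain realization using
bilinear-transformed digital filters at the trace's sampling rate. The
sweep (2000 log-spaced points over $10^{-3}$–$10^{3}$ Hz) reports a
midband of 59.90 dB and half-power crossings at 0.0575 Hz and 35.00 Hz.
Two numerical conventions matter here:

* crossings are the *half-power* points ($-10\log_{10}2 \approx
  -3.01$ dB below midband), so an isolated Butterworth stage's crossing
  equals its design cutoff exactly;
* the crossing is bracketed on the sweep and refined by linear
  interpolation in $(\log f, \mathrm{dB})$ on a 400-point local regrid,
  giving about $10^{-4}$ relative accuracy.

The lower crossing sits slightly above the 0.05 Hz design value because
the 0.03 Hz AC-coupling stage adds attenuation at the high-pass corner;
an idealized cascade cannot land below its own high-pass cutoff. Hardware
characterizations of this design print 0.05 and 35.12 Hz; the ~0.3%
gap at the upper corner reflects unpublished component values, and the
implementation reports its computed crossing rather than tuning toward
the printed one.

Causal filtering is the default (it mimics the analog chain, including its
phase distortion); `zero_phase = TRUE` switches to forward-backward
filtering. Op-amp non-idealities, CMRR and noise figure are out of scope.

## Post-processing

**Detrending.** The baseline estimate is a cascaded (two-pass) moving
average with windows $w$ and $w/2$, $w$ defaulting to one beat period
(0.833 s at 72 bpm; the pipeline sets it from the configured heart rate).
A rectangular average of width $w$ has transmission zeros at multiples of
$1/w$, so with $w$ equal to the beat period the pulse fundamental and all
its harmonics are nulled out of the baseline — measured on the 72 bpm
synthetic: 99.6% removal of a 0.05 Hz sinusoid, 91% removal of 0.25 Hz
respiratory wander, per-beat span distortion 0.25%, and re-detrending
changes the output by ~0.1% (idempotence). A single wide moving median
(the obvious alternative) was measured to remove only ~50% of 0.25 Hz
wander while distorting spans by ~8%, because a nonlinear median over
several cycles tracks a quantile of the pulse shape; it remains available
as `detrend_method = "moving_median"` (median pass plus smoothing) for
traces with impulsive artifacts, and a global polynomial fit for short
segments. Edges use reflection padding; the pipeline runs preprocessing
before discarding the settling lead-in so edge bias lands in discarded
samples.

**Denoising.** Wavelet shrinkage with the standard recipe: db4,
decomposition depth $\lfloor \log_2(f_s/8) \rfloor$, universal threshold
$\hat\sigma\sqrt{2\ln N}$ with $\hat\sigma$ from the MAD of the finest
detail scale, soft thresholding. The transform is a periodized orthonormal
DWT (reflection-padded to a dyadic-divisible length); synthesis is the
transpose of the orthonormal analysis operator, so reconstruction is exact,
which the tests verify directly. The vendor denoiser this stands in for is
parameterless in the source material; all choices are exposed in
`preprocess_config()`.

## Feature detection

Thresholds are placed at fixed fractions (defaults 0.6 and 0.4) of the
locally estimated dynamic range (5 s blocks, neighbour-widened,
interpolated per sample), making detection invariant to offsets and robust
to residual drift. Each excursion above the upper threshold contributes
one peak — the maximum sample, earliest on ties; peaks closer than the
0.25 s refractory period (240 bpm ceiling) are merged keeping the larger.
Valleys are the minima between consecutive peaks, plus a leading/trailing
foot when the trace dips below the lower threshold outside the peak span.
On clean synthetic traces the detected features are sample-identical to
the per-beat brute-force extrema, which the tests check for 1–50 beats.

## Pipeline and settling

`run_pipeline()` chains simulate → wander → noise → transduce → front end
→ detrend → denoise → detect → track → evaluate, with one global seed
fanned out to fixed per-stage offsets (+101 trajectory, +202 wander,
+303 noise). The analog chain is driven with a 60 s constant-BP lead-in
that is discarded before post-processing: the high-pass stages' step
response otherwise corrupts the anchor beat, and through the telescoping
sum, every later beat. Sixty seconds is more than ten time constants of
the slowest stage ($\tau = 1/(2\pi \cdot 0.03\,\mathrm{Hz}) \approx
5.3$ s).

Evaluation pairs each reference reading (simulator truth at 1-minute
intervals, the initial cuff reading included, matching 30 readings in
30 minutes) with the nearest tracked beat within 2 s, then computes

$$\mathrm{MAE} = \frac1n \sum_i |y_i - x_i|, \qquad
  \mathrm{SD} = \sqrt{\frac{\sum_i (y_i - x_i - \mathrm{MAE})^2}{n-1}}.$$

The SD formula is implemented exactly as device-validation tables print
it: the dispersion of *signed* errors about the mean *absolute* error.
This is nonstandard — it is not invariant under flipping error signs, and
for uniformly positive errors of equal size it gives 0 while for
sign-balanced errors it roughly doubles the usual SD. Because published
per-subject tables cannot be re-derived to settle which convention they
used, both are implemented (`sd_variant = "signed"` default,
`"abs_error"` alternative) and the divergence is pinned down by explicit
arithmetic tests.

## Known limitation: drift blindness

Every stage that removes baseline wander — the 0.03/0.05 Hz analog
high-passes and the digital detrend — also removes *true* blood-pressure
variation in the same band. The pulse span (SBP − DBP) modulates the
carrier at the beat frequency and survives filtering, but a slow
common-mode shift of SBP and DBP is spectrally identical to baseline
drift and is irrecoverable after AC coupling. For a random-walk truth
with step SD $\sigma$, the tracked-vs-true error at beat $k$ therefore
grows like the walk's low-frequency excursion, on the order of
$\sigma\sqrt{k}$: with $\sigma = 0.5$ mmHg/beat this is ~4 mmHg after one
minute and ~20 mmHg after thirty. Measured end-to-end under the reference
conditions, the larger-of-SBP/DBP MAE over 30 one-minute references ranges
from ~4 to ~14 mmHg across seeds, and the signed-error SD from ~4 to ~28 —
sometimes inside, sometimes far outside the usual validation bounds
(MAE ≤ 5, SD ≤ 8 mmHg). That is a property of the method, not of the
implementation: any AC-coupled delta-accumulation tracker needs periodic
cuff re-anchoring to follow slow drift, and real resting BP
(mean-reverting, unlike a random walk) flatters it. The package surfaces
the foot-voltage drift as a quality metric and leaves re-calibration
policy out of scope.

## Problem sizes

Unit tests run at 250 Hz with records from 1 to 360 beats; the end-to-end
study uses the full 30-minute, 2160-beat record at 500 Hz (~10 s of
compute). The acceptance script (`scripts/acceptance.R`) regenerates the
frequency-response sweep and the 30-minute study from scratch at the seed
given on the command line.
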