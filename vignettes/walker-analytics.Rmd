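---
title: "Methods: gait symmetry, neuromuscular and stability analytics for an instrumented walker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait symmetry, neuromuscular and stability analytics for an instrumented walker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srwalker)
```

## The problem

A sensor-instrumented rehabilitation walker records three signal
modalities while a patient walks: bilateral handlebar forces from
force-sensing resistors (FSRs) read through a 10-bit ADC, surface
electromyography (sEMG) from an arm muscle in millivolts, and tri-axial
acceleration of the walker frame.  Over a 15-day program with closed-loop
vibrotactile feedback, patients with rheumatoid-arthritis-related gait
impairment redistribute load between their hands, increase neuromuscular
engagement, and the walker's analytics should quantify all of it:
how asymmetric the loading is, when to cue the user, when the frame is
tipping, how muscle activation evolves, where the rehabilitation
trajectory is heading, and how regular the gait cycle is.

`srwalker` implements this full analytical chain, driven by a seeded
synthetic generator so that every stage is testable without recorded
patient data.

## Force symmetry

The core metric is the Robinson symmetry index,

$$\mathrm{FSI} = \frac{|F_R - F_L|}{F_R + F_L} \in [0, 1],$$

0 meaning perfect left/right symmetry and 1 total asymmetry.  It is
symmetric in its arguments and invariant to common rescaling of both
forces, so it does not care whether the patient leans hard or lightly,
only how unevenly.

Two aggregation conventions were possible for the one-value-per-day
trajectory; we compute the FSI *of the session-mean forces* rather than
the mean of per-sample FSI values.  The former is robust to instantaneous
near-zero-load samples (for which the index is undefined or wildly noisy)
and corresponds to the question "how asymmetric was the average loading
today".  Samples where both channels fall below a 0.5 N contact floor are
excluded as non-contact before averaging.

Percentage improvement between baseline and end of program is
$100\,(\mathrm{FSI}_1 - \mathrm{FSI}_{15})/\mathrm{FSI}_1$; applied to the
published ten-subject endpoint table this reproduces every printed
improvement value to two decimals, so we treat it as the implicit
definition.  Report tables round half-up (4 decimals for FSI, 2 for
percentages), matching clinical-table conventions rather than R's
round-half-to-even.

ADC counts are mapped to newtons by piecewise-linear interpolation
through a calibration curve of known reference loads, clamped at the end
knots; the default curve is linear with 100 N full scale.

## The synthetic cohort

The generator's defaults *are* the study conditions:

* ten subjects whose Day-1/Day-15 FSI endpoints equal the published
  per-subject values (cohort means 0.9691 and 0.2019);
* fifteen days; session length 80 s; force sampling 50 Hz; sEMG 4 kHz;
  accelerometer 100 Hz;
* force-sensor noise 0.5 N (roughly 1 % of a typical 50 N total
  handlebar load);
* per-subject sEMG amplitude endpoints spread around, and averaging
  exactly to, 0.885 mV (Day 1) and 5.138 mV (Day 15);
* total handlebar load 44--62 N across subjects.

Between the endpoints the FSI target decays *geometrically*
(constant-rate relative decay).  The published trajectories show a smooth
monotone decline without stating a functional form; exponential decay is
the standard first model for adaptation curves, and a linear option is
retained per profile.  Within a session, both force channels share a
common sinusoidal gait-phase modulation (1 Hz, depth 0.3); because the
modulation is common-mode it cancels exactly in the session-mean FSI, so
zero-noise streams reproduce their day's target index exactly -- this is
what makes the generator usable as a calibration oracle for the symmetry
module.

All randomness flows from one master seed.  Each stream
(subject x day x modality) derives a sub-seed by hashing its identity
string together with the master seed, so regenerating any one stream
never perturbs the others and two runs with the same master seed are
bit-identical.

What the generator does **not** emulate: musculoskeletal dynamics, RA
pathology, fatigue within a session, sensor drift across days, or the
resistance-to-force characteristic of real FSR voltage dividers (the
hardware's divider constants are not published; the ADC mapping is a
configurable calibration curve instead).  Passing tests therefore
demonstrate the correctness of the analytics under the stated statistical
structure, not clinical validity on real recordings.

## Closed-loop haptic feedback

The trigger threshold is calibrated as the arithmetic mean of asymmetry
samples observed under varying load (the shipped default reproduces a
five-subject, 100-instance calibration protocol on seeded synthetic
draws).  During a session the per-sample normalized asymmetry is compared
against the threshold; a raw force-difference mode (newtons) is available
as a configuration knob because the original hardware's trigger statistic
is not documented.

The motor on the *heavier* side is activated, cueing the user to unload
it; side assignment is not documented either, and this choice is the one
consistent with "vibration means: shift weight away from here".  A side
cannot retrigger while its 300 ms pulse window is open, which caps the
event rate at one pulse per duration and makes the event count monotone
non-increasing in the threshold.  The simulated actuation latency
(default 50 ms) must respect the 120 ms loop-latency bound carried in the
configuration.

## Walker instability detection

Tilt is the angle between the measured acceleration and the device
z-axis (convention: z up, right-handed), `acos(az/|a|)`.  Classification
uses two tilt bands (upright < 15 deg <= inclined < 60 deg <= falling)
plus a free-fall override: a gravity-isolated magnitude below 0.5 g
forces the falling state regardless of tilt.  The thresholds are
engineering defaults -- the source system documents only that "predefined
thresholds" exist.

Raw accelerometry cannot be read as orientation through gait impact
spikes and sensor jitter, so each axis is low-pass filtered (2 Hz,
2nd-order zero-phase Butterworth) before tilt and magnitude are computed.
Without this gravity isolation, sensor noise near a threshold fragments
one falling episode into many and alerting becomes erratic.  One alert is
emitted per contiguous falling episode persisting at least the 200 ms
debounce.  The module detects *walker* instability; it does not claim to
detect or predict user falls.

## sEMG conditioning

The chain is band-pass -> wavelet denoise -> rectified amplitude, with
stages enforced in that order on the record object.

* **Band-pass**: Butterworth 30--500 Hz.  "4th order" is read as overall
  filter order 4, i.e. a 2nd-order band-pass section, applied
  forward-backward (`filtfilt`) for zero phase.  Designed gains: passband
  deviation under 1 %, 1 Hz stopband leakage under 1 %, DC removed.
* **Wavelet denoise**: Daubechies db4, 4 dyadic levels, soft thresholding
  at the universal threshold $\sigma\sqrt{2\ln N}$ with $\sigma$
  estimated from the median absolute deviation of the finest-level
  details.  The periodized transform is implemented in-package (analysis
  and synthesis are exact inverses; the filters match standard db4
  coefficients to 10 significant digits) and signals are reflect-padded
  to a dyadic multiple, so length is preserved.  Because the finest level
  at 4 kHz spans 1--2 kHz where clean sEMG carries no energy, the noise
  estimate is driven by genuine contamination and the denoiser is
  near-identity on clean records.
* **Amplitude**: mean rectified value (RMS provided as a secondary
  metric).

The synthetic sEMG is amplitude-modulated filtered Gaussian noise -- the
standard surrogate -- with its spectrum shaped to the realistic 60--200 Hz
concentration of biceps sEMG and rescaled so the clean mean rectified
amplitude equals the day-interpolated target exactly.  Contamination is a
0.4 Hz baseline drift and a 750 Hz interference tone with documented
amplitudes.  The sEMG sampling default is 4 kHz: with the band edge at
500 Hz, a 2 kHz rate would place the signal band directly against the
finest wavelet level and spectral leakage would inflate the noise
estimate.

The Day-1 versus Day-15 comparison is a classical paired t-test on
per-subject amplitudes (two-sided, since sidedness is not documented),
with Q-Q quantile pairs at plotting positions $(i - 1/2)/n$ available for
the normality check.  Two published values cannot be recomputed from
printed information and are deliberately not targeted: the printed
t-statistic (per-subject amplitudes are not published) and the printed
amplitude change of 4.28 mV, which differs slightly from the difference
of the printed means (5.138 − 0.885 = 4.253); the package reports the
computed difference.

## Gaussian process trajectory model

The trajectory model is exact GP regression written from first
principles: constant mean fixed at the training average, RBF kernel
$k(x,x') = \sigma_f^2 \exp(-(x-x')^2/2\ell^2)$, Gaussian observation
noise $\sigma_n^2$.  Inference uses a Cholesky factorisation of
$K + \sigma_n^2 I$ with escalating jitter ($10^{-10}$ to $10^{-6}$,
scaled by $\sigma_f^2$) should the factorisation fail.  Hyperparameters
maximise the log marginal likelihood by L-BFGS-B in log space with
analytic gradients, restarted from seeded log-uniform draws plus one
data-driven start; the best restart wins.  Dense-inverse oracles verify
likelihood, mean and variance to 10 significant digits on small fixtures;
with $\sigma_n^2 = 0$ the model interpolates its training data and far
from data it reverts to the prior mean and signal variance.

Predictive 95 % bands are observation-level (they include
$\sigma_n^2$), because plotted bands are expected to envelop noisy
measurements.

The modelled series is the pooled cohort trajectory: 80 one-second
epochs per day over 15 days (1200 points per channel), each point the
across-subject mean of the epoch-averaged channel force, with one GP per
handlebar channel.  Three choices matter here:

* the underlying recovery curve is sampled *continuously* in time.
  Rehabilitation progress is continuous; a per-day staircase would be
  both unrealistic and hostile to any smooth regression model (the
  maximum-likelihood length-scale collapses onto the day boundaries);
* epochs span whole gait-modulation cycles, so the within-session
  modulation integrates out of the epoch means;
* the train/test split is chronological (earliest 80 % for training)
  because forecasting the future trajectory is the model's purpose, and
  the 5-fold cross-validation uses contiguous blocks for the same
  reason.

Under these conditions the chronological holdout $R^2$ on both channels
sits above 0.9 (typically 0.97--0.99), the same regime as the published
per-channel accuracy; the exact published $R^2$/RMSE values are bound to
the unpublished recordings and are not reproduction targets.

Problem sizes used by the test suite -- 1200-point trajectories, 200-point
parameter-recovery draws over 20 seeds, 150-point cross-validation
fixtures -- were chosen to exercise the dense solver in the regime the
study describes while keeping each fit to seconds.

## Stride-time variability

Footfall peaks are detected as local maxima with topographic prominence
of at least 30 % of the signal range and separation of at least 0.4 s
(human stride constraints).  "Transient filtering" is implemented as:
drop the first and last detected cycles, then gate intervals at
median +/- 3 scaled MAD.  The MAD is floored at one sample period --
peak times are quantized to the sampling grid, so a perfectly periodic
signal has MAD 0 and would otherwise disable its own gate.

Stride intervals generated from the timing-jitter model
$t_i = i\,\mu + \varepsilon_i$, $\varepsilon_i \sim N(0, \sigma^2)$
have interval variance $2\sigma^2$ (differencing doubles the jitter
variance and induces lag-1 anticorrelation); this closed form anchors the
generator tests.  Group defaults encode the clinical contrast the module
must detect: control gait at 1.1 s mean stride with 0.02 s jitter,
ALS-like gait at 1.3 s with 0.06 s jitter.  The group comparison reports
mean within-subject variances, their ratio, and a median-centred Levene
test on the pooled intervals -- chosen over an F-test for robustness to
non-normal stride distributions, since the source analysis does not name
its test.  The external ALS recordings themselves are not packaged and
their specific variance values are not targets; precomputed interval
files can be supplied through the documented CSV schema.

## Orchestration and reproducibility

`run_pipeline()` executes generation, symmetry, feedback, instability,
sEMG, GPR and stride stages against one configuration object, writes CSV
and JSON artifacts when given an output directory, and consolidates a
report whose provenance carries the master seed and an FNV-1a hash of the
canonical-JSON configuration -- never a wall-clock timestamp -- so two runs
with the same seed serialise byte-identically.  Stream files are
validated against exact column schemas with located range and
monotonicity errors.  The package's interface is its exported functions;
a thin command-line front-end over them ships in `inst/cli/srwalker.R`
for shell-driven runs.

## Known limitations

* All calibration targets are endpoint-based; the shape of each
  subject's recovery between Day 1 and Day 15 is a modelling assumption,
  not data.
* The feedback simulator carries actuator parameters as metadata only;
  no perception or actuator physics is modelled.
* Fall detection sensitivity/specificity claims hold for the synthetic
  orientation sweeps at the stated noise levels; real-world walker
  instability is richer than programmed tilt sequences.
* The GP uses dense exact inference; it is comfortable at the study's
  1200 samples but not designed for orders of magnitude more.
* Subject-independent (leave-one-subject-out) validation is out of
  scope, matching the source study's own caveat.
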