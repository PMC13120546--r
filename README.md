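# srwalker

Gait symmetry, neuromuscular and stability analytics for
sensor-instrumented rehabilitation walkers.

Instrumented walkers record bilateral handlebar forces (FSR sensors
through a 10-bit ADC), surface EMG of an arm muscle, and tri-axial frame
acceleration while a patient walks, and cue the patient with vibrotactile
feedback when loading becomes one-sided.  `srwalker` implements the full
analytical chain for such a device, aimed at rehabilitation researchers
and biomedical engineers who need the analytics reproducible and testable
without access to patient recordings:

* **Force symmetry** — the Robinson symmetry index
  `FSI = |F_R − F_L| / (F_R + F_L)` (0 = perfect symmetry, 1 = total
  asymmetry), per-day trajectories, percentage improvement, cohort
  summary tables, ADC-to-force calibration.
* **Closed-loop haptic feedback** — mean-asymmetry threshold
  calibration and a simulator that emits vibration events on the heavier
  side with a per-side refractory window and a latency contract.
* **Walker instability detection** — tilt from gravity-isolated
  tri-axial acceleration, upright / inclined / falling classification
  with a free-fall override, debounced alerts.
* **sEMG pipeline** — zero-phase Butterworth band-pass (30–500 Hz),
  db4 wavelet denoising (universal soft threshold), rectified amplitude
  metrics, paired Day-1 vs Day-15 t-test, Q–Q normality pairs.
* **Gaussian Process Regression** — from-scratch exact GP with RBF
  kernel `k(x,x′) = σ_f² exp(−(x−x′)²/2ℓ²)`, constant mean and noise
  `σ_n²`; hyperparameters by multi-start gradient ascent of the log
  marginal likelihood; predictive means with 95 % bands; chronological
  80/20 holdout and blocked 5-fold cross-validation.
* **Stride variability** — gait-cycle segmentation by prominence-based
  peak detection with transient filtering, stride-time variance, and a
  median-centred Levene comparison of ALS-like versus control gait.
* **Synthetic cohort generator** — seeded multimodal streams calibrated
  to the published ten-subject, 15-day pilot cohort, so every stage runs
  and is tested offline.

## Worked example

```r
library(srwalker)

# published per-subject FSI endpoints -> cohort summary table
cs <- cohort_summary(pilot_cohort_fsi()[, c("subject_id", "day1", "day15")])
print(cs)

# one synthetic session and its analytics
cfg <- default_cohort(seed = 1)
s1  <- generate_force_pair(cfg$subjects[[1]], day = 1, config = cfg)
session_fsi(s1)
nrow(run_feedback(s1, default_asymmetry_threshold()))

# trajectory model: 1200-point pooled cohort series, chronological 80/20
traj <- cohort_force_trajectory(cfg)
rep  <- gp_trajectory_report(traj, n_restarts = 2, seed = 1)
rep$fsr1$holdout
```

Output:

```
Cohort FSI summary (10 subjects)
 subject_id   day1  day15 improvement_pct
  Subject 1 0.9526 0.1530          83.94%
  Subject 2 0.9800 0.1129          88.48%
  Subject 3 0.9721 0.1877          80.69%
  Subject 4 0.9890 0.1905          80.74%
  Subject 5 0.9390 0.1171          87.53%
  Subject 6 0.9890 0.4489          54.61%
  Subject 7 0.9890 0.4116          58.38%
  Subject 8 0.9890 0.1157          88.30%
  Subject 9 0.9962 0.1183          88.12%
 Subject 10 0.8949 0.1630          81.79%
Mean:  Day 1 0.9691   Day 15 0.2019   Improvement 79.26%

Session FSI, Subject 1, Day 1: 0.9529
Haptic events in the session: 265 (threshold 0.247)
GPR holdout: FSR1 R^2 = 0.988 (RMSE 0.058 N), FSR2 R^2 = 0.978 (RMSE 0.077 N)
```

The summary table reads: Subject 1 started the program loading the
handles almost entirely one-sided (FSI 0.9526) and ended near symmetry
(0.1530), an 83.94 % reduction; across the cohort the index fell from
0.9691 to 0.2019, a 79.26 % mean improvement.  The Day-1 session of the
seeded synthetic cohort measures FSI 0.9529 (target 0.9526 plus sensor
noise) and triggers 265 vibration pulses at the calibrated threshold.
The trajectory GP predicts the held-out final fifth of the pooled force
series with R² ≈ 0.98 per channel.

A full end-to-end run (simulate → analyse → model → report) is one call:

```r
report <- run_pipeline(run_config(master_seed = 1, output_dir = "runs/demo"))
print(report)
```

or from a shell via the thin front-end
`Rscript inst/cli/srwalker.R run-all --seed 1 --out runs/demo`.

## Package layout

```
R/                 implementation (generator, symmetry, feedback, fall,
                   sEMG + wavelet engine, GPR, stride, pipeline)
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (models, parameters, design choices)
scripts/           acceptance script
inst/cli/          command-line front-end
```
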