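# radarecg

Reconstructing ECG waveforms from millimeter-wave radar measurements of
chest-wall motion, end to end and entirely on synthetic data.

Continuous-wave Doppler radar senses the sub-millimeter chest vibrations
produced by the beating heart. Because cardiac mechanical motion is coupled
to the heart's electrical activity (excitation–contraction coupling), the
radar-derived motion signal carries enough information to recover the ECG
waveform itself — P wave, QRS complex and T wave — without electrodes. This
package implements the full processing stack for that task, for researchers
in biomedical signal processing who want a reproducible, self-contained
test bed:

- **Simulation** — a physics-based quadrature radar model. Chest
  displacement `x(t)` (respiration + a damped 20 Hz cardiac ring at each
  R peak) phase-modulates balanced baseband channels
  `I(t) = A·cos(4πx/λ₀ + θ)`, `Q(t) = A·sin(4πx/λ₀ + θ)` at the 94 GHz /
  3 mm carrier, with Gaussian phase and channel noise. Ground-truth ECG
  comes from a five-Gaussian phase-domain model with AR(1)-correlated RR
  intervals, so every R-peak time is known exactly. Seven posture/breathing
  scenarios (sitting/lateral/supine; eupnea, apnea, hypoxic, rapid-shallow)
  with realistic dataset proportions.
- **Demodulation** — four-quadrant arctangent phase extraction, ±2π
  unwrapping, `x(t) = (λ₀/4π)(w(t) − θ)`.
- **Preprocessing** — respiratory suppression by MODWT (db4) with
  spectral-energy level selection, adaptive Kalman smoothing
  (innovation-driven noise covariance with forgetting), fifth-order
  polynomial ECG baseline removal, and MAD-calibrated wavelet
  soft-thresholding.
- **Model** — an encoder–decoder network written from scratch in
  vectorized R (no deep-learning framework): three parallel multi-scale
  CNN branches (receptive fields ≈ 0.1/0.25/0.5 s) alongside a lightweight
  multi-head self-attention encoder with a sigmoid-gated feed-forward
  stage; learned fusion; a causal dilated TCN decoder whose blocks carry
  *spectral attention* — an FFT-domain amplitude mask (1 inside
  0.5–40 Hz, 0.1 outside) multiplied by learned channel–frequency weights,
  recombined with the original phase. Trained with Adam, cosine-annealed
  learning rate, early stopping, and a per-segment RMSE loss
  `L = √(1/L Σ(ŷᵢ−yᵢ)²)`.
- **Evaluation** — Pearson correlation, RMSE, MAE; Q/R/S/T localization
  errors (median and 90th percentile) from a built-in
  Pan–Tompkins-style detector; per-scenario summaries and CDF tables.

Training and evaluation are strictly subject-disjoint (k-fold over
subjects), so reported metrics always refer to unseen subjects.

## Worked example

```r
library(radarecg)

ds <- generate_dataset(n_subjects = 6, n_segments = 60, seed = 1)
ds <- demodulate_dataset(ds)       # adds x_rec
ds <- preprocess_dataset(ds)       # adds x_card, ecg_clean

folds <- split_subject_kfold(unique(sapply(ds$segments, `[[`, "subject_id")),
                             k = 3, seed = 1)
fit <- train_fold(ds, folds[[1]],
                  train_config(epochs = 30, batch_size = 4, seed = 1),
                  desk_model_config())
te <- segment_matrices(ds, fit$test_ids)
report <- evaluate_reconstructions(predict_batches(fit$model, te$X),
                                   te$Y, te$scenarios)
report
```

```
eval_report: n = 20 (degenerate excluded: 0)
  PCC 0.8380  RMSE 0.5493  MAE 0.3775
 wave median  p90   n misses
    Q   0.01 0.02 243     18
    R   0.00 0.01 243     18
    S   0.01 0.02 243     18
    T   0.03 0.06 240     18
```

(A few minutes on one CPU core. `PCC` is the mean Pearson correlation
between reconstructed and true z-normalized ECG on the two held-out
subjects; the localization rows give median and 90th-percentile absolute
timing errors in seconds for each wave, with reference peaks that found no
match within ±0.15 s counted as misses. The desk-scale study in the test
suite — 8 subjects, 200 segments under the full seven-scenario mix,
30 epochs — lands at held-out PCC ≈ 0.8 with median R-peak error of
0.01 s; correlation is bounded by the channel-noise SNR of the
lowest-amplitude subjects, while beat timing stays accurate.)

A thin command-line wrapper is included at `inst/cli/radarecg.R`
(`simulate`, `demod`, `preprocess`, `train`, `evaluate`, `run`).

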