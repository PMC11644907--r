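# wheelbci

Motion-artifact correction and classification for wheelchair
motor-imagery EEG.

EEG recorded from a user driving a powered wheelchair is contaminated by
terrain-induced vibration that conventional ocular/EMG cleaning does not
remove. `wheelbci` implements an **empirical error model** that predicts
the artifact amplitude of a 5-s cue epoch from four physical inputs — the
accelerometer readings, the tire–surface friction coefficient µ, the
subject weight W, and the wheelchair weight U — and removes that amplitude
from the channel-averaged EEG before feature extraction and CNN
classification of RELAX / LEFT / RIGHT motor-imagery cues.

## The model in brief

All errors are per-epoch RMS differences between a motion recording and a
stationary artifact-minimised reference. For each modality *m* (three
accelerometer axes + the 8-channel EEG average) and each factor, the model
extrapolates from the reference condition by the physical ratio, e.g. for
surfaces:

    E_{m,sn} = (µ_s1 / µ_sn) · Wf_{m,s} · E_{m,s1} + Cf_{m,s}

with a fitted weight factor `Wf` (per-condition fits, averaged) and a
second-level correction factor `Cf` (mean residual on hold-out
conditions). Accelerometer axis errors combine as a Euclidean norm; the
overall error averages the three EEG factor terms and the normalized
accelerometer term:

    E = (E_sn + E_pn + E_wn + λ·Ea) / 4

The epoch's averaged EEG is then rescaled so its RMS drops by exactly `E`,
restored to 8 channels via per-channel RMS weights, cut into an 8 × 14
grid of Hjorth / statistical / wavelet / band-power features, and
classified by a small 2-D CNN (two tanh convolutions with batch norm, one
max-pool, dropout 0.5, dense-100, softmax; Adam 0.001/0.9/0.999). The CNN
and the Daubechies wavelet transform are implemented natively in the
package and are bit-reproducible from a seed.

Because the underlying wheelchair recordings are not redistributable, the
package includes a synthetic EEG+IMU generator with a fully known
multiplicative artifact law; every downstream stage is validated against
that ground truth.

## Worked example

```r
library(wheelbci)

cfg  <- synth_config(n_trials_per_class = 2, n_grid_trials = 1)
grid <- generate_condition_grid(cfg, seed = 50)      # 75 recordings + reference
params <- calibrate(grid$reference, grid$recordings)
print(params)
#> <error_model_params>
#>   weight factors:
#>         surface subject wheelchair
#> accel_x  1.0399  0.9895     1.0299
#> accel_y  1.0546  0.9877     1.0381
#> accel_z  1.0708  0.9842     1.0513
#> eeg_avg  1.1902  0.9577     1.1458
#>   correction factors:
#>         surface subject wheelchair
#> accel_x  0.0017  0.0001     0.0021
#> accel_y  0.0017  0.0000     0.0022
#> accel_z  0.0016  0.0001     0.0021
#> eeg_avg  1.0998  0.0688     1.3639
#>   accel->EEG normalization: 91.61
```

The generator's true weight factors here are all 1. The accelerometer
`Wf` come back within ~5 % with near-zero `Cf`; the EEG factors sit
within ~20 % because the class rhythms and background add signal power
the pure amplitude law does not model — that bias is exactly what the
second-level `Cf` absorbs on the hold-out conditions. (Calibrating on a
signal-free grid recovers every factor to 1e-6; the test suite does
this.) Predicting and removing the error for one epoch:

```r
rec   <- grid$recordings[[16]]                       # surface s2, baseline subject/chair
epoch <- segment_by_cues(rec)[[2]]                   # a LEFT cue
rms(epoch$ground_truth$eeg_artifact)                 # injected artifact
#> [1] 10.8
pred  <- predict_condition_error(params, epoch$meta)
round(pred$e_total, 2)
#> [1] 7.33
r1 <- reshape1(epoch$eeg)
corrected <- apply_correction(r1$avg, pred$e_total)
round(c(raw = rms(r1$avg), corrected = rms(corrected)), 2)
#>       raw corrected
#>     12.03      4.70
```

The epoch carries 10.8 µV of injected artifact; the model predicts a
total error of 7.33 µV (the four-way average in `E` mixes the
surface-driven excess with the reference-level factor terms, so
single-factor artifacts are deliberately under-predicted — see the
methods vignette) and the correction brings the averaged RMS from 12.0 µV
down to 4.7 µV, close to the clean-signal scale.
`run_pipeline()` chains segmentation, correction, feature grids, the
80:20 stratified split, CNN training and evaluation; `run_validation_case()`
reproduces the per-surface / per-wheelchair comparison cases (a–d) with
and without the empirical model.

A thin CLI wraps the same functions:

```sh
wheelbci simulate --out data/ --seed 1
wheelbci calibrate --dir data/ --out params.json
wheelbci case --id c --dir data/ --out case_c.json
```

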