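---
title: "Empirical error-model correction of wheelchair-motion EEG artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical error-model correction of wheelchair-motion EEG artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelbci)
```

## The problem

A brain–computer-interface wheelchair decodes motor-imagery EEG while the
chair is moving. Terrain-induced vibration contaminates the scalp
recordings far beyond what ocular/EMG cleaning methods handle, and the
contamination depends on physical parameters of the ride: the tire–surface
friction of the terrain, the subject's weight, and the wheelchair's weight.
`wheelbci` implements a pipeline that (1) calibrates an *empirical error
model* predicting the artifact amplitude from those parameters plus
accelerometer readings, (2) removes the predicted amplitude from the
channel-averaged EEG, and (3) classifies 5-s cue epochs
(RELAX / LEFT / RIGHT) with a compact 2-D convolutional network.

## The error model

All quantities are windowed RMS amplitudes of 5-s cue epochs, computed
about the window mean (DC components — gravity on the accelerometer z
axis, electrode drift — carry no motion information). The *error* of a
motion epoch is its RMS minus the RMS of the paired epoch of a stationary,
artifact-minimised reference recording. The two recordings are not
sample-synchronized, so a pointwise difference is undefined; the RMS
difference is the natural amplitude-domain analogue.

For each modality $m$ (three accelerometer axes and the averaged EEG) and
each factor (surface $s$, subject weight $p$, wheelchair weight $w$), the
model is anchored at the first condition (surface $s_1$, weight $W_1$,
chair $U_1$) and extrapolates by the physical ratio. For surfaces:

$$E_{m,s_n} = \frac{\mu_{s_1}}{\mu_{s_n}} \, W\!f_{m,s} \, E_{m,s_1} + C\!f_{m,s}$$

The *weight factor* $W\!f$ is fitted per non-reference condition as the
value making the ratio law exact, then averaged over conditions (this
averaged form is the general model). The *correction factor* $C\!f$ is a
second-level additive correction: the mean residual (measured − predicted)
on hold-out conditions — the last two surfaces, the last two subjects, and
both non-reference wheelchairs. By construction the mean hold-out residual
is zero after fitting.

Per-factor accelerometer errors are combined across axes with the
Euclidean norm, then averaged across the three factors into $E_a$. The
overall EEG error averages the three EEG factor predictions and $E_a$:

$$E = \tfrac14\!\left(E_{s_n} + E_{p_n} + E_{w_n} + \lambda E_a\right)$$

where $\lambda$ is a normalization constant (the ratio of the reference
EEG error in microvolts to the reference accelerometer error in g) that
makes the accelerometer term commensurable with the EEG terms before the
average — the quantities otherwise carry different units.

### Applying the correction

The model's output is an amplitude, so the correction is amplitude-domain:
the 8 channels are averaged into a single series (*Data Reshape 1*, which
also records per-channel RMS weights normalized to mean 1), the series is
rescaled so its RMS drops by exactly $E$ (identity when $E \le 0$, zero
floor when $E$ exceeds the series RMS), and the per-channel weights expand
the corrected series back to 8 channels (*Data Reshape 2*). The round trip
average → expand → average is exact because the weights have mean 1.

A per-epoch rescaling is deliberately conservative: it removes the
condition-dependent amplitude the model can actually predict and nothing
else. It cannot alter the spectral composition within an epoch — a
limitation discussed below.

## Features and classifier

Each epoch's (corrected) averaged series is cut into 8 half-overlapping
sub-windows; each sub-window yields 14 features: Hjorth mobility and
complexity, excess kurtosis, mean, max, coefficient of variation,
skewness, wavelet detail energy and entropy (level-4 periodized Daubechies
db4; the orthonormal transform conserves energy exactly, which the test
suite checks via Parseval), variance, and the maximum periodogram ordinate
in the delta (0.5–4), theta (4–8), alpha (8–13) and beta (13–30 Hz) bands
(unwindowed $|\mathrm{FFT}|^2/n$ of the linearly detrended window). A hook
can append `min` and `peak_to_peak` for a 16-feature variant. The
resulting 8 × 14 grids are column-standardized with training-set
statistics.

The default classifier (`LM-CNN`) is
Conv2D(3×3, 32, tanh) → BatchNorm → Conv2D(3×3, 64, tanh) → BatchNorm →
MaxPool(2×2) → Dropout(0.5) → Dense(100, ReLU) → Softmax(3),
trained with Adam (learning rate 0.001, $\beta_1 = 0.9$,
$\beta_2 = 0.999$). Three comparison stacks (`CNN2`–`CNN4`: ReLU
convolutions, selu dense layers of 100/256 units, no batch norm) are
available, and `grid_search_cv()` selects batch size and epoch count by
stratified k-fold cross-validation (ties go to the smaller batch, then
fewer epochs). The network is implemented natively in R with exact
seeded reproducibility: initialization, shuffling and dropout all derive
from one seed, and training twice with the same seed is bit-identical.
Kernel sizes and filter counts (3×3; 32 then 64) are the smallest
conventional stack that fits an 8 × 14 input. The dense activation follows
the ReLU description of the architecture prose; selu variants remain
configurable.

## The synthetic study

Real recordings of this kind are not redistributable, so the package ships
a generator whose defaults define the simulated study:

* **Protocol**: 5-s cues at 250 Hz (the sampling rate of the 8-channel
  Cyton-class board the format emulates), RELAX interleaved between
  LEFT/RIGHT imagery cues; montage Fp1, Fp2, F3, F4, C3, C4, P3, P4.
* **Background EEG**: band-limited (1–40 Hz) Gaussian noise, 10 µV RMS per
  channel, independent across channels.
* **Class signatures**: event-related modulation as mu (10 Hz) and beta
  (20 Hz) components over C3/C4, lateralized by class, with graded
  amplitudes — RELAX (2, 1 µV), LEFT (16, 4 µV), RIGHT (20, 12 µV).
  Classes therefore differ both spectrally and in overall amplitude, as
  ERD/ERS does; pure equal-amplitude spectral lines would carry no
  amplitude information at all and make amplitude-domain correction
  meaningless.
* **Artifact**: one band-limited (0.5–30 Hz) vibration waveform per
  recording, added common-mode to all 8 EEG channels and (scaled) to the
  three accelerometer axes, so the accelerometer is genuinely informative
  about the EEG artifact. Broadband, rather than low-frequency-only,
  because electrode-motion artifacts contaminate the delta-through-beta
  range. Within every cue window the artifact segment is rescaled to its
  exact target RMS, making the amplitude law hold deterministically —
  parameter recovery at zero background noise is then exact rather than
  Monte-Carlo.
* **Amplitude law**: artifact RMS = base × ratio-law per factor
  (friction ratio × $W\!f$, weight ratios likewise; factor 1 at the
  reference level). Default base: 9 µV EEG / 0.05 g accelerometer — about
  twice the class-signal RMS of the averaged channel, a heavily
  contaminated regime. The stationary reference recording carries no
  vibration artifact.
* **Condition tables**: friction 0.90/0.75/0.60/0.45/0.35 for
  marble/road/brick/carpet/concrete (plausible tire–surface coefficients;
  the reference surface is the high-friction, low-vibration one), subject
  weights 73.9/81/85/82/78.3 kg, wheelchair weights 80/90/25 kg. The full
  design — 5 surfaces × 5 subjects × 3 wheelchairs × 3 trials — yields 225
  motion recordings plus the reference.

Everything the generator injects is returned as ground truth, so
calibration accuracy is measurable, not assumed.

### What the generator does not emulate

No ocular or myogenic artifacts, no 1/f spectral background, no
non-stationarity within a session, no electrode-specific artifact gains,
and no biomechanical coupling between terrain profile and head motion.
Passing tests demonstrate internal consistency of the method under its own
assumptions — a multiplicative amplitude law and a common-mode artifact —
not performance on real wheelchair EEG.

## Numerical choices and degenerate inputs

* RMS everywhere is about the window mean; `apply_correction` floors at
  the zero series when the predicted error exceeds the signal RMS.
* An all-zero reshape window gets unit channel weights and a degeneracy
  flag; constant series make Hjorth and skewness/kurtosis error out by
  name rather than emit NaN; a zero-mean window reports CV = 0 with a
  flag instead of infinity.
* The db4 transform truncates each window to a multiple of $2^{4}$
  samples; band powers require every band to contain at least one
  frequency bin (about 72 samples at 250 Hz), which an 8-sub-window split
  of a 5-s epoch satisfies comfortably.
* Negative measured errors (motion quieter than reference) are retained in
  calibration; clipping happens only at correction time.
* Hold-out sets, the `wf_conditions` averaging mode, band edges, wavelet
  depth and the feature-grid geometry are all arguments, not constants.

## Sizes used in validation

The test suite and the acceptance script exercise the pipeline at sizes a
laptop handles comfortably: calibration grids of 75–150 recordings with
short (4–8 cue) sessions, classification runs of 640 epochs (5 surfaces ×
16 recordings × 8 cues), and a 200-sample separable set for the classifier
overfit check. These sizes were chosen to keep the full validation run in
minutes while leaving every statistical check well-powered.

## Known limitations

The per-epoch scalar correction preserves, per condition, all information
in the data (it is an invertible rescaling given the condition), so its
benefit to a downstream classifier comes entirely from homogenizing
amplitude across conditions, not from denoising within an epoch. Two
consequences are worth knowing. First, spectral class information masked
by in-band artifact power is not recoverable by this correction. Second,
the four-way average in the overall error $E$ mixes the active factor's
prediction with the (smaller) predictions of factors sitting at their
reference levels, so when a single factor drives the artifact the model
deliberately under-predicts the excess — the correction removes a
condition-tracking but diluted amount. On synthetic data this makes the
corrected and uncorrected pipelines perform within a few accuracy points
of each other rather than showing the large gains reported on real
recordings, where artifact amplitude fluctuates far more than the clean
signal. Regression-style corrections that exploit the accelerometer
waveform itself (not just its RMS) are the natural extension and are out
of scope here.

Cross-subject generalization is untested by design: the default split is
stratified at the epoch level, and a subject-level split is available but
not the default.
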