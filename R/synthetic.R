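#' Configuration of the synthetic EEG + IMU generator
#'
#' Defines the simulated study: cue protocol, EEG background, per-class
#' mu/beta signatures, the motion-artifact amplitude law, and the condition
#' tables (surface friction, subject weights, wheelchair weights).
#'
#' The artifact obeys a multiplicative law: in a condition with friction
#' `mu`, subject weight `W` and wheelchair weight `U`, the per-epoch artifact
#' RMS is `base * f_s * f_p * f_w` where `f_s = (mu1/mu) * Wf_s` (1 when the
#' condition sits at the reference level `mu1`), and analogously for the
#' subject (`W1/W`) and wheelchair (`U1/U`) factors. The stationary
#' reference recording contains no vibration artifact at all.
#'
#' Friction defaults are plausible tire-surface coefficients (marble is the
#' high-friction, low-vibration reference); subject weights follow a typical
#' adult cohort and wheelchair weights a powered-chair fleet (80, 90, 25 kg).
#' The vibration band (0.5-30 Hz) reflects the broadband character of
#' electrode-motion artifacts, which contaminate the delta through beta
#' range rather than low frequencies alone. Default class signatures model
#' event-related synchronisation as graded mu/beta amplitude over the motor
#' channels (RELAX weak, LEFT mu-dominant, RIGHT strongest with a beta
#' emphasis), and the default artifact base RMS (9 microvolts) puts the
#' artifact at roughly twice the class-signal RMS of the channel-averaged
#' series -- a heavily contaminated but not hopeless regime.
#'
#' @param fs Sampling rate, Hz.
#' @param n_trials_per_class Imagery cues per class per recording; each is
#'   preceded by a RELAX cue, so a recording holds `4*n` 5-s cues.
#' @param class_labels Cue labels; RELAX plus the imagery classes.
#' @param background_band EEG background band (Hz).
#' @param class_signatures Named list: per label, `c(mu = , beta = )`
#'   amplitudes in microvolts of the 10 Hz mu and 20 Hz beta components
#'   added over the motor channels C3/C4.
#' @param artifact_base_rms Named list `list(eeg = , accel = )`: artifact
#'   RMS at the reference condition, in microvolts and g.
#' @param true_weight_factors Named vector `c(surface=, subject=, wheelchair=)`
#'   of ground-truth weight factors applied off-reference.
#' @param friction_table Named friction coefficients, first entry = reference.
#' @param subject_weights Named subject weights (kg), first = reference.
#' @param wheelchair_weights Named wheelchair weights (kg), first = reference.
#' @param noise_rms Per-channel EEG background RMS (microvolts).
#' @param accel_noise_rms Accelerometer sensor-noise RMS (g).
#' @param artifact_band Artifact/vibration band (Hz).
#' @param n_grid_trials Trials per condition cell in
#'   [generate_condition_grid()].
#' @param seed Base seed for the generator.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 250,
                         n_trials_per_class = 4,
                         class_labels = c("RELAX", "LEFT", "RIGHT"),
                         background_band = c(1, 40),
                         class_signatures = list(
                           RELAX = c(mu = 2, beta = 1),
                           LEFT  = c(mu = 16, beta = 4),
                           RIGHT = c(mu = 20, beta = 12)),
                         artifact_base_rms = list(eeg = 9, accel = 0.05),
                         true_weight_factors = c(surface = 1, subject = 1,
                                                 wheelchair = 1),
                         friction_table = c(s1 = 0.9, s2 = 0.75, s3 = 0.6,
                                            s4 = 0.45, s5 = 0.35),
                         subject_weights = c(w1 = 73.9, w2 = 81, w3 = 85,
                                             w4 = 82, w5 = 78.3),
                         wheelchair_weights = c(u1 = 80, u2 = 90, u3 = 25),
                         noise_rms = 10,
                         accel_noise_rms = 0.005,
                         artifact_band = c(0.5, 30),
                         n_grid_trials = 3,
                         seed = 1L) {
  if (artifact_base_rms$eeg < 0 || artifact_base_rms$accel < 0 ||
      noise_rms < 0 || accel_noise_rms < 0) {
    stopf("rms/amplitude values must be >= 0")
  }
  miss <- setdiff(class_labels, names(class_signatures))
  if (length(miss)) stopf("class_signatures missing label(s): %s",
                          paste(miss, collapse = ", "))
  if (any(true_weight_factors <= 0)) stopf("true weight factors must be > 0")
  structure(
    list(fs = fs, n_trials_per_class = n_trials_per_class,
         class_labels = class_labels, background_band = background_band,
         class_signatures = class_signatures,
         artifact_base_rms = artifact_base_rms,
         true_weight_factors = true_weight_factors,
         friction_table = friction_table,
         subject_weights = subject_weights,
         wheelchair_weights = wheelchair_weights,
         noise_rms = noise_rms, accel_noise_rms = accel_noise_rms,
         artifact_band = artifact_band, n_grid_trials = n_grid_trials,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# band-limited Gaussian noise via FFT masking, unit variance target pre-scaling
band_noise <- function(n, fs, lo, hi) {
  if (n < 4L) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)               # two-sided frequency axis
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# zero-mean, exact-RMS scaling of a segment
scale_to_rms <- function(x, target) {
  x <- x - mean(x)
  r <- sqrt(mean(x^2))
  if (r == 0 || target == 0) return(x * 0)
  x * (target / r)
}

#' Artifact multiplier for a motion condition
#'
#' Product of the three per-factor terms of the generator's amplitude law;
#' each term is 1 at the factor's reference level. Returns 0 for the
#' stationary reference recording (no motion, no vibration).
#'
#' @param cfg A [synth_config()].
#' @param condition A [recording_meta()].
#' @return Scalar multiplier applied to `artifact_base_rms`.
#' @export
artifact_multiplier <- function(cfg, condition) {
  if (condition$is_reference) return(0)
  wf <- cfg$true_weight_factors
  f_s <- if (condition$surface_id == names(cfg$friction_table)[1]) 1 else
    (cfg$friction_table[[1]] / condition$friction) * wf[["surface"]]
  f_p <- if (condition$subject_weight == cfg$subject_weights[[1]]) 1 else
    (cfg$subject_weights[[1]] / condition$subject_weight) * wf[["subject"]]
  f_w <- if (condition$wheelchair_weight == cfg$wheelchair_weights[[1]]) 1 else
    (cfg$wheelchair_weights[[1]] / condition$wheelchair_weight) * wf[["wheelchair"]]
  f_s * f_p * f_w
}

default_schedule <- function(cfg) {
  imagery <- setdiff(cfg$class_labels, "RELAX")
  pat <- unlist(lapply(imagery, function(l) c("RELAX", l)))
  cue_schedule(rep(pat, cfg$n_trials_per_class))
}

#' Generate one synthetic recording
#'
#' EEG = band-limited background + per-cue class signature (mu/beta
#' sinusoids over C3/C4, random phase per cue) + a common-mode motion
#' artifact; accelerometer = gravity baseline + sensor noise + the same
#' vibration waveform. Inside every cue window the artifact segment is
#' scaled to its exact target RMS, `artifact_base_rms * artifact_multiplier`,
#' so the injected amplitude law holds deterministically. The injected
#' artifact series and the true weight factors are returned as
#' `ground_truth` on the recording.
#'
#' @param cfg A [synth_config()].
#' @param condition A [recording_meta()]; its `surface_id` must be in
#'   `cfg$friction_table` (or carry an explicit friction).
#' @param seed Integer seed; identical seed + config + condition gives a
#'   bit-identical recording.
#' @param cues Optional [cue_schedule()]; default built from `cfg`.
#' @return A [bci_recording()] with a `ground_truth` list.
#' @export
generate_recording <- function(cfg, condition, seed = cfg$seed,
                               cues = default_schedule(cfg)) {
  stopifnot(inherits(cfg, "synth_config"), inherits(condition, "recording_meta"))
  if (!condition$is_reference &&
      !condition$surface_id %in% names(cfg$friction_table)) {
    stopf("unknown surface_id '%s'", condition$surface_id)
  }
  if (nrow(cues) == 0L) stopf("empty cue schedule")
  fs <- cfg$fs
  n <- round(max(cues$start_s + cues$duration_s) * fs)
  mult <- artifact_multiplier(cfg, condition)
  t_eeg <- cfg$artifact_base_rms$eeg * mult
  t_acc <- cfg$artifact_base_rms$accel * mult
  axis_gain <- c(ax = 1, ay = 0.8, az = 0.6)  # vibration couples unevenly

  with_seed(seed, {
    eeg <- matrix(0, 8L, n, dimnames = list(default_montage(), NULL))
    if (cfg$noise_rms > 0) {
      for (c_ in 1:8) {
        eeg[c_, ] <- scale_to_rms(
          band_noise(n, fs, cfg$background_band[1], cfg$background_band[2]),
          cfg$noise_rms)
      }
    }
    accel <- matrix(0, 3L, n, dimnames = list(c("ax", "ay", "az"), NULL))
    accel["az", ] <- 1                         # gravity, g
    if (cfg$accel_noise_rms > 0) {
      for (a_ in 1:3) {
        accel[a_, ] <- accel[a_, ] + stats::rnorm(n, sd = cfg$accel_noise_rms)
      }
    }

    # per-cue class signatures over the motor channels
    tt <- seq_len(n) / fs
    iC3 <- match("C3", default_montage()); iC4 <- match("C4", default_montage())
    for (i in seq_len(nrow(cues))) {
      a <- round(cues$start_s[i] * fs) + 1L
      b <- a + round(cues$duration_s[i] * fs) - 1L
      sig <- cfg$class_signatures[[cues$label[i]]]
      if (is.null(sig) || all(sig == 0)) next
      ph <- stats::runif(2, 0, 2 * pi)
      w <- switch(cues$label[i],
                  LEFT  = c(C3 = 0.4, C4 = 1.6),
                  RIGHT = c(C3 = 1.6, C4 = 0.4),
                  c(C3 = 1, C4 = 1))
      osc <- sig[["mu"]] * sin(2 * pi * 10 * tt[a:b] + ph[1]) +
             sig[["beta"]] * sin(2 * pi * 20 * tt[a:b] + ph[2])
      eeg[iC3, a:b] <- eeg[iC3, a:b] + w[["C3"]] * osc
      eeg[iC4, a:b] <- eeg[iC4, a:b] + w[["C4"]] * osc
    }

    # common-mode vibration artifact, exact RMS per cue window
    art <- numeric(n)
    if (mult > 0 && (t_eeg > 0 || t_acc > 0)) {
      v <- band_noise(n, fs, cfg$artifact_band[1], cfg$artifact_band[2])
      for (i in seq_len(nrow(cues))) {
        a <- round(cues$start_s[i] * fs) + 1L
        b <- a + round(cues$duration_s[i] * fs) - 1L
        art[a:b] <- scale_to_rms(v[a:b], 1)   # unit RMS within the window
      }
    }
    eeg_art <- t_eeg * art
    eeg <- eeg + matrix(eeg_art, 8L, n, byrow = TRUE)
    acc_art <- outer(axis_gain * t_acc, art)
    accel <- accel + acc_art

    bci_recording(
      eeg, accel, fs = fs, cues = cues, meta = condition,
      ground_truth = list(
        eeg_artifact = eeg_art,
        accel_artifact = acc_art,
        true_weight_factors = cfg$true_weight_factors,
        artifact_multiplier = mult,
        target_rms = list(eeg = t_eeg, accel = axis_gain * t_acc)
      )
    )
  })
}

#' Generate the full condition grid plus the stationary reference
#'
#' One stationary reference recording plus one motion recording per
#' (surface, subject, wheelchair, trial) cell. With the default tables
#' (5 surfaces, 5 subjects, 3 wheelchairs, 3 trials) this yields 225 motion
#' recordings. Ground truth (true weight factors and per-cell artifact
#' multipliers) is bundled with the output.
#'
#' @param cfg A [synth_config()].
#' @param seed Base seed; each cell uses a distinct derived seed.
#' @return A list with `reference` (a [bci_recording()]), `recordings`
#'   (list of motion recordings) and `ground_truth`.
#' @export
generate_condition_grid <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!length(cfg$friction_table) || !length(cfg$subject_weights) ||
      !length(cfg$wheelchair_weights)) {
    stopf("grid needs at least one surface, subject and wheelchair")
  }
  ref_meta <- recording_meta(
    subject_weight = cfg$subject_weights[[1]],
    wheelchair_weight = cfg$wheelchair_weights[[1]],
    surface_id = names(cfg$friction_table)[1],
    friction = cfg$friction_table[[1]],
    wheelchair_id = names(cfg$wheelchair_weights)[1],
    subject_id = names(cfg$subject_weights)[1],
    is_reference = TRUE
  )
  reference <- generate_recording(cfg, ref_meta, seed = seed)
  recs <- list()
  mults <- numeric(0)
  k <- 0L
  for (s in names(cfg$friction_table)) {
    for (p in names(cfg$subject_weights)) {
      for (u in names(cfg$wheelchair_weights)) {
        for (tr in seq_len(cfg$n_grid_trials)) {
          k <- k + 1L
          meta <- recording_meta(
            subject_weight = cfg$subject_weights[[p]],
            wheelchair_weight = cfg$wheelchair_weights[[u]],
            surface_id = s, friction = cfg$friction_table[[s]],
            wheelchair_id = u, subject_id = p, is_reference = FALSE
          )
          recs[[k]] <- generate_recording(cfg, meta, seed = seed + k)
          mults[k] <- artifact_multiplier(cfg, meta)
        }
      }
    }
  }
  list(reference = reference, recordings = recs,
       ground_truth = list(true_weight_factors = cfg$true_weight_factors,
                           artifact_multipliers = mults))
}
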