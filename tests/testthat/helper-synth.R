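# shared fixtures built in code

test_montage <- function() c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4")

# quick epoch around a given 8 x n EEG window (zero accel unless given)
make_epoch <- function(eeg, fs = 250, label = "RELAX", accel = NULL,
                       meta = NULL, is_reference = FALSE) {
  n <- ncol(eeg)
  if (is.null(accel)) accel <- matrix(0, 3, n)
  if (is.null(meta)) {
    meta <- recording_meta(73.9, 80, "s1", 0.9, "u1", "w1",
                           is_reference = is_reference)
  }
  bci_epoch(eeg, accel, label = label, fs = fs, meta = meta)
}

# seeded random recording for IO round trips
random_recording <- function(seed = 1, n_cues = 3, fs = 250) {
  set.seed(seed)
  cues <- cue_schedule(rep(c("RELAX", "LEFT", "RELAX"), length.out = n_cues))
  n <- round(sum(cues$duration_s) * fs)
  bci_recording(matrix(rnorm(8 * n, sd = 10), 8, n),
                matrix(rnorm(3 * n, sd = 0.02), 3, n),
                fs = fs, cues = cues,
                meta = recording_meta(81, 90, "s2", 0.75, "u2", "w2"))
}

# small zero-noise config for exact calibration checks
calib_config <- function(wf = c(surface = 1, subject = 1, wheelchair = 1),
                         noise_rms = 0, n_trials_per_class = 1) {
  synth_config(
    n_trials_per_class = n_trials_per_class,
    noise_rms = noise_rms, accel_noise_rms = 0,
    class_signatures = list(RELAX = c(mu = 0, beta = 0),
                            LEFT = c(mu = 0, beta = 0),
                            RIGHT = c(mu = 0, beta = 0)),
    true_weight_factors = wf,
    n_grid_trials = 1
  )
}

# separable toy feature grids for classifier tests
separable_grids <- function(n, shape = c(8, 14), sd = 0.5, shift = 3,
                            classes = c("RELAX", "LEFT", "RIGHT"),
                            seed = 0) {
  set.seed(seed)
  lapply(rep(classes, length.out = n), function(cl) {
    m <- matrix(rnorm(prod(shape), sd = sd), shape[1], shape[2])
    m[, match(cl, classes)] <- m[, match(cl, classes)] + shift
    structure(m, label = cl)
  })
}
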