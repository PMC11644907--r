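#' Default electrode montage
#'
#' The 8-channel montage used throughout: frontal-polar, frontal, central and
#' parietal pairs. C3/C4 sit over the hand motor areas and carry the
#' mu/beta modulation that motor imagery classification relies on.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4")
}

#' Per-recording metadata
#'
#' Describes the motion condition a recording was collected under: the
#' subject's weight `W` (kg), the wheelchair's weight `U` (kg), the terrain
#' and its tire-surface friction coefficient `mu`, and whether the recording
#' is the stationary artifact-minimised reference.
#'
#' @param subject_weight Subject weight in kg (> 0).
#' @param wheelchair_weight Wheelchair weight in kg (> 0).
#' @param surface_id Surface identifier, e.g. `"s1"`.
#' @param friction Dimensionless tire-surface friction coefficient (> 0).
#' @param wheelchair_id Wheelchair identifier, e.g. `"u1"`.
#' @param subject_id Subject identifier, e.g. `"w1"`.
#' @param is_reference `TRUE` for the stationary baseline recording.
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(subject_weight, wheelchair_weight,
                           surface_id = "s1", friction = 0.9,
                           wheelchair_id = "u1", subject_id = "w1",
                           is_reference = FALSE) {
  if (subject_weight <= 0) stopf("subject_weight must be > 0")
  if (wheelchair_weight <= 0) stopf("wheelchair_weight must be > 0")
  if (friction <= 0) stopf("friction must be > 0")
  structure(
    list(subject_weight = subject_weight,
         wheelchair_weight = wheelchair_weight,
         surface_id = surface_id, friction = friction,
         wheelchair_id = wheelchair_id, subject_id = subject_id,
         is_reference = isTRUE(is_reference)),
    class = "recording_meta"
  )
}

#' Cue schedule
#'
#' An ordered, non-overlapping sequence of visual cues. Each cue is shown
#' for 5 s by default; LEFT/RIGHT imagery cues must be separated by a RELAX
#' cue, mirroring the recording protocol.
#'
#' @param labels Character vector of cue labels (`RELAX`, `LEFT`, `RIGHT`).
#' @param start_s Onset times in seconds; defaults to back-to-back cues.
#' @param duration_s Cue durations in seconds (recycled), default 5.
#' @return A `cue_schedule` data frame with columns label/start_s/duration_s.
#' @export
cue_schedule <- function(labels, start_s = NULL, duration_s = 5) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0L) stopf("cue schedule needs at least one entry")
  bad <- setdiff(labels, c("RELAX", "LEFT", "RIGHT"))
  if (length(bad)) stopf("unknown cue label(s): %s", paste(bad, collapse = ", "))
  duration_s <- rep_len(duration_s, n)
  if (is.null(start_s)) start_s <- cumsum(c(0, duration_s[-n]))
  if (length(start_s) != n) stopf("start_s must match labels in length")
  o <- order(start_s)
  labels <- labels[o]; start_s <- start_s[o]; duration_s <- duration_s[o]
  if (n > 1L && any(start_s[-1] < (start_s + duration_s)[-n] - 1e-9)) {
    stopf("cue entries overlap")
  }
  # protocol: consecutive imagery cues are separated by RELAX
  img <- labels %in% c("LEFT", "RIGHT")
  if (any(img[-1] & img[-n])) {
    stopf("LEFT/RIGHT cues must be separated by a RELAX cue")
  }
  structure(
    data.frame(label = labels, start_s = start_s, duration_s = duration_s,
               stringsAsFactors = FALSE),
    class = c("cue_schedule", "data.frame")
  )
}

#' Synchronized EEG + accelerometer recording
#'
#' Container for one session: 8 EEG channels (microvolts) and 3 accelerometer
#' axes (g) sampled at a common rate, with the cue schedule and condition
#' metadata.
#'
#' @param eeg 8 x n numeric matrix, microvolts, rows in montage order.
#' @param accel 3 x n numeric matrix, g, rows ax/ay/az.
#' @param fs Sampling rate in Hz (> 0).
#' @param cues A [cue_schedule()].
#' @param meta A [recording_meta()].
#' @param channel_names Montage labels; must equal `default_montage()` in
#'   order unless overridden consistently.
#' @param ground_truth Optional list attached by the synthetic generator
#'   (injected artifact series and true weight factors); `NULL` for real data.
#' @return An object of class `bci_recording`.
#' @export
bci_recording <- function(eeg, accel, fs, cues, meta,
                          channel_names = default_montage(),
                          ground_truth = NULL) {
  eeg <- as.matrix(eeg); accel <- as.matrix(accel)
  if (nrow(eeg) != 8L) stopf("eeg must have exactly 8 rows, got %d", nrow(eeg))
  if (nrow(accel) != 3L) stopf("accel must have exactly 3 rows, got %d", nrow(accel))
  if (ncol(eeg) != ncol(accel)) {
    stopf("eeg (%d) and accel (%d) sample counts differ", ncol(eeg), ncol(accel))
  }
  if (length(channel_names) != 8L) stopf("channel_names must have 8 entries")
  if (fs <= 0) stopf("fs must be > 0")
  if (ncol(eeg) > 0L) {
    assert_finite(eeg, "eeg"); assert_finite(accel, "accel")
  }
  if (!inherits(cues, "cue_schedule")) stopf("cues must be a cue_schedule")
  if (!inherits(meta, "recording_meta")) stopf("meta must be a recording_meta")
  rownames(eeg) <- channel_names
  rownames(accel) <- c("ax", "ay", "az")
  structure(
    list(eeg = eeg, accel = accel, fs = fs, cues = cues, meta = meta,
         channel_names = channel_names, ground_truth = ground_truth),
    class = "bci_recording"
  )
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d samples @ %g Hz (%.1f s), %d cues\n",
              ncol(x$eeg), x$fs, ncol(x$eeg) / x$fs, nrow(x$cues)))
  cat(sprintf("  condition: surface %s (mu=%.3g), subject %.1f kg, chair %.1f kg%s\n",
              x$meta$surface_id, x$meta$friction, x$meta$subject_weight,
              x$meta$wheelchair_weight,
              if (x$meta$is_reference) " [reference]" else ""))
  invisible(x)
}

#' One cue-aligned 5-s epoch
#'
#' @param eeg 8 x n EEG window (microvolts).
#' @param accel 3 x n accelerometer window (g).
#' @param label Cue label of the epoch.
#' @param fs Sampling rate (Hz).
#' @param meta The parent recording's [recording_meta()].
#' @param ground_truth Optional per-epoch ground truth from the generator.
#' @return An object of class `bci_epoch`.
#' @export
bci_epoch <- function(eeg, accel, label, fs, meta, ground_truth = NULL) {
  eeg <- as.matrix(eeg); accel <- as.matrix(accel)
  if (nrow(eeg) != 8L || nrow(accel) != 3L || ncol(eeg) != ncol(accel)) {
    stopf("epoch needs an 8 x n eeg and 3 x n accel window")
  }
  if (is.null(rownames(eeg))) rownames(eeg) <- default_montage()
  if (is.null(rownames(accel))) rownames(accel) <- c("ax", "ay", "az")
  structure(
    list(eeg = eeg, accel = accel, label = label, fs = fs, meta = meta,
         ground_truth = ground_truth),
    class = "bci_epoch"
  )
}

#' @export
print.bci_epoch <- function(x, ...) {
  cat(sprintf("<bci_epoch> label %s, %d samples @ %g Hz\n",
              x$label, ncol(x$eeg), x$fs))
  invisible(x)
}
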