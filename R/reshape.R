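#' Data Reshape 1: collapse 8 EEG channels to one averaged series
#'
#' Averages the 8 channels sample-by-sample into the single series `E_avg`
#' that the error model operates on, and records per-channel weights so the
#' single corrected series can later be expanded back to 8 channels
#' ([reshape2()]). The weight of channel c is its RMS amplitude divided by
#' the mean RMS over channels, so `mean(weights) == 1` by construction and
#' the round trip average-restore-average is exact.
#'
#' For an all-zero window every channel weight is defined as 1 and the
#' result is flagged (`degenerate = TRUE`).
#'
#' @param eeg 8 x n numeric matrix (n >= 2), finite.
#' @return A list with `avg` (length-n series), `weights` (class
#'   `channel_weights`: 8 values, mean 1) and `degenerate` flag.
#' @export
reshape1 <- function(eeg) {
  eeg <- as.matrix(eeg)
  if (nrow(eeg) != 8L) stopf("reshape1 expects an 8 x n window")
  if (ncol(eeg) < 2L) stopf("reshape1 needs at least 2 samples")
  assert_finite(eeg, "eeg window")
  avg <- colMeans(eeg)
  ch_rms <- sqrt(rowMeans(eeg^2))     # amplitude share, not demeaned
  degenerate <- all(ch_rms == 0)
  if (degenerate) {
    w <- rep(1, 8L)
  } else {
    w <- ch_rms / mean(ch_rms)
  }
  names(w) <- rownames(eeg)
  list(avg = avg,
       weights = structure(w, class = "channel_weights"),
       degenerate = degenerate)
}

#' Data Reshape 2: restore a single series to 8 channels
#'
#' Multiplies the corrected single-channel series by each channel weight:
#' `out[c, t] = weights[c] * corrected[t]`. Because the weights have mean 1,
#' the channel mean of the output equals the input series exactly.
#'
#' @param corrected Length-n numeric series.
#' @param weights A `channel_weights` object from [reshape1()] (8 values,
#'   mean 1, all >= 0).
#' @return An 8 x n matrix.
#' @export
reshape2 <- function(corrected, weights) {
  w <- as.numeric(weights)
  if (length(w) != 8L) stopf("shape error: weights must have 8 entries")
  if (any(w < 0)) stopf("channel weights must be >= 0")
  if (abs(mean(w) - 1) > 1e-9) stopf("channel weights must have mean 1")
  if (!is.numeric(corrected) || length(corrected) < 1L) {
    stopf("shape error: corrected must be a non-empty numeric series")
  }
  out <- outer(w, as.numeric(corrected))
  rownames(out) <- names(weights)
  out
}
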