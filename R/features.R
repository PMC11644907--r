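#' Names and order of the per-window feature vector
#'
#' The canonical 14 features, in the fixed order used throughout: Hjorth
#' mobility and complexity, excess kurtosis, mean, max, coefficient of
#' variation, skewness, wavelet detail energy and entropy, variance, and the
#' maximum periodogram power in the delta/theta/alpha/beta bands. Optional
#' extras (`"min"`, `"peak_to_peak"`) can be appended to reach a configured
#' length.
#'
#' @param extra_features Character vector of extras to append.
#' @return Character vector of feature names.
#' @export
feature_names <- function(extra_features = character(0)) {
  base <- c("mobility", "complexity", "kurtosis", "mean", "max",
            "coeff_variation", "skewness", "wavelet_detail_energy",
            "wavelet_detail_entropy", "variance",
            "fft_delta_max_power", "fft_theta_max_power",
            "fft_alpha_max_power", "fft_beta_max_power")
  bad <- setdiff(extra_features, c("min", "peak_to_peak"))
  if (length(bad)) stopf("unknown extra feature(s): %s", paste(bad, collapse = ", "))
  c(base, extra_features)
}

#' Hjorth parameters of a series
#'
#' Activity is the variance; mobility is `sqrt(var(diff(x))/var(x))`, an RMS
#' frequency proxy; complexity is the mobility of the first difference over
#' the mobility of the signal, a bandwidth proxy.
#'
#' @param x Numeric series, length >= 3, non-constant.
#' @return List with `activity`, `mobility`, `complexity`.
#' @export
hjorth_params <- function(x) {
  if (length(x) < 3L) stopf("hjorth_params needs length >= 3")
  v0 <- stats::var(x)
  if (v0 == 0) stopf("degenerate variance: constant series")
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- stats::var(d1); v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  list(activity = v0, mobility = mob,
       complexity = sqrt(v2 / v1) / mob)
}

#' Moment-based statistical features
#'
#' Sample mean, max, unbiased variance, coefficient of variation
#' (`sd / |mean|`), skewness and excess kurtosis via standardized central
#' moments. A series with exactly zero mean reports CV = 0 with a
#' `cv_degenerate` flag rather than an infinity. A constant series still
#' reports mean/max/variance/CV, but its skewness and kurtosis are
#' undefined and returned as `NA` with `var_degenerate = TRUE` (callers
#' that need all moments treat that as an error).
#'
#' @param x Numeric series, length >= 4.
#' @return List of the six features plus `cv_degenerate`/`var_degenerate`.
#' @export
moment_features <- function(x) {
  n <- length(x)
  if (n < 4L) stopf("moment_features needs length >= 4")
  mu <- mean(x)
  v <- stats::var(x)
  cv_deg <- mu == 0
  if (v == 0) {
    return(list(mean = mu, max = max(x), variance = 0, coeff_variation = 0,
                skewness = NA_real_, kurtosis = NA_real_,
                cv_degenerate = cv_deg, var_degenerate = TRUE))
  }
  m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  list(mean = mu, max = max(x), variance = v,
       coeff_variation = if (cv_deg) 0 else sqrt(v) / abs(mu),
       skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3,
       cv_degenerate = cv_deg, var_degenerate = FALSE)
}

#' Wavelet detail energy and entropy
#'
#' Level-4 db4 decomposition ([dwt_db4()]); `detail_energy` is the summed
#' squared detail coefficients over all levels, and `detail_entropy` the
#' Shannon entropy (bits, `0*log 0 = 0`) of the per-level relative detail
#' energies. A zero series has energy 0 and entropy 0.
#'
#' @param x Numeric series (>= 16 usable samples).
#' @param level Decomposition depth, default 4.
#' @return List with `detail_energy`, `detail_entropy`.
#' @export
wavelet_features <- function(x, level = 4L) {
  dec <- dwt_db4(x, level)
  e <- vapply(dec$details, function(d) sum(d^2), numeric(1))
  tot <- sum(e)
  if (tot == 0) return(list(detail_energy = 0, detail_entropy = 0))
  p <- e[e > 0] / tot
  list(detail_energy = tot, detail_entropy = -sum(p * log2(p)))
}

band_edges <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Maximum periodogram power in the clinical EEG bands
#'
#' The periodogram is the unwindowed squared FFT magnitude divided by n,
#' computed on the mean-removed (constant-detrended) series, the standard
#' periodogram convention. Per band (delta 0.5-4, theta
#' 4-8, alpha 8-13, beta 13-30 Hz; half-open at the upper edge except beta)
#' the maximum periodogram ordinate is returned. The series must be long
#' enough that every band contains at least one frequency bin.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz; must be >= 60 to cover the beta band.
#' @return Named list delta/theta/alpha/beta.
#' @export
band_max_powers <- function(x, fs) {
  if (fs < 60) stopf("fs = %g too low to cover the beta band (need >= 60 Hz)", fs)
  n <- length(x)
  if (n < 2L) stopf("band_max_powers needs length >= 2")
  P <- Mod(stats::fft(x - mean(x)))^2 / n
  k <- seq_len(n %/% 2)            # positive frequencies, excluding DC
  f <- k * fs / n
  P <- P[k + 1L]
  out <- lapply(band_edges(), function(b) {
    inb <- if (b[2] == 30) f >= b[1] & f <= b[2] else f >= b[1] & f < b[2]
    if (!any(inb)) stopf("no frequency bin inside the %g-%g Hz band (series too short)",
                         b[1], b[2])
    max(P[inb])
  })
  names(out) <- paste0("fft_", names(band_edges()), "_max_power")
  out
}

feature_vector_from_series <- function(x, fs, extra_features = character(0)) {
  hj <- tryCatch(hjorth_params(x),
                 error = function(e) stopf("mobility/complexity: %s", conditionMessage(e)))
  mo <- tryCatch(moment_features(x),
                 error = function(e) stopf("moment features: %s", conditionMessage(e)))
  if (isTRUE(mo$var_degenerate)) {
    stopf("skewness/kurtosis: degenerate variance (constant series)")
  }
  wv <- tryCatch(wavelet_features(x),
                 error = function(e) stopf("wavelet features: %s", conditionMessage(e)))
  bp <- tryCatch(band_max_powers(x, fs),
                 error = function(e) stopf("band powers: %s", conditionMessage(e)))
  v <- c(mobility = hj$mobility, complexity = hj$complexity,
         kurtosis = mo$kurtosis, mean = mo$mean, max = mo$max,
         coeff_variation = mo$coeff_variation, skewness = mo$skewness,
         wavelet_detail_energy = wv$detail_energy,
         wavelet_detail_entropy = wv$detail_entropy,
         variance = mo$variance,
         fft_delta_max_power = bp$fft_delta_max_power,
         fft_theta_max_power = bp$fft_theta_max_power,
         fft_alpha_max_power = bp$fft_alpha_max_power,
         fft_beta_max_power = bp$fft_beta_max_power)
  if ("min" %in% extra_features) v <- c(v, min = min(x))
  if ("peak_to_peak" %in% extra_features) v <- c(v, peak_to_peak = diff(range(x)))
  assert_finite(v, "feature vector")
  v[feature_names(extra_features)]
}

epoch_series <- function(epoch, source) {
  switch(source,
    raw_avg = reshape1(epoch$eeg)$avg,
    corrected_avg = {
      if (is.null(epoch$corrected_avg)) {
        stopf("epoch carries no corrected series; run the correction first")
      }
      epoch$corrected_avg
    },
    stopf("unknown source '%s'", source))
}

#' Per-epoch feature vector
#'
#' Computes all features on the single averaged series of the epoch
#' (`raw_avg`), or on the error-corrected averaged series attached by the
#' pipeline (`corrected_avg`). Deterministic; degenerate inputs raise an
#' error naming the failing feature rather than producing NaNs.
#'
#' @param epoch A [bci_epoch()].
#' @param source `"corrected_avg"` (default) or `"raw_avg"`.
#' @param extra_features Extras appended after the 14 named features.
#' @return Named numeric vector with the epoch label as attribute `label`.
#' @export
extract_feature_vector <- function(epoch, source = c("corrected_avg", "raw_avg"),
                                   extra_features = character(0)) {
  source <- match.arg(source)
  x <- epoch_series(epoch, source)
  v <- feature_vector_from_series(x, epoch$fs, extra_features)
  attr(v, "label") <- epoch$label
  v
}

subwindow_starts <- function(n, k, overlap) {
  L <- floor(n / ((k - 1) * (1 - overlap) + 1))
  if (L < 1L) stopf("sub-windows too short")
  starts <- if (k == 1L) 1L else floor((seq_len(k) - 1) * (n - L) / (k - 1)) + 1L
  list(starts = as.integer(starts), length = as.integer(L))
}

#' Arrange an epoch into the 2-D feature grid fed to the CNN
#'
#' Splits the epoch's (corrected or raw) averaged series into
#' `n_subwindows` overlapping sub-windows and stacks one feature vector per
#' sub-window: an `n_subwindows x n_features` grid. Column standardization
#' is applied separately with training-set statistics
#' ([compute_feature_stats()], [standardize_features()]).
#'
#' @param epoch A [bci_epoch()].
#' @param n_subwindows Number of rows (default 8).
#' @param overlap_fraction Fractional overlap between consecutive windows
#'   (default 0.5).
#' @param source Series to use, as in [extract_feature_vector()].
#' @param extra_features Extras appended to each row.
#' @return A `feature_matrix`: numeric matrix with attribute `label`.
#' @export
build_feature_matrix <- function(epoch, n_subwindows = 8L,
                                 overlap_fraction = 0.5,
                                 source = c("corrected_avg", "raw_avg"),
                                 extra_features = character(0)) {
  source <- match.arg(source)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stopf("overlap_fraction must be in [0, 1)")
  }
  x <- epoch_series(epoch, source)
  sw <- subwindow_starts(length(x), n_subwindows, overlap_fraction)
  rows <- lapply(seq_len(n_subwindows), function(i) {
    seg <- x[sw$starts[i]:(sw$starts[i] + sw$length - 1L)]
    feature_vector_from_series(seg, epoch$fs, extra_features)
  })
  g <- do.call(rbind, rows)
  rownames(g) <- NULL
  structure(g, label = epoch$label, class = c("feature_matrix", "matrix", "array"))
}

#' Column statistics of a training set of feature matrices
#'
#' @param matrices List of feature matrices (equal dimensions).
#' @return List with per-column `mean` and `sd` (zero sd mapped to 1 so a
#'   constant column standardizes to 0 instead of NaN).
#' @export
compute_feature_stats <- function(matrices) {
  if (!length(matrices)) stopf("no feature matrices supplied")
  all_rows <- do.call(rbind, lapply(matrices, unclass))
  mu <- colMeans(all_rows)
  sd_ <- apply(all_rows, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  list(mean = mu, sd = sd_)
}

#' Standardize feature matrices with training-set statistics
#'
#' @param matrices List of feature matrices.
#' @param stats Output of [compute_feature_stats()].
#' @param invert If `TRUE`, apply the inverse transform instead.
#' @return List of standardized matrices (labels preserved).
#' @export
standardize_features <- function(matrices, stats, invert = FALSE) {
  lapply(matrices, function(m) {
    lab <- attr(m, "label")
    out <- if (invert) {
      sweep(sweep(unclass(m), 2L, stats$sd, "*"), 2L, stats$mean, "+")
    } else {
      sweep(sweep(unclass(m), 2L, stats$mean, "-"), 2L, stats$sd, "/")
    }
    structure(out, label = lab, class = c("feature_matrix", "matrix", "array"))
  })
}
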