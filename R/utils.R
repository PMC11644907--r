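#' Root-mean-square of a signal about its mean
#'
#' All error-model quantities in this package are windowed RMS amplitudes
#' computed after removing the window mean: DC offsets (the 1 g gravity
#' component on the accelerometer z axis, slow electrode drift on EEG) carry
#' no motion information and would otherwise enter the error nonlinearly.
#'
#' @param x Numeric vector.
#' @param demean Remove the mean before squaring (default `TRUE`).
#' @return Scalar RMS value.
#' @export
rms <- function(x, demean = TRUE) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("rms() needs a non-empty numeric vector", call. = FALSE)
  }
  if (demean) x <- x - mean(x)
  sqrt(mean(x^2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
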