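# Periodized orthogonal discrete wavelet transform (Daubechies db4, 8 taps).
# Circular filtering keeps the transform orthonormal for even lengths, so
# signal energy is exactly preserved across levels (Parseval), which the
# wavelet energy/entropy features rely on.

db4_filters <- function() {
  h <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
         -0.027983769416984, -0.187034811718881, 0.030841381835987,
         0.032883011666983, -0.010597401784997)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(lo = h, hi = g)
}

dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  L <- length(filt$lo)
  # a_k = sum_m lo[m] * x[(2k + m - 2) mod n + 1]
  idx <- outer(2L * seq_len(half) - 2L, seq_len(L) - 1L, "+") %% n + 1L
  xm <- matrix(x[idx], half, L)
  list(approx = as.numeric(xm %*% filt$lo),
       detail = as.numeric(xm %*% filt$hi))
}

#' Periodized Daubechies-4 wavelet decomposition
#'
#' Decomposes a series to `level` scales with the 8-tap db4 filter pair and
#' circular (periodized) boundary handling. The input is truncated to the
#' largest multiple of `2^level`; the transform is orthonormal, so the
#' energies of the approximation and all detail bands sum to the energy of
#' the (truncated) input.
#'
#' @param x Numeric series of length >= `2^level`.
#' @param level Decomposition depth (default 4).
#' @return List with `approx` (deepest approximation), `details` (list of
#'   detail coefficient vectors, level 1 = finest) and `n_used`.
#' @export
dwt_db4 <- function(x, level = 4L) {
  level <- as.integer(level)
  n_used <- (length(x) %/% (2L^level)) * (2L^level)
  if (n_used < 2L^level || n_used < 16L) {
    stopf("series too short for a level-%d db4 decomposition (need >= %d usable samples)",
          level, max(2L^level, 16L))
  }
  x <- x[seq_len(n_used)]
  filt <- db4_filters()
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- dwt_step(a, filt)
    details[[l]] <- st$detail
    a <- st$approx
  }
  list(approx = a, details = details, n_used = n_used)
}
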