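# Minimal periodic orthogonal discrete wavelet transform, used to isolate
# the broad (coarse-band) glass-substrate background from narrow Raman
# peaks. Only the approximation branch is needed: the signal is decomposed
# `levels` times with the lowpass analysis filter and reconstructed with all
# detail bands zeroed, yielding the smooth component.
#
# Filter: symlet-8 (16-tap, near-symmetric, orthonormal) — smooth enough
# that the approximation band carries only features broad relative to
# 2^levels grid steps.

.sym8_lo <- c(
  -3.3824159510061256e-03, -5.4213233179114812e-04, 3.1695087811492981e-02,
   7.6074873249176054e-03, -1.4329423835080971e-01, -6.1273359067658524e-02,
   4.8135965125837221e-01,  7.7718575170052351e-01,  3.6444189483533140e-01,
  -5.1945838107709037e-02, -2.7219029917056003e-02,  4.9137179673607506e-02,
   3.8087520138906151e-03, -1.4952258337048231e-02, -3.0292051472136680e-04,
   1.8899503327594609e-03)

wavelet_filters <- function(wavelet = "sym8") {
  if (!identical(wavelet, "sym8")) {
    stop("parameter error: only the 'sym8' wavelet is provided", call. = FALSE)
  }
  h <- .sym8_lo
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)  # quadrature-mirror highpass
  list(h = h, g = g)
}

dwt_step_lo <- function(s, h) {
  N <- length(s)
  L <- length(h)
  idx <- (outer(seq(0L, N - 2L, by = 2L), 0:(L - 1L), `+`) %% N) + 1L
  drop(matrix(s[idx], nrow = N %/% 2L) %*% h)
}

idwt_step <- function(a, d, h, g) {
  N <- 2L * length(a)
  L <- length(h)
  s <- numeric(N)
  starts <- seq(0L, N - 2L, by = 2L)
  for (m in seq_len(L)) {
    pos <- ((starts + m - 1L) %% N) + 1L
    s[pos] <- s[pos] + h[m] * a + g[m] * d
  }
  s
}

#' Coarse-band (approximation) component of a signal
#'
#' Decomposes `x` to `levels` wavelet scales (periodic orthogonal transform,
#' symmetric padding to a multiple of 2^levels) and reconstructs with every
#' detail band set to zero, returning the smooth background component at the
#' original length.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth; requires `2^levels <= length(x)`.
#' @param wavelet Wavelet name (only `"sym8"`).
#' @return Numeric vector, same length as `x`.
#' @export
dwt_approximation <- function(x, levels, wavelet = "sym8") {
  n <- length(x)
  if (2^levels > n) {
    stop("parameter error: dwt_levels too deep for signal length",
         call. = FALSE)
  }
  filt <- wavelet_filters(wavelet)
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    # reflect the tail so the periodic wrap sees no jump
    pad <- x[n - seq_len(n_pad - n) + 1L]
    x <- c(x, pad)
  }
  a <- x
  for (j in seq_len(levels)) a <- dwt_step_lo(a, filt$h)
  for (j in seq_len(levels)) {
    a <- idwt_step(a, numeric(length(a)), filt$h, filt$g)
  }
  a[seq_len(n)]
}
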