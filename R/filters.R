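#' Zero-phase Butterworth filter
#'
#' Filters a uniformly sampled signal with the squared magnitude response of
#' an order-`order` Butterworth filter, applied in the frequency domain.
#' This matches the magnitude response of the usual forward-backward
#' (filtfilt) application of a time-domain Butterworth filter and is exactly
#' zero phase. The signal is reflection-padded before the FFT to suppress
#' circular edge effects.
#'
#' There is no IIR filter implementation in base R; the frequency-sampling
#' route is deterministic, exactly linear, and its attenuation is easy to
#' verify against the closed-form Butterworth gain, which is what the tests
#' do.
#'
#' @param x numeric signal (no NAs; interpolate first).
#' @param fs sampling rate, Hz.
#' @param low high-pass cutoff in Hz, or `NULL` for none.
#' @param high low-pass cutoff in Hz, or `NULL` for none.
#' @param order Butterworth order (default 4).
#' @return filtered signal, same length as `x`.
#' @export
butterworth <- function(x, fs, low = NULL, high = NULL, order = 4L) {
  if (anyNA(x)) stop("signal contains NA; interpolate before filtering")
  nyq <- fs / 2
  if (!is.null(high) && high >= nyq) stop("low-pass cutoff must be below Nyquist")
  if (!is.null(low) && low >= nyq) stop("high-pass cutoff must be below Nyquist")
  if (is.null(low) && is.null(high)) return(x)
  n <- length(x)
  if (n < 4L) return(x)

  pad <- min(n - 1L, max(16L, ceiling(3 * fs / max(c(low, high, 1e-12)[1], 1e-12))))
  pad <- min(pad, n - 1L)
  xp <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp)
  f <- freq_axis(m, fs)

  gain <- rep(1, m)
  if (!is.null(high)) gain <- gain / (1 + (f / high)^(2 * order))
  if (!is.null(low)) {
    g <- numeric(m)
    nz <- f > 0
    g[nz] <- 1 / (1 + (low / f[nz])^(2 * order))
    gain <- gain * g
  }
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

freq_axis <- function(m, fs) {
  k <- seq_len(m) - 1L
  k[k > m / 2] <- k[k > m / 2] - m
  abs(k) * fs / m
}

#' Local minima (troughs) with a prominence criterion
#'
#' Finds local minima of `x` and keeps those whose prominence (depth below
#' the lower of the two enclosing maxima, measured the usual topographic way)
#' exceeds `prominence`.
#'
#' @param x numeric signal.
#' @param prominence minimum prominence (same units as `x`).
#' @return integer indices of retained troughs, increasing.
#' @export
find_troughs <- function(x, prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # strict sign changes; plateaus resolved at their first point
  sgn <- sign(d)
  sgn[sgn == 0] <- 1
  cand <- which(diff(sgn) > 0) + 1L
  if (!length(cand)) return(integer(0))
  if (prominence <= 0) return(cand)
  keep <- vapply(cand, function(i) trough_prominence(x, i) >= prominence,
                 logical(1))
  cand[keep]
}

# prominence of a trough: on each side, walk until a point lower than x[i]
# is found (or the signal end); the side's barrier is the max in between;
# prominence is min(left barrier, right barrier) - x[i]
trough_prominence <- function(x, i) {
  n <- length(x)
  left <- if (i > 1L) {
    lower <- which(x[1:(i - 1L)] < x[i])
    lo <- if (length(lower)) max(lower) + 1L else 1L
    max(x[lo:(i - 1L)])
  } else -Inf
  right <- if (i < n) {
    lower <- which(x[(i + 1L):n] < x[i])
    hi <- if (length(lower)) i + min(lower) - 1L else n
    max(x[(i + 1L):hi])
  } else -Inf
  min(left, right) - x[i]
}

#' Complex Morlet wavelet time-frequency power
#'
#' Convolves each signal with complex Morlet wavelets
#' `exp(2i pi f t) exp(-t^2 / (2 sigma_t^2))`, `sigma_t = c / (2 pi f)`,
#' where `c` is the number of cycles, and returns squared magnitude.
#' Wavelets are L1-normalized so a unit-amplitude sinusoid at the wavelet's
#' center frequency yields (asymptotically) unit peak amplitude.
#'
#' @param x numeric signal or samples-by-trials matrix.
#' @param fs sampling rate, Hz.
#' @param freqs center frequencies, Hz.
#' @param cycles Morlet parameter c (number of cycles, default 3).
#' @return array `length(x) x length(freqs)` (or samples x freqs x trials)
#'   of power values.
#' @export
morlet_power <- function(x, fs, freqs, cycles = 3) {
  if (is.matrix(x)) {
    out <- array(NA_real_, c(nrow(x), length(freqs), ncol(x)))
    for (j in seq_len(ncol(x))) out[, , j] <- morlet_power(x[, j], fs, freqs, cycles)
    return(out)
  }
  n <- length(x)
  out <- matrix(NA_real_, n, length(freqs))
  for (k in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[k], fs, cycles)
    out[, k] <- Mod(conv_same(x, w))^2
  }
  out
}

morlet_wavelet <- function(f, fs, cycles) {
  sigma_t <- cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sum(Mod(w))
}

# centered ("same") complex convolution via FFT with zero padding
conv_same <- function(x, w) {
  n <- length(x)
  m <- length(w)
  L <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, rep(0, L - n)))
  W <- stats::fft(c(w, rep(0, L - m)))
  full <- stats::fft(X * W, inverse = TRUE) / L
  start <- (m - 1L) %/% 2L + 1L
  full[start:(start + n - 1L)]
}
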