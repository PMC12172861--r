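#' Simulate EEG epochs with controllable band power and an injectable
#' oddball negativity
#'
#' Epochs are 1/f ("pink-ish") noise plus sinusoidal alpha (10 Hz by
#' default) and theta (6 Hz) components with per-epoch amplitudes, plus an
#' optional Gaussian-windowed deflection on oddball epochs that is negative
#' on frontal channels and polarity-inverted on posterior channels -- the
#' topography of an auditory mismatch response.
#'
#' @param n_epochs number of epochs.
#' @param window_ms epoch window relative to the anchor, ms.
#' @param fs sampling rate, Hz.
#' @param channels channel role names; names containing `"posterior"` get
#'   the inverted ERP polarity.
#' @param noise_sd pink-noise SD, microvolts.
#' @param alpha_amp,theta_amp sinusoid amplitudes (microvolts); scalar or
#'   per-epoch vector.
#' @param alpha_hz,theta_hz component frequencies.
#' @param oddball logical per-epoch oddball labels (default: none).
#' @param erp_amp ERP deflection amplitude in microvolts (negative for an
#'   MMN-like response) applied to oddball epochs.
#' @param erp_latency_ms,erp_width_ms Gaussian deflection center and SD.
#' @param seed integer seed.
#' @return list of class `eeg_epochs`: `data` (samples x channels x
#'   epochs, microvolts), `time_ms`, `fs`, `channels`, `oddball`.
#' @export
simulate_eeg_epochs <- function(n_epochs = 100L,
                                window_ms = c(-100, 500), fs = 500,
                                channels = c("frontal_midline", "posterior_1",
                                             "posterior_2"),
                                noise_sd = 5,
                                alpha_amp = 0, theta_amp = 0,
                                alpha_hz = 10, theta_hz = 6,
                                oddball = NULL, erp_amp = 0,
                                erp_latency_ms = 120, erp_width_ms = 60,
                                seed = NULL) {
  stopifnot(all(is.finite(c(noise_sd, alpha_amp, theta_amp, erp_amp))))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- round((window_ms[2] - window_ms[1]) * fs / 1000)
  time_ms <- window_ms[1] + (seq_len(n) - 1L) * 1000 / fs
  nc <- length(channels)
  if (is.null(oddball)) oddball <- rep(FALSE, n_epochs)
  stopifnot(length(oddball) == n_epochs)
  alpha_amp <- rep_len(alpha_amp, n_epochs)
  theta_amp <- rep_len(theta_amp, n_epochs)

  erp_shape <- exp(-0.5 * ((time_ms - erp_latency_ms) / erp_width_ms)^2)
  posterior <- grepl("posterior", channels)

  dat <- array(0, c(n, nc, n_epochs))
  for (e in seq_len(n_epochs)) {
    ph_a <- stats::runif(1, 0, 2 * pi)
    ph_t <- stats::runif(1, 0, 2 * pi)
    osc <- alpha_amp[e] * sin(2 * pi * alpha_hz * time_ms / 1000 + ph_a) +
      theta_amp[e] * sin(2 * pi * theta_hz * time_ms / 1000 + ph_t)
    for (c in seq_len(nc)) {
      x <- pink_noise(n, noise_sd) + osc
      if (oddball[e] && erp_amp != 0) {
        pol <- if (posterior[c]) -1 else 1
        x <- x + pol * erp_amp * erp_shape
      }
      dat[, c, e] <- x
    }
  }
  structure(list(data = dat, time_ms = time_ms, fs = fs,
                 channels = channels, oddball = oddball),
            class = "eeg_epochs")
}

# 1/f-shaped noise via spectral shaping of white noise, scaled to sd
pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- freq_axis(n, 1)
  scale <- 1 / sqrt(pmax(f, f[2]))     # flatten below the first bin
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d samples x %d channels x %d epochs @ %g Hz (%d oddball)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              sum(x$oddball)))
  invisible(x)
}
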