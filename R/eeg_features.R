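#' Band-pass preprocessing of continuous or epoched EEG
#'
#' Zero-phase Butterworth band-pass (defaults 0.5-30 Hz, order 4) applied
#' per channel (and per epoch when given an `eeg_epochs` object), with
#' optional re-referencing to the mean of named channels.
#'
#' @param x numeric vector, samples-by-channels matrix, or `eeg_epochs`.
#' @param fs sampling rate (ignored for `eeg_epochs`).
#' @param band two-element band in Hz.
#' @param order filter order.
#' @param reference channel names (for `eeg_epochs`) whose mean is
#'   subtracted, or `NULL` to keep the recording reference.
#' @return same shape as the input, filtered.
#' @export
eeg_preprocess <- function(x, fs = 500, band = c(0.5, 30), order = 4L,
                           reference = NULL) {
  stopifnot(band[1] < band[2])
  if (inherits(x, "eeg_epochs")) {
    if (!is.null(reference)) {
      ref_idx <- match(reference, x$channels)
      if (anyNA(ref_idx)) stop("unknown reference channel(s)")
      ref <- apply(x$data[, ref_idx, , drop = FALSE], c(1, 3), mean)
      for (c in seq_along(x$channels)) x$data[, c, ] <- x$data[, c, ] - ref
    }
    for (e in seq_len(dim(x$data)[3])) {
      for (c in seq_len(dim(x$data)[2])) {
        x$data[, c, e] <- butterworth(x$data[, c, e], x$fs,
                                      low = band[1], high = band[2],
                                      order = order)
      }
    }
    return(x)
  }
  if (is.matrix(x)) {
    return(apply(x, 2, butterworth, fs = fs, low = band[1], high = band[2],
                 order = order))
  }
  butterworth(x, fs, low = band[1], high = band[2], order = order)
}

#' Amplitude-criterion epoch rejection
#'
#' Drops epochs in which any sample on any channel exceeds `threshold`
#' microvolts in absolute value -- a deterministic stand-in for visual
#' artifact screening.
#'
#' @param epochs an `eeg_epochs`.
#' @param threshold rejection threshold, microvolts (default 100).
#' @return the `eeg_epochs` with offending epochs removed; the number
#'   dropped is recorded in attribute `n_rejected`.
#' @export
reject_epochs <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  bad <- apply(abs(epochs$data), 3, max) > threshold
  if (all(bad)) stop("all epochs exceed the rejection threshold")
  epochs$data <- epochs$data[, , !bad, drop = FALSE]
  epochs$oddball <- epochs$oddball[!bad]
  attr(epochs, "n_rejected") <- sum(bad)
  epochs
}

#' Mismatch negativity from standard and oddball epochs
#'
#' Baseline-corrects both conditions to their `[-100, 0)` ms means,
#' averages, forms the oddball-minus-standard difference waveform on the
#' measurement channel, finds the most negative sample of the difference in
#' the `[120, 300]` ms search window, and returns the mean amplitude over a
#' 40 ms window centered at that peak. When posterior channels are present
#' the polarity-inversion check reports whether their difference waveform
#' has the opposite sign at the peak.
#'
#' @param standards,oddballs `eeg_epochs` objects with identical windows
#'   and channels.
#' @param channel measurement channel name (default the first channel).
#' @param search_ms peak search window.
#' @param peak_halfwidth_ms half width of the amplitude window (20 ms).
#' @param baseline_ms baseline window.
#' @return list: `difference` (samples x channels), `time_ms`,
#'   `peak_latency_ms`, `mean_amplitude` (microvolts),
#'   `polarity_inverted` (logical or NA when no posterior channel).
#' @export
mmn <- function(standards, oddballs, channel = NULL,
                search_ms = c(120, 300), peak_halfwidth_ms = 20,
                baseline_ms = c(-100, 0)) {
  stopifnot(inherits(standards, "eeg_epochs"), inherits(oddballs, "eeg_epochs"))
  if (dim(standards$data)[3] == 0L || dim(oddballs$data)[3] == 0L) {
    stop("empty condition")
  }
  if (!isTRUE(all.equal(standards$time_ms, oddballs$time_ms))) {
    stop("epoch windows differ between conditions")
  }
  if (is.null(channel)) channel <- standards$channels[1]
  ch <- match(channel, standards$channels)
  if (is.na(ch)) stop("unknown channel `", channel, "`")
  tms <- standards$time_ms

  avg <- function(ep) {
    base <- tms >= baseline_ms[1] & tms < baseline_ms[2]
    d <- ep$data
    for (e in seq_len(dim(d)[3])) {
      for (c in seq_len(dim(d)[2])) {
        d[, c, e] <- d[, c, e] - mean(d[base, c, e])
      }
    }
    apply(d, c(1, 2), mean)
  }
  diffw <- avg(oddballs) - avg(standards)

  win <- tms >= search_ms[1] & tms <= search_ms[2]
  rel <- which(win)[which.min(diffw[win, ch])]
  peak_t <- tms[rel]
  amp_win <- tms >= peak_t - peak_halfwidth_ms & tms <= peak_t + peak_halfwidth_ms
  amp <- mean(diffw[amp_win, ch])

  posterior <- grepl("posterior", standards$channels)
  inverted <- NA
  if (any(posterior)) {
    post_amp <- mean(diffw[amp_win, posterior, drop = FALSE])
    inverted <- sign(post_amp) == -sign(amp) && post_amp != 0
  }
  list(difference = diffw, time_ms = tms, peak_latency_ms = peak_t,
       mean_amplitude = amp, polarity_inverted = inverted, channel = channel)
}

#' Occipital alpha power by tapered FFT
#'
#' Per epoch: remove the epoch mean, taper with a Tukey window whose
#' cosine ramps cover 10% of the epoch, FFT, and sum one-sided power over
#' the bins inside the alpha band. Power is normalized so the summed
#' spectrum equals the time-domain variance of the tapered epoch
#' (a Parseval convention).
#'
#' @param epochs an `eeg_epochs` (1000 ms epochs give ~1 Hz resolution).
#' @param channel channel name or index (default: mean of channels
#'   containing "posterior", else the first channel).
#' @param band frequency band, Hz (default 8-12).
#' @param taper total taper fraction of the Tukey window (default 0.1).
#' @return numeric vector of per-epoch alpha power (microvolts squared).
#' @export
alpha_power <- function(epochs, channel = NULL, band = c(8, 12),
                        taper = 0.1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n <- dim(epochs$data)[1]
  sig <- epoch_channel(epochs, channel)
  w <- tukey_window(n, taper)
  freqs <- (seq_len(n) - 1L) * epochs$fs / n
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= epochs$fs / 2
  vapply(seq_len(ncol(sig)), function(e) {
    x <- sig[, e]
    x <- (x - mean(x)) * w
    p <- Mod(stats::fft(x))^2 / n^2
    # one-sided: double everything except DC (and Nyquist if present)
    one <- 2 * p
    one[1] <- p[1]
    if (n %% 2 == 0) one[n / 2 + 1] <- p[n / 2 + 1]
    sum(one[keep])
  }, numeric(1))
}

epoch_channel <- function(epochs, channel) {
  if (is.null(channel)) {
    post <- grepl("posterior", epochs$channels)
    if (any(post)) {
      return(apply(epochs$data[, post, , drop = FALSE], c(1, 3), mean))
    }
    channel <- 1L
  }
  if (is.character(channel)) channel <- match(channel, epochs$channels)
  if (is.na(channel)) stop("unknown channel")
  epochs$data[, channel, ]
}

tukey_window <- function(n, taper) {
  if (taper <= 0) return(rep(1, n))
  w <- rep(1, n)
  ramp <- floor(taper * n / 2)
  if (ramp > 0) {
    k <- seq_len(ramp)
    edge <- 0.5 * (1 - cos(pi * (k - 1) / ramp))
    w[k] <- edge
    w[n - k + 1L] <- edge
  }
  w
}

#' Midfrontal theta power before responses
#'
#' Morlet time-frequency power (default c = 3 cycles over 30 linear
#' frequency steps on 1-30 Hz), averaged over the theta band and a
#' pre-response window, per epoch. Intended for [-1000, 1000] ms
#' tap-anchored epochs on the frontal-midline channel.
#'
#' @param epochs an `eeg_epochs`.
#' @param channel channel (default: first channel containing
#'   `"frontal"`, else the first channel).
#' @param band theta band, Hz.
#' @param window_ms averaging window relative to the anchor.
#' @param freqs wavelet center frequencies.
#' @param cycles Morlet parameter c.
#' @return numeric vector of per-epoch mean theta power.
#' @export
midfrontal_theta <- function(epochs, channel = NULL, band = c(4, 8),
                             window_ms = c(-500, 0),
                             freqs = seq(1, 30, length.out = 30),
                             cycles = 3) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(channel)) {
    fr <- grep("frontal", epochs$channels)
    channel <- if (length(fr)) fr[1] else 1L
  }
  sig <- epoch_channel(epochs, channel)
  tsel <- epochs$time_ms >= window_ms[1] & epochs$time_ms <= window_ms[2]
  fsel <- freqs >= band[1] & freqs <= band[2]
  if (!any(fsel)) stop("no wavelet frequency inside the band")
  pw <- morlet_power(sig, epochs$fs, freqs[fsel], cycles)
  apply(pw[tsel, , , drop = FALSE], 3, mean)
}

#' Per-subject median split of epochs by a covariate
#'
#' Labels each epoch high/low relative to its subject's median; with an odd
#' epoch count the median epoch goes to the low side, so counts differ by
#' at most one.
#'
#' @param value numeric per-epoch covariate (e.g. ApEn of the surrounding
#'   window).
#' @param subject per-epoch subject labels (one subject when `NULL`).
#' @return logical vector, TRUE = high side.
#' @export
median_split <- function(value, subject = NULL) {
  if (is.null(subject)) subject <- rep(1L, length(value))
  out <- logical(length(value))
  for (s in unique(subject)) {
    i <- which(subject == s)
    r <- rank(value[i], ties.method = "first")
    out[i] <- r > length(i) / 2
  }
  out
}
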