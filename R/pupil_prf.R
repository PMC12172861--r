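#' Pupil response function
#'
#' The stereotyped Erlang-shaped impulse response of pupil diameter to a
#' discrete event, `h(t) = (t/t_max)^n * exp(n * (1 - t/t_max))`,
#' normalized to a unit peak at `t = t_max` so deconvolution coefficients
#' carry diameter units. Defaults `n = 10`, `t_max = 900` ms give the
#' canonical slow response peaking at 900 ms.
#'
#' @param t time since event, ms (vectorized; values < 0 return 0).
#' @param n shape parameter.
#' @param t_max time-to-peak, ms.
#' @return unitless response, peak 1 at `t = t_max`.
#' @export
prf <- function(t, n = 10, t_max = 900) {
  out <- numeric(length(t))
  pos <- t > 0
  r <- t[pos] / t_max
  out[pos] <- r^n * exp(n * (1 - r))
  out
}

#' Simulate a pupillometry recording for a task session
#'
#' Builds a 500 Hz diameter trace as the sum of
#' * a slow tonic component: a cubic-spline-smoothed random walk over knots
#'   every `tonic_knot_s` seconds plus an optional linear trend,
#' * PRF-convolved responses at every tone and tap onset with non-negative
#'   amplitudes drawn from a truncated normal, and
#' * white Gaussian measurement noise,
#' with blinks inserted as missing-data gaps flanked by steep artifactual
#' transients (partial-occlusion ramps) such as video eye trackers produce.
#'
#' @param events event log with tone (and optionally tap) rows.
#' @param fs sampling rate, Hz.
#' @param baseline mean tonic diameter, arbitrary units.
#' @param tonic_sd SD of the tonic random-walk increments per knot.
#' @param tonic_knot_s knot spacing of the tonic component, s.
#' @param trend linear trend over the whole recording (a.u. from start to end).
#' @param amp_mean,amp_sd truncated-normal event amplitude parameters
#'   (a.u.; both must be non-negative).
#' @param noise_sd measurement noise SD (a.u.).
#' @param n_blinks expected number of blinks (Poisson).
#' @param blink_dur_ms range of blink gap durations.
#' @param prf_n,prf_tmax PRF shape parameters, see [prf()].
#' @param duration_ms recording length; defaults to span of events + 3 s.
#' @param seed integer seed.
#' @return object of class `pupil_recording`: list with `time_ms`,
#'   `diameter`, `missing` (0/1), `fs`, `blink_intervals` (true inserted
#'   gaps), and `ground_truth` (tonic trace, event times, amplitudes).
#' @export
simulate_pupil <- function(events, fs = 500, baseline = 5,
                           tonic_sd = 0.1, tonic_knot_s = 2, trend = 0,
                           amp_mean = 0.3, amp_sd = 0.1, noise_sd = 0.02,
                           n_blinks = 5, blink_dur_ms = c(100, 400),
                           prf_n = 10, prf_tmax = 900,
                           duration_ms = NULL, seed = NULL) {
  if (amp_mean < 0 || amp_sd < 0) stop("amplitude parameters must be >= 0")
  if (!is.null(seed)) withr::local_seed(seed)
  ev_t <- sort(events$time_ms[events$kind %in% c("tone", "tap")])
  if (is.null(duration_ms)) {
    duration_ms <- (if (length(ev_t)) max(ev_t) else 0) + 3000
  }
  n <- floor(duration_ms * fs / 1000)
  time_ms <- (seq_len(n) - 1L) * 1000 / fs

  # tonic: smoothed random walk + trend
  knots <- seq(0, duration_ms, by = tonic_knot_s * 1000)
  walk <- cumsum(stats::rnorm(length(knots), 0, tonic_sd))
  walk <- walk - mean(walk)
  tonic <- baseline + trend * time_ms / duration_ms +
    stats::spline(knots, walk, xout = time_ms, method = "natural")$y

  # event responses
  amps <- numeric(length(ev_t))
  if (length(ev_t)) {
    amps <- truncnorm_pos(length(ev_t), amp_mean, amp_sd)
  }
  phasic <- numeric(n)
  kernel_len <- ceiling(6 * prf_tmax * fs / 1000)
  kernel <- prf((seq_len(kernel_len) - 1L) * 1000 / fs, prf_n, prf_tmax)
  for (i in seq_along(ev_t)) {
    j0 <- floor(ev_t[i] * fs / 1000) + 1L
    if (j0 > n) next
    j1 <- min(n, j0 + kernel_len - 1L)
    phasic[j0:j1] <- phasic[j0:j1] + amps[i] * kernel[seq_len(j1 - j0 + 1L)]
  }

  diameter <- tonic + phasic + stats::rnorm(n, 0, noise_sd)
  missing <- integer(n)

  # blinks: steep down-ramp, gap, steep recovery
  k_blinks <- stats::rpois(1, n_blinks)
  blink_iv <- matrix(numeric(0), 0, 2)
  if (k_blinks > 0) {
    starts <- sort(stats::runif(k_blinks, 500, duration_ms - 1000))
    durs <- stats::runif(k_blinks, blink_dur_ms[1], blink_dur_ms[2])
    ramp_ms <- 20
    for (b in seq_len(k_blinks)) {
      i0 <- max(1L, floor(starts[b] * fs / 1000))
      i1 <- min(n, ceiling((starts[b] + durs[b]) * fs / 1000))
      r <- max(1L, round(ramp_ms * fs / 1000))
      pre <- max(1L, i0 - r):max(1L, i0 - 1L)
      post <- min(n, i1 + 1L):min(n, i1 + r)
      # partial occlusion: diameter collapses towards a fraction of itself
      diameter[pre] <- diameter[pre] * seq(1, 0.4, length.out = length(pre))
      diameter[post] <- diameter[post] * seq(0.4, 1, length.out = length(post))
      diameter[i0:i1] <- NA_real_
      missing[i0:i1] <- 1L
      blink_iv <- rbind(blink_iv, c(time_ms[i0], time_ms[i1]))
    }
  }

  structure(list(
    time_ms = time_ms, diameter = diameter, missing = missing, fs = fs,
    blink_intervals = blink_iv,
    ground_truth = list(tonic = tonic, event_times_ms = ev_t,
                        amplitudes = amps, noise_sd = noise_sd)
  ), class = "pupil_recording")
}

truncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mean, sd)
  x
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf("<pupil_recording> %d samples @ %g Hz (%.1f s), %.1f%% missing\n",
              length(x$diameter), x$fs,
              length(x$diameter) / x$fs, 100 * mean(x$missing)))
  invisible(x)
}
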