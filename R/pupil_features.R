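#' Non-negative least squares
#'
#' Lawson-Hanson active-set solution of `min || A x - b ||` subject to
#' `x >= 0`. Thin wrapper over the compiled solver; the returned gradient
#' lets callers verify the KKT conditions.
#'
#' @param A design matrix.
#' @param b response vector.
#' @return list with `x` (coefficients, all >= 0), `rss`, `gradient`
#'   (`t(A) %*% residual`; ~0 where `x > 0`, <= 0 where `x = 0`).
#' @export
nnls <- function(A, b) {
  stopifnot(is.matrix(A), nrow(A) == length(b))
  nnls_cpp(A, as.numeric(b))
}

#' Traditional window-based tonic/phasic pupil features
#'
#' Per trial (tone onset): baseline = mean diameter over `[-200, 0)` ms,
#' response = mean over `[500, 700)` ms minus the baseline. Windows are
#' half-open and anchored at the onset. Because consecutive responses
#' overlap at a 750 ms pace, these baselines absorb response build-up --
#' the motivation for the deconvolution method.
#'
#' @param rec preprocessed `pupil_recording`.
#' @param onsets_ms tone onset times, ms.
#' @param baseline_win,response_win window edges in ms relative to onset.
#' @return data frame: `trial`, `onset_ms`, `baseline`, `response`,
#'   `missing_frac` (fraction of masked samples in the union of both
#'   windows), `flagged` (window outside the record).
#' @export
traditional_features <- function(rec, onsets_ms,
                                 baseline_win = c(-200, 0),
                                 response_win = c(500, 700)) {
  stopifnot(inherits(rec, "pupil_recording"))
  t0 <- rec$time_ms[1]
  t1 <- rec$time_ms[length(rec$time_ms)]
  out <- data.frame(trial = seq_along(onsets_ms), onset_ms = onsets_ms,
                    baseline = NA_real_, response = NA_real_,
                    missing_frac = NA_real_, flagged = FALSE)
  for (i in seq_along(onsets_ms)) {
    on <- onsets_ms[i]
    lo <- on + min(baseline_win[1], response_win[1])
    hi <- on + max(baseline_win[2], response_win[2])
    if (lo < t0 || hi > t1) { out$flagged[i] <- TRUE; next }
    b_idx <- rec$time_ms >= on + baseline_win[1] & rec$time_ms < on + baseline_win[2]
    r_idx <- rec$time_ms >= on + response_win[1] & rec$time_ms < on + response_win[2]
    out$baseline[i] <- mean(rec$diameter[b_idx])
    out$response[i] <- mean(rec$diameter[r_idx]) - out$baseline[i]
    out$missing_frac[i] <- mean(rec$missing[b_idx | r_idx])
  }
  out
}

#' Trough-anchored spline + non-negative deconvolution of a pupil trace
#'
#' Decomposes a preprocessed recording into a slow tonic component and
#' per-event phasic response amplitudes:
#' 1. downsample to `fs_out` (default 250 Hz);
#' 2. detect high-prominence troughs (prominence threshold defaults to
#'    `prominence_factor` times a robust SD of the high-passed trace);
#' 3. provisional tonic = interpolating natural cubic spline through the
#'    trough points;
#' 4. non-negative least squares of (signal - provisional tonic) on
#'    PRF-shaped regressors at every event onset;
#' 5. subtract the modeled responses from the signal, re-detect troughs,
#'    and fit the second-iteration spline: the final tonic, which lies at
#'    or below the signal at its trough points (lower envelope);
#' 6. re-estimate the coefficients against (signal - final tonic);
#' 7. per trial, `tonic_novel` = final tonic at tone onset and
#'    `phasic_novel` = sum of coefficients of events within +-200 ms of
#'    the onset (avoiding tap/tone collinearity);
#' 8. z-score both features within the recording (one subject).
#'
#' @param rec preprocessed `pupil_recording` (blinks interpolated,
#'   low-passed).
#' @param event_times_ms all stimulus and tap onsets used as regressors.
#' @param trial_onsets_ms tone onsets defining trials (default: the
#'   events).
#' @param fs_out decomposition sampling rate.
#' @param prominence_factor multiplier on the robust SD for trough
#'   prominence.
#' @param prf_n,prf_tmax PRF parameters.
#' @param assign_win_ms half-open window (+-) for summing coefficients onto
#'   trials.
#' @return list of class `pupil_decomposition`: `time_ms`, `signal`
#'   (downsampled), `tonic`, `coefficients` (per event, >= 0),
#'   `event_times_ms`, `trough_times_ms`, `features` (per-trial data frame
#'   with `tonic_novel`, `phasic_novel`, `missing_frac`, z-scored
#'   variants), `fallback` (TRUE when < 2 troughs forced a linear tonic),
#'   `rss_tonic_only`, `rss_full`.
#' @export
decompose_tonic_phasic <- function(rec, event_times_ms,
                                   trial_onsets_ms = NULL,
                                   fs_out = 250,
                                   prominence_factor = 0.2,
                                   prf_n = 10, prf_tmax = 900,
                                   assign_win_ms = 200) {
  stopifnot(inherits(rec, "pupil_recording"))
  if (anyNA(rec$diameter)) stop("interpolate blinks before decomposition")
  if (is.null(trial_onsets_ms)) trial_onsets_ms <- event_times_ms
  event_times_ms <- sort(event_times_ms)

  # 1. downsample
  dec <- max(1L, round(rec$fs / fs_out))
  idx <- seq(1L, length(rec$diameter), by = dec)
  tt <- rec$time_ms[idx]
  x <- rec$diameter[idx]
  miss <- rec$missing[idx]
  fs <- rec$fs / dec
  n <- length(x)

  # 2. troughs of the signal; prominence scaled to the fast fluctuations
  hp <- x - butterworth(x, fs, high = 0.5, order = 2L)
  prom <- prominence_factor * stats::mad(hp)
  tr1 <- find_troughs(x, prom)

  # PRF regressor bank at the decomposition rate
  kernel_len <- ceiling(6 * prf_tmax * fs / 1000)
  kernel <- prf((seq_len(kernel_len) - 1L) * 1000 / fs, prf_n, prf_tmax)
  build_design <- function() {
    A <- matrix(0, n, length(event_times_ms))
    for (j in seq_along(event_times_ms)) {
      i0 <- findInterval(event_times_ms[j], tt) + 1L
      if (i0 > n) next
      i1 <- min(n, i0 + kernel_len - 1L)
      A[i0:i1, j] <- kernel[seq_len(i1 - i0 + 1L)]
    }
    A
  }
  A <- build_design()

  fallback <- length(tr1) < 2L
  interp_spline <- function(px, py) {
    if (length(px) < 2L) {
      co <- stats::coef(stats::lm(x ~ tt))
      return(unname(co[1] + co[2] * tt))
    }
    stats::spline(px, py, xout = tt, method = "natural")$y
  }

  # 3. iteration 1
  tonic1 <- interp_spline(tt[tr1], x[tr1])
  # 4. coefficients against the provisional tonic
  fit1 <- nnls(A, x - tonic1)
  # 5. iteration 2 on the response-subtracted signal
  x2 <- x - as.numeric(A %*% fit1$x)
  tr2 <- find_troughs(x2, prom)
  if (length(tr2) < 2L) { tr2 <- tr1; fallback <- TRUE }
  tonic2 <- interp_spline(tt[tr2], x2[tr2])
  # 6. final coefficients
  fit2 <- nnls(A, x - tonic2)
  coefs <- fit2$x

  rss_tonic_only <- sum((x - tonic2)^2)
  rss_full <- fit2$rss

  # 7. per-trial features
  feats <- data.frame(trial = seq_along(trial_onsets_ms),
                      onset_ms = trial_onsets_ms)
  feats$tonic_novel <- stats::approx(tt, tonic2, xout = trial_onsets_ms,
                                     rule = 2)$y
  feats$phasic_novel <- vapply(trial_onsets_ms, function(on) {
    sum(coefs[event_times_ms >= on - assign_win_ms &
                event_times_ms < on + assign_win_ms])
  }, numeric(1))
  feats$missing_frac <- vapply(trial_onsets_ms, function(on) {
    w <- tt >= on - assign_win_ms & tt < on + assign_win_ms
    if (!any(w)) NA_real_ else mean(miss[w])
  }, numeric(1))
  # 8. within-recording z-scores
  feats$tonic_z <- as.numeric(scale(feats$tonic_novel))
  feats$phasic_z <- as.numeric(scale(feats$phasic_novel))

  structure(list(time_ms = tt, signal = x, tonic = tonic2,
                 coefficients = coefs, event_times_ms = event_times_ms,
                 trough_times_ms = tt[tr2], trough_idx = tr2,
                 features = feats, fallback = fallback,
                 rss_tonic_only = rss_tonic_only, rss_full = rss_full),
            class = "pupil_decomposition")
}

#' Missing-data screens for pupil trials and probes
#'
#' Applies the exclusion rules used for per-trial pupil features: a trial is
#' excluded when more than `trial_max` (strictly) of its feature window is
#' missing; a probe is excluded when more than `probe_max_excluded` of its
#' `n_back` preceding trials are excluded; a whole dataset is flagged when
#' more than half of all samples are missing.
#'
#' @param trial_features data frame with `trial`, `onset_ms` and
#'   `missing_frac` (e.g. from [traditional_features()] or
#'   [decompose_tonic_phasic()]`$features`).
#' @param probe_times_ms probe onset times, ms.
#' @param trial_max maximum tolerated missing fraction per trial (0.20).
#' @param probe_max_excluded maximum tolerated excluded trials per probe
#'   (10).
#' @param n_back number of pre-probe trials inspected (25).
#' @param overall_missing overall missing fraction of the recording (for
#'   the dataset-level flag), or `NA` to skip.
#' @return list: `trial_features` with an `excluded` column, `probes` data
#'   frame (`probe_time_ms`, `n_excluded`, `excluded`), and
#'   `dataset_flagged`.
#' @export
screen_pupil_trials <- function(trial_features, probe_times_ms = numeric(0),
                                trial_max = 0.20, probe_max_excluded = 10L,
                                n_back = 25L, overall_missing = NA_real_) {
  stopifnot(is.data.frame(trial_features),
            all(c("onset_ms", "missing_frac") %in% names(trial_features)))
  tf <- trial_features
  tf$excluded <- !is.na(tf$missing_frac) & tf$missing_frac > trial_max
  tf$excluded[is.na(tf$missing_frac)] <- TRUE

  probes <- data.frame(probe_time_ms = probe_times_ms,
                       n_excluded = rep(NA_integer_, length(probe_times_ms)),
                       excluded = rep(NA, length(probe_times_ms)))
  for (i in seq_along(probe_times_ms)) {
    prior <- which(tf$onset_ms < probe_times_ms[i])
    prior <- utils::tail(prior, n_back)
    probes$n_excluded[i] <- sum(tf$excluded[prior])
    probes$excluded[i] <- probes$n_excluded[i] > probe_max_excluded
  }
  list(trial_features = tf, probes = probes,
       dataset_flagged = isTRUE(overall_missing > 0.5))
}
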