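test_that("PRF shape: zero at origin, unit peak at t_max", {
  expect_equal(prf(0), 0)
  expect_equal(prf(900), 1)
  expect_equal(prf(-100), 0)
  tt <- seq(0, 4000, by = 0.5)
  expect_equal(tt[which.max(prf(tt))], 900)
  expect_true(all(prf(tt) >= 0))
  # alternative shape parameters keep the unit-peak normalization
  expect_equal(prf(600, n = 8, t_max = 600), 1)
})

test_that("butterworth magnitude response matches the closed form", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  for (f0 in c(0.5, 20)) {
    x <- sin(2 * pi * f0 * t)
    y <- butterworth(x, fs, high = 5, order = 4)
    mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
    gain <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
    # squared magnitude of an order-4 butterworth (forward-backward)
    expected <- 1 / (1 + (f0 / 5)^8)
    expect_equal(gain, expected, tolerance = 0.05)
  }
  # DC passes untouched; cutoff at/above Nyquist rejected
  expect_equal(butterworth(rep(2, 100), fs, high = 5), rep(2, 100),
               tolerance = 1e-9)
  expect_error(butterworth(rnorm(100), fs, high = 250), "Nyquist")
})

test_that("trough detection honors the prominence criterion", {
  x <- c(5, 4, 5, 1, 5, 4.9, 5, 0, 5)
  expect_equal(find_troughs(x, prominence = 2), c(4L, 8L))
  expect_equal(find_troughs(x, prominence = 0.05), c(2L, 4L, 6L, 8L))
  expect_length(find_troughs(seq_len(10), prominence = 0), 0L)
})

test_that("blink detection recovers inserted gaps (forward-inverse)", {
  rec <- pupil_fixture(seed = 101, n_tones = 60, noise_sd = 0.01,
                       n_blinks = 6)
  # regenerate until blinks present (rpois could give 0; seed fixed so no)
  expect_gt(nrow(rec$blink_intervals), 0)
  iv <- detect_blinks(rec, margin_ms = 20)
  # truth expanded by the generator's 20 ms occlusion ramps
  truth <- cbind(rec$blink_intervals[, 1] - 20, rec$blink_intervals[, 2] + 20)
  jacc <- interval_jaccard(iv, truth, rec$time_ms)
  expect_gt(jacc, 0.8)
  # every missing sample is inside a detected interval
  miss_t <- rec$time_ms[rec$missing == 1]
  inside <- vapply(miss_t, function(tm) {
    any(iv[, 1] <= tm & iv[, 2] >= tm)
  }, logical(1))
  expect_true(all(inside))
})

test_that("clean traces yield no detections; infinite thresholds disable them", {
  rec <- pupil_fixture(seed = 102, n_tones = 20, noise_sd = 0, n_blinks = 0)
  expect_equal(nrow(detect_blinks(rec)), 0L)
  rec2 <- pupil_fixture(seed = 103, n_tones = 20, noise_sd = 0.01, n_blinks = 2)
  iv <- detect_blinks(rec2, vel_onset = -Inf)
  # only the truly missing samples get wrapped
  expect_true(all(rec2$missing[rec2$time_ms %in% rec2$blink_intervals[, 1]] == 1))
  expect_equal(nrow(iv), nrow(rec2$blink_intervals))
})

test_that("merge-and-interpolate merges < 100 ms gaps and is exact on ramps", {
  fs <- 500
  n <- 2500
  rec <- structure(list(time_ms = (seq_len(n) - 1) * 2, fs = fs,
                        diameter = seq(5, 6, length.out = n),
                        missing = integer(n),
                        blink_intervals = matrix(numeric(0), 0, 2)),
                   class = "pupil_recording")
  iv <- rbind(c(1000, 1200), c(1250, 1400), c(1600, 1700))
  out <- merge_and_interpolate(rec, iv, gap_ms = 100)
  # first two merge (50 ms apart), third stays (200 ms after second)
  expect_equal(nrow(out$blink_intervals), 2L)
  expect_equal(out$blink_intervals[1, ], c(1000, 1400), ignore_attr = TRUE)
  # linear interpolation reproduces the linear ramp exactly
  expect_equal(out$diameter, rec$diameter, tolerance = 1e-9)
  # mask marks interpolated samples
  expect_true(all(out$missing[out$time_ms >= 1000 & out$time_ms <= 1400] == 1))
  expect_error(merge_and_interpolate(rec, cbind(0, max(rec$time_ms))),
               "whole recording")
})

test_that("traditional features: constant trace and single-event closed form", {
  ev <- data.frame(time_ms = 3000, kind = "tone")
  flat <- simulate_pupil(ev, baseline = 5, tonic_sd = 0, amp_mean = 0,
                         amp_sd = 0, noise_sd = 0, n_blinks = 0, seed = 1)
  tf <- traditional_features(flat, onsets_ms = c(1000, 2000, 3000))
  expect_true(all(abs(tf$response) < 1e-12))
  expect_true(all(abs(tf$baseline - 5) < 1e-12))

  one <- simulate_pupil(ev, baseline = 5, tonic_sd = 0, amp_mean = 1,
                        amp_sd = 0, noise_sd = 0, n_blinks = 0, seed = 1)
  tf1 <- traditional_features(one, onsets_ms = 3000)
  # closed form: mean of h over [500, 700) minus ~0 baseline
  hh <- mean(prf(seq(500, 700 - 2, by = 2)))
  expect_equal(tf1$response, hh, tolerance = 0.01)
  # window outside the record is flagged
  tf2 <- traditional_features(one, onsets_ms = c(50, 3000))
  expect_true(tf2$flagged[1])
})

test_that("traditional baselines inflate under overlapping events", {
  rec <- pupil_fixture(seed = 104, n_tones = 80, noise_sd = 0, tonic_sd = 0)
  on <- rec$ground_truth$event_times_ms
  tf <- traditional_features(rec, onsets_ms = on[20:60])
  true_tonic <- mean(rec$ground_truth$tonic)
  expect_gt(mean(tf$baseline), true_tonic + 0.1)
})

test_that("decomposition recovers tonic and amplitudes (forward-inverse)", {
  rec <- pupil_fixture(seed = 105, n_tones = 80, noise_sd = 0.01,
                       preprocessed = TRUE)
  dec <- decompose_tonic_phasic(rec, rec$ground_truth$event_times_ms)
  truth_tonic <- approx(rec$time_ms, rec$ground_truth$tonic,
                        xout = dec$time_ms)$y
  expect_gt(cor(dec$tonic, truth_tonic), 0.95)
  expect_gt(cor(dec$coefficients, rec$ground_truth$amplitudes,
                method = "spearman"), 0.8)
  # non-negativity and lower-envelope contract at trough points
  expect_true(all(dec$coefficients >= 0))
  at_troughs <- dec$trough_idx
  expect_true(all(dec$tonic[at_troughs] <= dec$signal[at_troughs] + 1e-6))
  # modeling responses must not hurt the fit
  expect_lte(dec$rss_full, dec$rss_tonic_only + 1e-9)
  expect_false(dec$fallback)
})

test_that("decomposition: zero-amplitude events give near-zero coefficients", {
  # slow, nearly flat tonic: without phasic structure the trough envelope
  # must reproduce the trace and leave nothing for the PRF regressors
  rec <- pupil_fixture(seed = 106, n_tones = 60, noise_sd = 0.005,
                       amp_mean = 0, amp_sd = 0, tonic_sd = 0.02,
                       preprocessed = TRUE)
  dec <- decompose_tonic_phasic(rec, rec$ground_truth$event_times_ms)
  expect_lt(max(dec$coefficients), 0.02)
  tt <- approx(rec$time_ms, rec$ground_truth$tonic, xout = dec$time_ms)$y
  expect_lt(sqrt(mean((dec$tonic - tt)^2)), 0.01)
})

test_that("adding a constant shifts tonic, leaves coefficients unchanged", {
  rec <- pupil_fixture(seed = 107, n_tones = 50, noise_sd = 0.01,
                       preprocessed = TRUE)
  rec2 <- rec
  rec2$diameter <- rec$diameter + 3
  d1 <- decompose_tonic_phasic(rec, rec$ground_truth$event_times_ms)
  d2 <- decompose_tonic_phasic(rec2, rec$ground_truth$event_times_ms)
  expect_equal(d2$tonic, d1$tonic + 3, tolerance = 1e-6)
  expect_equal(d2$coefficients, d1$coefficients, tolerance = 1e-6)
})

test_that("traditional and novel tonic agree; phasic estimates diverge", {
  rec <- pupil_fixture(seed = 108, n_tones = 90, noise_sd = 0.01,
                       preprocessed = TRUE)
  on <- rec$ground_truth$event_times_ms
  trial_on <- on[10:80]
  dec <- decompose_tonic_phasic(rec, on, trial_onsets_ms = trial_on)
  tf <- traditional_features(rec, onsets_ms = trial_on)
  r_tonic <- cor(tf$baseline, dec$features$tonic_novel)
  r_phasic <- cor(tf$response, dec$features$phasic_novel)
  expect_gt(r_tonic, 0.9)
  expect_lt(r_phasic, r_tonic - 0.2)
})

test_that("NNLS satisfies the KKT conditions and matches lm on interior solutions", {
  set.seed(109)
  A <- matrix(rnorm(200 * 12), 200)
  xtrue <- runif(12, 0.2, 2)            # strictly positive: interior optimum
  b <- A %*% xtrue + rnorm(200, 0, 0.01)
  r <- nnls(A, b)
  ls <- coef(lm(b ~ A - 1))
  if (all(ls > 0)) expect_equal(unname(r$x[, 1]), unname(ls), tolerance = 1e-8)
  # general case with active constraints
  b2 <- A %*% c(rep(0, 6), xtrue[7:12]) - A[, 1] * 3 + rnorm(200, 0, 0.01)
  r2 <- nnls(A, b2)
  expect_true(all(r2$x >= 0))
  g <- r2$gradient
  expect_true(all(abs(g[r2$x > 1e-10]) < 1e-6))   # stationarity on support
  expect_true(all(g[r2$x <= 1e-10] < 1e-6))       # feasibility of the rest
})

test_that("screening rules reproduce the exact exclusion boundaries", {
  # the probe at 31*750 looks back at the last 25 prior trials: 6..30
  tf <- data.frame(trial = 1:30, onset_ms = (1:30) * 750,
                   missing_frac = rep(0, 30))
  tf$missing_frac[10] <- 0.21   # excluded (> 20%)
  tf$missing_frac[11] <- 0.20   # retained (boundary)
  sc <- screen_pupil_trials(tf, probe_times_ms = 31 * 750)
  expect_true(sc$trial_features$excluded[10])
  expect_false(sc$trial_features$excluded[11])
  expect_equal(sc$probes$n_excluded, 1L)
  expect_false(sc$probes$excluded)

  # probe boundary: 11 excluded trials in the window -> out, 10 -> kept
  tf11 <- tf; tf11$missing_frac[] <- 0; tf11$missing_frac[6:16] <- 0.5
  expect_true(screen_pupil_trials(tf11, 31 * 750)$probes$excluded)
  tf10 <- tf; tf10$missing_frac[] <- 0; tf10$missing_frac[6:15] <- 0.5
  expect_false(screen_pupil_trials(tf10, 31 * 750)$probes$excluded)

  # clean session: zero exclusions; dataset flag at > 50% missing
  clean_tf <- data.frame(trial = 1:4, onset_ms = (1:4) * 750,
                         missing_frac = 0)
  clean <- screen_pupil_trials(clean_tf, numeric(0), overall_missing = 0.1)
  expect_false(any(clean$trial_features$excluded))
  expect_false(clean$dataset_flagged)
  expect_true(screen_pupil_trials(clean_tf, numeric(0),
                                  overall_missing = 0.6)$dataset_flagged)
})

test_that("select_eye picks the cleaner trace", {
  a <- pupil_fixture(seed = 110, n_tones = 20, n_blinks = 0)
  b <- pupil_fixture(seed = 111, n_tones = 20, n_blinks = 6)
  expect_identical(select_eye(list(b, a)), a)
})

test_that("full preprocessing chain runs end to end on a blinky recording", {
  rec <- pupil_fixture(seed = 112, n_tones = 60, noise_sd = 0.02, n_blinks = 5)
  iv <- detect_blinks(rec, margin_ms = 20)
  rec2 <- merge_and_interpolate(rec, iv)
  expect_false(anyNA(rec2$diameter))
  rec3 <- pupil_lowpass(rec2)
  dec <- decompose_tonic_phasic(rec3, rec$ground_truth$event_times_ms)
  expect_true(all(dec$coefficients >= 0))
  expect_gt(cor(dec$tonic, approx(rec$time_ms, rec$ground_truth$tonic,
                                  xout = dec$time_ms)$y), 0.8)
})
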