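test_that("band-pass preprocessing matches the expected magnitude response", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  gain_at <- function(f0) {
    x <- sin(2 * pi * f0 * t)
    y <- eeg_preprocess(x, fs = fs)
    sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  }
  expect_gt(gain_at(10), 0.95)          # passband
  expect_lt(gain_at(45), 0.2)           # above the 30 Hz edge
  # DC offset removed by the 0.5 Hz highpass
  y <- eeg_preprocess(rep(4, 3000), fs = fs)
  expect_lt(max(abs(y[mid])), 0.1)
  expect_error(eeg_preprocess(rnorm(100), fs = fs, band = c(0.5, 300)),
               "Nyquist")
})

test_that("amplitude-criterion rejection drops exactly the spiked epochs", {
  ep <- simulate_eeg_epochs(n_epochs = 30, noise_sd = 5, seed = 1)
  clean <- reject_epochs(ep, threshold = 100)
  expect_equal(attr(clean, "n_rejected"), 0L)
  ep$data[10, 1, 7] <- 500
  rej <- reject_epochs(ep, threshold = 100)
  expect_equal(attr(rej, "n_rejected"), 1L)
  expect_equal(dim(rej$data)[3], 29L)
  # infinite threshold is the identity
  expect_equal(dim(reject_epochs(ep, threshold = Inf)$data)[3], 30L)
  ep$data[] <- 1e4
  expect_error(reject_epochs(ep, 100), "all epochs")
})

test_that("MMN forward-inverse: injected deflection is recovered with inversion", {
  # averaging scale chosen so residual noise after averaging is well below
  # the 2 uV deflection: peak picking on a noisy difference waveform biases
  # the amplitude negative by about one standard error
  std <- simulate_eeg_epochs(n_epochs = 300, noise_sd = 0.5, seed = 2)
  odd <- simulate_eeg_epochs(n_epochs = 300, noise_sd = 0.5,
                             oddball = rep(TRUE, 300), erp_amp = -2,
                             erp_latency_ms = 150, seed = 3)
  m <- mmn(std, odd)
  expect_lt(abs(m$mean_amplitude - (-2)) / 2, 0.10)
  expect_lt(abs(m$peak_latency_ms - 150), 40)
  expect_true(m$polarity_inverted)

  # identical conditions: difference near zero, no spurious deep negativity
  odd0 <- simulate_eeg_epochs(n_epochs = 300, noise_sd = 0.5,
                              oddball = rep(TRUE, 300), erp_amp = 0, seed = 4)
  m0 <- mmn(std, odd0)
  expect_lt(abs(m0$mean_amplitude), 0.4)
  expect_error(mmn(std, simulate_eeg_epochs(n_epochs = 0, seed = 5)),
               "empty condition")
})

test_that("alpha power matches the analytic tapered-sinusoid oracle", {
  fs <- 500
  ep <- simulate_eeg_epochs(n_epochs = 1, window_ms = c(0, 1000), fs = fs,
                            channels = "posterior_1", noise_sd = 0,
                            alpha_amp = 2, alpha_hz = 10, seed = 6)
  p <- alpha_power(ep)
  # oracle: time-domain variance of the tapered, demeaned epoch (Parseval),
  # all of which sits at 10 Hz for a bin-centered sinusoid
  x <- ep$data[, 1, 1]
  n <- length(x)
  w <- ftrsgt:::tukey_window(n, 0.1)
  # a few percent of the tapered power leaks outside 8-12 Hz through the
  # near-rectangular window's sidelobes; the full-band identity is exact
  # (see the Parseval test below)
  expect_equal(p, mean(((x - mean(x)) * w)^2), tolerance = 0.05)

  # a 4 Hz sinusoid leaves the alpha band empty
  ep4 <- simulate_eeg_epochs(n_epochs = 1, window_ms = c(0, 1000), fs = fs,
                             channels = "posterior_1", noise_sd = 0,
                             alpha_amp = 2, alpha_hz = 4, seed = 7)
  expect_lt(alpha_power(ep4), 0.01 * p)
  # zero signal -> zero power
  ep0 <- simulate_eeg_epochs(n_epochs = 1, window_ms = c(0, 1000), fs = fs,
                             channels = "posterior_1", noise_sd = 0, seed = 8)
  expect_equal(alpha_power(ep0), 0)
})

test_that("Parseval sanity: full-band FFT power equals tapered variance", {
  ep <- simulate_eeg_epochs(n_epochs = 5, window_ms = c(0, 1000),
                            channels = "posterior_1", noise_sd = 3, seed = 9)
  total <- alpha_power(ep, band = c(0, ep$fs / 2))
  for (e in 1:5) {
    x <- ep$data[, 1, e]
    w <- ftrsgt:::tukey_window(length(x), 0.1)
    expect_equal(total[e], mean(((x - mean(x)) * w)^2), tolerance = 1e-9)
  }
})

test_that("alpha separates simulated mind-wandering from on-task epochs", {
  mw <- rep(c(TRUE, FALSE), each = 40)
  ep <- simulate_eeg_epochs(n_epochs = 80, window_ms = c(0, 1000),
                            channels = "posterior_1", noise_sd = 3,
                            alpha_amp = ifelse(mw, 2.5, 0.8), seed = 10)
  p <- alpha_power(ep)
  expect_gt(mean(p[mw]), mean(p[!mw]))
})

test_that("Morlet power matches a direct-convolution oracle", {
  fs <- 250
  t <- seq(-1, 1, by = 1 / fs)
  x <- sin(2 * pi * 6 * t) + withr::with_seed(11, rnorm(length(t), 0, 0.3))
  pw <- morlet_power(x, fs, freqs = 6, cycles = 3)[, 1]
  # oracle: naive O(n m) time-domain complex convolution
  wv <- ftrsgt:::morlet_wavelet(6, fs, 3)
  m <- length(wv)
  half <- (m - 1L) %/% 2L
  xp <- c(rep(0, m), x, rep(0, m))
  direct <- vapply(seq_along(x), function(i) {
    seg <- xp[(i + m - half):(i + m - half + m - 1L)]
    Mod(sum(seg * rev(wv)))^2
  }, numeric(1))
  expect_equal(pw, direct, tolerance = 1e-8)
  # steady-state power of a matched unit sinusoid is flat and positive
  mid <- seq(round(length(t) * 0.4), round(length(t) * 0.6))
  expect_lt(sd(pw[mid]) / mean(pw[mid]), 0.2)
})

test_that("midfrontal theta contrasts injected band differences", {
  high <- rep(c(TRUE, FALSE), each = 30)
  ep <- simulate_eeg_epochs(n_epochs = 60, window_ms = c(-1000, 1000),
                            channels = c("frontal_midline", "posterior_1"),
                            noise_sd = 3, theta_amp = ifelse(high, 2.5, 0.8),
                            seed = 12)
  th <- midfrontal_theta(ep)
  expect_length(th, 60L)
  expect_true(all(th >= 0))
  expect_gt(mean(th[high]), mean(th[!high]))
  # identical conditions: no systematic difference
  ep0 <- simulate_eeg_epochs(n_epochs = 60, window_ms = c(-1000, 1000),
                             channels = "frontal_midline", noise_sd = 3,
                             theta_amp = 1.5, seed = 13)
  th0 <- midfrontal_theta(ep0)
  expect_lt(abs(mean(th0[high]) - mean(th0[!high])),
            5 * sd(th0) / sqrt(30))
})

test_that("median split balances condition counts within subjects", {
  val <- withr::with_seed(14, rnorm(25))
  subj <- rep(1:3, c(9, 8, 8))
  hi <- median_split(val, subj)
  for (s in 1:3) {
    n_hi <- sum(hi[subj == s])
    n_lo <- sum(!hi[subj == s])
    expect_lte(abs(n_hi - n_lo), 1L)
  }
})
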