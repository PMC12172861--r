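# shared fixtures, built in code at test time

# a short two-block design so tests stay fast
small_design <- function(n_tones = c(160L, 160L), n_probes = c(2L, 2L),
                         oddball_blocks = integer(0)) {
  task_design(n_tones_per_block = n_tones, n_probes_per_block = n_probes,
              oddball_blocks = oddball_blocks)
}

# independent brute-force ApEn oracle: naive pairwise block matching,
# self-matches included, natural log
apen_oracle <- function(x, m) {
  x <- as.character(x)
  phi_naive <- function(mm) {
    n <- length(x)
    nb <- n - mm + 1L
    blocks <- vapply(seq_len(nb),
                     function(i) paste(x[i:(i + mm - 1L)], collapse = ""),
                     character(1))
    mean(log(vapply(blocks, function(b) sum(blocks == b), numeric(1)) / nb))
  }
  phi_naive(m) - phi_naive(m + 1L)
}

# Jaccard overlap of two interval sets, evaluated on the sample grid
interval_jaccard <- function(a, b, time_ms) {
  ina <- rep(FALSE, length(time_ms))
  inb <- rep(FALSE, length(time_ms))
  for (i in seq_len(nrow(a))) ina[time_ms >= a[i, 1] & time_ms <= a[i, 2]] <- TRUE
  for (i in seq_len(nrow(b))) inb[time_ms >= b[i, 1] & time_ms <= b[i, 2]] <- TRUE
  sum(ina & inb) / sum(ina | inb)
}

# independent ML ordered probit (no random effects) by numerical
# optimization, used as the oracle for the Bayesian fit at large n
ml_ordered_probit <- function(y, X, K) {
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    raw <- par[-seq_len(ncol(X))]
    tau <- cumsum(c(raw[1], exp(raw[-1])))
    eta <- as.numeric(X %*% beta)
    hi <- c(tau, Inf)[y]
    lo <- c(-Inf, tau)[y]
    -sum(log(pmax(pnorm(hi - eta) - pnorm(lo - eta), 1e-300)))
  }
  p0 <- c(rep(0, ncol(X)), qnorm(cumsum(tabulate(y, K) / length(y)))[1],
          rep(0, K - 2L))
  opt <- stats::optim(p0, nll, method = "BFGS", control = list(maxit = 500))
  beta <- opt$par[seq_len(ncol(X))]
  raw <- opt$par[-seq_len(ncol(X))]
  list(beta = beta, tau = cumsum(c(raw[1], exp(raw[-1]))))
}

# pupil fixture: event-dense recording with known tonic and amplitudes.
# Slow tonic drift is set larger than single-event responses, as in real
# pupillometry. `preprocessed = TRUE` applies the standard 5 Hz lowpass
# (only valid for gap-free fixtures).
pupil_fixture <- function(seed = 3, n_tones = 80L, noise_sd = 0.01,
                          n_blinks = 0, amp_mean = 0.3, amp_sd = 0.1,
                          tonic_sd = 0.15, preprocessed = FALSE) {
  ev <- data.frame(time_ms = 1000 + (seq_len(n_tones) - 1) * 750,
                   kind = "tone")
  rec <- simulate_pupil(ev, noise_sd = noise_sd, n_blinks = n_blinks,
                        amp_mean = amp_mean, amp_sd = amp_sd,
                        tonic_sd = tonic_sd, seed = seed)
  if (preprocessed) rec <- pupil_lowpass(rec)
  rec
}

two_block_formula_test <- function() {
  response ~ bv + ae + bv_ae + trial + block2 + group + group:block2
}

prepare_for_fit <- function(ev) {
  feats <- extract_probe_features(ev, n_back = 25)
  feats <- feats[feats$usable, ]
  feats$bv_ae <- feats$bv * feats$ae
  feats$group <- as.integer(feats$group == "real")
  feats$block2 <- as.numeric(feats$block == 2L)
  feats
}
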