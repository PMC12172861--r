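#' Latent attentional-state process parameters
#'
#' The generator's stand-in for the mind-wandering construct that the
#' ordered-probit model measures: a mean-reverting AR(1) process on the tone
#' grid plus a linear time-on-task drift. Higher state values mean more
#' mind wandering, producing noisier tap timing and more repetitive button
#' sequences.
#'
#' Defaults give the state a stationary SD near 0.8 with a decorrelation
#' time of roughly 2000 tones (~25 minutes), i.e. attentional episodes that
#' drift on the scale of minutes -- long relative to the 25-tap pre-probe
#' windows, as self-reported mind-wandering episodes are.
#'
#' @param ar_coefficient AR(1) coefficient per tone, |phi| < 1.
#' @param innovation_sd standard deviation of AR(1) innovations.
#' @param time_on_task_slope drift per standardized tone index.
#' @param mean stationary mean of the AR(1) component.
#' @return object of class `latent_state` (named list).
#' @export
latent_state <- function(ar_coefficient = 0.9995, innovation_sd = 0.025,
                         time_on_task_slope = 0.5, mean = 0) {
  stopifnot(abs(ar_coefficient) < 1, innovation_sd >= 0)
  structure(list(ar_coefficient = ar_coefficient,
                 innovation_sd = innovation_sd,
                 time_on_task_slope = time_on_task_slope,
                 mean = mean),
            class = "latent_state")
}

#' Ground-truth parameters of the probe-response model
#'
#' Houses the latent-scale fixed effects, ordered cutpoints and
#' random-intercept standard deviations used both to generate synthetic probe
#' responses and as the recovery target in calibration experiments. Defaults
#' are the effect sizes characteristic of FT-RSGT mind-wandering studies:
#' BV +0.19, AE -0.07, BV x AE 0, Trial +0.81, stimulation block +0.27,
#' group -0.05, group x block 0.
#'
#' @param beta named numeric vector of latent-scale coefficients.
#' @param thresholds 3 strictly increasing cutpoints for the 4-point scale.
#' @param sd_subject subject random-intercept SD.
#' @param sd_subject_block block-within-subject random-intercept SD.
#' @return object of class `ground_truth` (named list).
#' @export
ground_truth <- function(beta = c(bv = 0.19, ae = -0.07, bv_ae = 0.00,
                                  trial = 0.81, block2 = 0.27,
                                  group = -0.05, group_block2 = 0.00),
                         thresholds = c(-0.5, 0.5, 1.5),
                         sd_subject = 0.5,
                         sd_subject_block = 0.3) {
  stopifnot(all(diff(thresholds) > 0), sd_subject >= 0, sd_subject_block >= 0)
  structure(list(beta = beta, thresholds = thresholds,
                 sd_subject = sd_subject,
                 sd_subject_block = sd_subject_block),
            class = "ground_truth")
}

# AR(1) + linear drift, simulated on the tone grid. Initialized at the
# stationary distribution so the trajectory has finite, constant variance.
simulate_latent_state <- function(n, state) {
  phi <- state$ar_coefficient
  s <- numeric(n)
  stat_sd <- state$innovation_sd / sqrt(1 - phi^2)
  s[1] <- stats::rnorm(1, 0, stat_sd)
  innov <- stats::rnorm(n - 1, 0, state$innovation_sd)
  for (t in seq_len(n - 1L)) s[t + 1L] <- phi * s[t] + innov[t]
  idx <- seq_len(n)
  z_idx <- (idx - mean(idx)) / stats::sd(idx)
  state$mean + s + state$time_on_task_slope * z_idx
}

#' Simulate taps and probe responses for a task event log
#'
#' Fills an event log with one tap per tone (minus omissions, plus
#' double-taps) and with ordered-probit probe responses, all driven by a
#' latent attentional state evolving on the tone grid:
#' * tap asynchrony ~ Normal(0, sigma(state)) with
#'   `sigma = tap_sd_ms * exp(tap_sd_gain * state)`, so timing gets noisier
#'   as the state (mind wandering) rises;
#' * buttons follow a two-symbol first-order Markov chain whose repetition
#'   probability is `plogis(qlogis(repetition_bias) + repetition_gain *
#'   state)` - at bias 0.5 and gain 0 the sequence is an i.i.d. fair coin;
#' * each probe response is an ordered-probit draw with latent mean
#'   `state_coef * state(probe) + u_subject + u_subject_block`, cut at the
#'   ground-truth thresholds.
#'
#' @param events event log from [simulate_task_events()].
#' @param truth [ground_truth()] parameters (thresholds, random-effect SDs).
#' @param state [latent_state()] process parameters.
#' @param seed integer seed.
#' @param tap_sd_ms baseline tap asynchrony SD in ms.
#' @param tap_sd_gain log-scale gain of asynchrony SD per state unit.
#' @param repetition_bias Markov repetition probability at state 0.
#' @param repetition_gain logit-scale gain of repetition per state unit.
#' @param omission_rate,double_tap_rate per-tone probabilities of a missing
#'   tap and of an extra tap (defaults 1% each).
#' @param state_coef loading of the latent state on the probe latent mean.
#' @return the event log with tap rows inserted and probe responses filled;
#'   the per-tone latent state, tap asynchronies and random intercepts are
#'   attached as attribute `truth`.
#' @export
simulate_behavior <- function(events, truth = ground_truth(),
                              state = latent_state(), seed = NULL,
                              tap_sd_ms = 50, tap_sd_gain = 0.4,
                              repetition_bias = 0.5, repetition_gain = 1.0,
                              omission_rate = 0.01, double_tap_rate = 0.01,
                              state_coef = 1.0) {
  stopifnot(inherits(truth, "ground_truth"), inherits(state, "latent_state"))
  if (min(omission_rate, double_tap_rate) < 0 ||
      max(omission_rate, double_tap_rate) >= 1) {
    stop("omission and double-tap rates must be in [0, 1)")
  }
  if (repetition_bias <= 0 || repetition_bias >= 1) {
    stop("`repetition_bias` must be strictly inside (0, 1)")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  tones <- events[events$kind == "tone", , drop = FALSE]
  tones <- tones[order(tones$time_ms), , drop = FALSE]
  n <- nrow(tones)
  if (n == 0L) stop("event log has no tones")
  s <- simulate_latent_state(n, state)

  # taps: asynchrony, omissions, double-taps
  sd_t <- tap_sd_ms * exp(tap_sd_gain * s)
  asyn <- stats::rnorm(n, 0, sd_t)
  omit <- stats::runif(n) < omission_rate
  extra <- stats::runif(n) < double_tap_rate

  # button Markov chain over the kept taps
  p_rep <- stats::plogis(stats::qlogis(repetition_bias) + repetition_gain * s)
  button <- character(n)
  button[1] <- sample(c("L", "R"), 1L)
  flip <- stats::runif(n) >= p_rep          # TRUE -> switch button
  for (t in seq_len(n - 1L)) {
    button[t + 1L] <- if (flip[t + 1L]) setdiff(c("L", "R"), button[t]) else button[t]
  }

  tap_time <- tones$time_ms + asyn
  taps <- data.frame(
    time_ms = tap_time[!omit], kind = "tap", block = tones$block[!omit],
    oddball = 0L, button = button[!omit], response = NA_integer_,
    subject_id = tones$subject_id[!omit], group = tones$group[!omit],
    stringsAsFactors = FALSE
  )
  dbl <- which(extra & !omit)
  if (length(dbl)) {
    taps2 <- data.frame(
      time_ms = tap_time[dbl] + stats::runif(length(dbl), 20, 80),
      kind = "tap", block = tones$block[dbl], oddball = 0L,
      button = button[dbl], response = NA_integer_,
      subject_id = tones$subject_id[dbl], group = tones$group[dbl],
      stringsAsFactors = FALSE
    )
    taps <- rbind(taps, taps2)
  }

  # probe responses: ordered-probit draw at the state value of the last tone
  # before the probe
  u_s <- stats::rnorm(1, 0, truth$sd_subject)
  blocks <- sort(unique(events$block))
  u_sb <- stats::rnorm(length(blocks), 0, truth$sd_subject_block)
  names(u_sb) <- as.character(blocks)

  is_probe <- events$kind == "probe"
  pr_t <- events$time_ms[is_probe]
  pr_block <- events$block[is_probe]
  if (any(is_probe)) {
    idx <- findInterval(pr_t, tones$time_ms)
    idx[idx < 1L] <- 1L
    eta <- state_coef * s[idx] + u_s + u_sb[as.character(pr_block)]
    ystar <- eta + stats::rnorm(length(eta))
    events$response[is_probe] <-
      as.integer(findInterval(ystar, truth$thresholds)) + 1L
  }

  out <- rbind(events, taps)
  out <- out[order(out$time_ms), ]
  rownames(out) <- NULL
  attr(out, "design") <- attr(events, "design")
  attr(out, "truth") <- list(
    state = s, tone_time_ms = tones$time_ms, asynchrony_ms = asyn,
    omitted = omit, doubled = extra, u_subject = u_s, u_subject_block = u_sb
  )
  out
}

#' Simulate a multi-subject FT-RSGT study
#'
#' Convenience wrapper: one [simulate_task_events()] +
#' [simulate_behavior()] call per subject, with subjects split evenly
#' between sham and real stimulation groups. Per-subject seeds are derived
#' from `seed` so the study is reproducible as a whole.
#'
#' @param n_subjects number of subjects (alternating sham/real).
#' @param design a [task_design()].
#' @param truth,state,seed,... passed to the per-subject generators.
#' @return combined event log for all subjects.
#' @export
simulate_study <- function(n_subjects, design = task_design(),
                           truth = ground_truth(), state = latent_state(),
                           seed = NULL, ...) {
  if (!is.null(seed)) withr::local_seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  logs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    grp <- if (i %% 2L == 1L) "sham" else "real"
    ev <- simulate_task_events(design, seed = seeds[i],
                               subject_id = sprintf("s%03d", i), group = grp)
    logs[[i]] <- simulate_behavior(ev, truth = truth, state = state,
                                   seed = seeds[i] %% 1000000L + i, ...)
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}
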