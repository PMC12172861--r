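#' Simulate probe responses directly from the ordered-probit generative model
#'
#' Draws a two-group dataset on the scale the model is fit on: z-scored BV
#' and AE covariates are i.i.d. standard normal, Trial is the within-block
#' probe index standardized over the dataset, Block and Group are
#' treatment-coded indicators, random intercepts for subject and
#' block-within-subject come from the ground-truth SDs, and responses are
#' latent-normal draws cut at the ground-truth thresholds. This is the
#' dataset generator used by parameter-recovery calibration and by the
#' simulation-based power analysis.
#'
#' @param n_per_group subjects per group (sham / real).
#' @param probes_per_block integer vector of probes per block per subject;
#'   the task's two-block layout is `c(10, 20)`, recovery experiments use
#'   `c(20, 20)`.
#' @param truth a [ground_truth()]; `beta` must contain `bv`, `ae`, `bv_ae`,
#'   `trial`, `group` and per-block terms `block<k>` / `group_block<k>` for
#'   blocks beyond the first.
#' @param seed integer seed.
#' @return data frame with columns `subject_id`, `group` (0/1), `block`,
#'   `trial`, `bv`, `ae`, `bv_ae`, `response`, plus `block<k>` indicator
#'   columns; the latent state is not observable, matching real data.
#' @export
simulate_probe_data <- function(n_per_group = 50L,
                                probes_per_block = c(10L, 20L),
                                truth = ground_truth(), seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.null(seed)) withr::local_seed(seed)
  n_blocks <- length(probes_per_block)
  n_subj <- 2L * n_per_group
  per_subj <- sum(probes_per_block)

  subject_id <- rep(sprintf("s%03d", seq_len(n_subj)), each = per_subj)
  group <- rep(rep(c(0L, 1L), each = n_per_group), each = per_subj)
  block <- rep(rep(seq_len(n_blocks), times = probes_per_block), times = n_subj)
  probe_index <- rep(unlist(lapply(probes_per_block, seq_len)), times = n_subj)
  n <- length(block)

  bv <- stats::rnorm(n)
  ae <- stats::rnorm(n)
  trial <- (probe_index - mean(probe_index)) / stats::sd(probe_index)

  dat <- data.frame(subject_id = subject_id, group = group, block = block,
                    trial = trial, bv = bv, ae = ae, bv_ae = bv * ae,
                    stringsAsFactors = FALSE)

  eta <- truth$beta[["bv"]] * bv + truth$beta[["ae"]] * ae +
    truth$beta[["bv_ae"]] * dat$bv_ae + truth$beta[["trial"]] * trial +
    truth$beta[["group"]] * group
  for (b in seq_len(n_blocks)[-1]) {
    ind <- as.numeric(block == b)
    dat[[paste0("block", b)]] <- ind
    eta <- eta + truth$beta[[paste0("block", b)]] * ind
    gb <- paste0("group_block", b)
    if (!is.null(truth$beta[[gb]])) {
      eta <- eta + truth$beta[[gb]] * ind * group
    }
  }

  u_s <- stats::rnorm(n_subj, 0, truth$sd_subject)
  sb_key <- paste(subject_id, block)
  sb_levels <- unique(sb_key)
  u_sb <- stats::rnorm(length(sb_levels), 0, truth$sd_subject_block)
  names(u_sb) <- sb_levels

  ystar <- eta + u_s[match(subject_id, unique(subject_id))] +
    u_sb[sb_key] + stats::rnorm(n)
  dat$response <- as.integer(findInterval(ystar, truth$thresholds)) + 1L
  dat
}

two_block_formula <- function() {
  response ~ bv + ae + bv_ae + trial + block2 + group + group:block2
}

#' Decision rule: did a study "succeed"?
#'
#' TRUE iff at least `level` of the posterior draws of `parameter` fall on
#' the expected side of zero (the boundary counts as success).
#'
#' @param fit a `probit_fit`.
#' @param parameter coefficient name.
#' @param direction `"+"` or `"-"`, the expected sign.
#' @param level posterior mass required (default 0.95).
#' @return logical scalar.
#' @export
study_success <- function(fit, parameter, direction = c("-", "+"),
                          level = 0.95) {
  direction <- match.arg(direction)
  d <- probit_draws(fit, parameter)
  frac <- if (direction == "-") mean(d < 0) else mean(d > 0)
  frac >= level
}

#' Simulation-based power of the 95%-direction decision rule
#'
#' For each simulation: generate a two-group dataset from the generative
#' ordered-probit model with the group-by-block coefficient set to `b`
#' (nuisance parameters from `truth`), fit the model back with a reduced
#' sampler (the fit-back spec), and apply [study_success()]. Power is the
#' proportion of successes; its binomial standard error is attached.
#'
#' @param b effect size: the `group_block2` coefficient, latent probit
#'   scale.
#' @param n_per_group subjects per group in each simulated study.
#' @param n_sims number of simulated studies.
#' @param truth nuisance ground truth (fixed effects, thresholds, SDs); the
#'   group-block coefficient inside is overwritten with `b`.
#' @param probes_per_block per-subject probe layout (default `c(10, 20)`,
#'   the task's two-block design).
#' @param direction expected sign of the effect (default `"-"`).
#' @param level posterior-mass criterion.
#' @param fit_spec sampler settings for the fit-back loop; the default is a
#'   single short chain with the convergence gate off, an approximation
#'   documented in the methods vignette.
#' @param seed integer seed; per-simulation seeds derive from it.
#' @return list of class `power_estimate`: `power`, `se`, `n_success`,
#'   `n_sims`, `n_failed` (fit failures, excluded from the proportion).
#' @export
estimate_power <- function(b, n_per_group = 50L, n_sims = 100L,
                           truth = ground_truth(),
                           probes_per_block = c(10L, 20L),
                           direction = "-", level = 0.95,
                           fit_spec = probit_spec(chains = 1L, iter = 600L,
                                                  warmup = 300L,
                                                  gate = "none"),
                           seed = NULL) {
  stopifnot(n_sims >= 1L)
  if (!is.null(seed)) withr::local_seed(seed)
  truth$beta[["group_block2"]] <- b
  seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  success <- logical(n_sims)
  failed <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    res <- tryCatch({
      dat <- simulate_probe_data(n_per_group, probes_per_block, truth,
                                 seed = seeds[i])
      fit <- fit_ordered_probit(two_block_formula(), dat, spec = fit_spec)
      study_success(fit, "block2:group", direction = direction, level = level)
    }, error = function(e) NA)
    if (is.na(res)) failed[i] <- TRUE else success[i] <- res
  }
  n_ok <- sum(!failed)
  p <- if (n_ok > 0) sum(success) / n_ok else NA_real_
  structure(list(power = p, se = sqrt(p * (1 - p) / max(n_ok, 1)),
                 n_success = sum(success), n_sims = n_sims,
                 n_failed = sum(failed), b = b, n_per_group = n_per_group),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power %.1f%% (SE %.1f%%) at b = %g, N = %d/group [%d sims, %d failed]\n",
              100 * x$power, 100 * x$se, x$b, x$n_per_group, x$n_sims,
              x$n_failed))
  invisible(x)
}

#' Fit the parametric power surface
#'
#' Approximates simulated power over a grid of effect sizes `b` and
#' per-group sample sizes `N` with the asymptotic exponential growth model
#' `power(b, N) = 1 - exp(-(m0 + m1 b + m2 b^2) N)`. The fit linearizes to
#' `-log(1 - power) / N = m0 + m1 b + m2 b^2` and solves weighted least
#' squares with weights proportional to `n_sims * N`; cells with power 1
#' carry no information after the transform and are dropped.
#'
#' @param grid data frame with columns `b`, `N`, `power` and optionally
#'   `n_sims` (default weight 1).
#' @return object of class `power_surface`: coefficients `m0, m1, m2`, the
#'   grid, and residual sum of squares on the linearized scale.
#' @export
fit_power_surface <- function(grid) {
  stopifnot(is.data.frame(grid))
  need <- c("b", "N", "power")
  if (!all(need %in% names(grid))) {
    stop("grid needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(grid) < 3L) stop("need at least 3 grid cells with power < 1")
  if (is.null(grid$n_sims)) grid$n_sims <- 1
  use <- grid$power < 1 & grid$N > 0
  if (sum(use) < 3L) stop("need at least 3 grid cells with power < 1")
  g <- grid[use, ]
  yy <- -log(1 - g$power) / g$N
  fit <- stats::lm(yy ~ g$b + I(g$b^2), weights = g$n_sims * g$N)
  m <- unname(stats::coef(fit))
  structure(list(m0 = m[1], m1 = m[2], m2 = m[3], grid = grid,
                 rss = sum(stats::weighted.residuals(fit)^2)),
            class = "power_surface")
}

#' Predicted power from a fitted surface
#'
#' `1 - exp(-(m0 + m1 b + m2 b^2) N)`, clipped to `[0, 1)`; a non-positive
#' rate bracket predicts zero power.
#'
#' @param surface a `power_surface`.
#' @param b effect size(s).
#' @param N per-group sample size(s).
#' @return predicted power, recycled over `b` and `N`.
#' @export
predict_power <- function(surface, b, N) {
  stopifnot(inherits(surface, "power_surface"))
  rate <- surface$m0 + surface$m1 * b + surface$m2 * b^2
  pmax(0, 1 - exp(-pmax(rate, 0) * N))
}

#' Effect size achieving a target power at fixed N
#'
#' Solves `predict_power(surface, b, N) = target` for `b` on an interval by
#' root finding (the surface is quadratic in `b`, so callers pick the branch
#' via the search interval).
#'
#' @param surface a `power_surface`.
#' @param target desired power.
#' @param N per-group sample size.
#' @param interval search interval for `b`.
#' @return effect size `b`.
#' @export
solve_effect_size <- function(surface, target, N, interval = c(-2, 0)) {
  f <- function(b) predict_power(surface, b, N) - target
  stats::uniroot(f, interval = interval, tol = 1e-8)$root
}

#' @export
print.power_surface <- function(x, ...) {
  cat(sprintf("power surface: m0 = %.5f, m1 = %.5f, m2 = %.5f (rss %.3g, %d cells)\n",
              x$m0, x$m1, x$m2, x$rss, nrow(x$grid)))
  invisible(x)
}
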