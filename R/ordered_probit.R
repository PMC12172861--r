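#' Sampler and prior settings for the ordered-probit model
#'
#' @param chains number of MCMC chains (run sequentially).
#' @param iter post-warmup draws per chain.
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param prior_beta_sd Normal prior SD on fixed effects.
#' @param prior_tau_sd Normal prior SD on (ordered) cutpoints.
#' @param prior_sigma_sd half-Normal prior scale on random-intercept SDs.
#' @param rhat_max,ess_min convergence gate: largest admissible split R-hat
#'   and smallest admissible bulk ESS across reported parameters.
#' @param gate `"strict"` flags and warns on gate failure; `"none"` skips
#'   diagnostics entirely (used by the power-simulation fit-back loop).
#' @return list of class `probit_spec`.
#' @export
probit_spec <- function(chains = 4L, iter = 1000L, warmup = 500L,
                        prior_beta_sd = 2.5, prior_tau_sd = 5,
                        prior_sigma_sd = 1,
                        rhat_max = 1.01, ess_min = 400,
                        gate = c("strict", "none")) {
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup),
                 prior_beta_sd = prior_beta_sd, prior_tau_sd = prior_tau_sd,
                 prior_sigma_sd = prior_sigma_sd,
                 rhat_max = rhat_max, ess_min = ess_min,
                 gate = match.arg(gate)),
            class = "probit_spec")
}

#' Fit the hierarchical Bayesian ordered-probit regression
#'
#' Regresses an ordinal response (1..K) on fixed effects given by `formula`,
#' with random intercepts for subject and for block nested within subject,
#' via a latent-variable Gibbs sampler (data augmentation for the latent
#' responses and regression block; collapsed Metropolis updates for the
#' cutpoints). The latent residual SD is fixed at 1 and there is no global
#' intercept -- the cutpoints absorb it -- which identifies the probit scale.
#'
#' @param formula RHS-only or two-sided formula for the fixed effects, e.g.
#'   `response ~ bv * ae + trial + block + group + group:block`. Factors are
#'   treatment-coded; the intercept column is dropped after expansion.
#' @param data data frame with the model variables plus the grouping
#'   columns.
#' @param response name of the ordinal response column when `formula` has no
#'   LHS (default `"response"`).
#' @param subject,block names of the grouping columns.
#' @param spec a [probit_spec()].
#' @param ranef include the nested random intercepts (default TRUE; FALSE
#'   fits a plain ordered probit, mainly for validation against
#'   maximum-likelihood oracles).
#' @param seed integer seed (chains use the same stream sequentially).
#' @return object of class `probit_fit`: draws (list of per-chain matrices
#'   bound into iterations x chains x parameter arrays), posterior summary
#'   table, convergence diagnostics, Bayes R2 draws, and the model frame
#'   bookkeeping.
#' @export
fit_ordered_probit <- function(formula, data, response = "response",
                               subject = "subject_id", block = "block",
                               spec = probit_spec(), ranef = TRUE,
                               seed = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("no data to fit")
  if (!is.null(seed)) withr::local_seed(seed)

  if (length(formula) == 3L) {
    response <- deparse(formula[[2]])
  }
  y <- data[[response]]
  if (is.null(y)) stop("response column `", response, "` not found")
  y <- as.integer(y)
  if (anyNA(y)) stop("response contains NA; filter unusable rows first")
  K <- max(y)
  if (K < 2L || min(y) < 1L) stop("response must be integer categories 1..K")

  rhs <- if (length(formula) == 3L) formula[-2] else formula
  X <- stats::model.matrix(rhs, data = data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (nrow(X) != nrow(data)) stop("model matrix dropped rows (NAs in covariates?)")

  if (ranef && is.null(data[[subject]])) {
    stop("grouping column `", subject, "` not found")
  }
  subj_f <- if (ranef) factor(data[[subject]]) else factor(rep("all", nrow(data)))
  if (ranef && nlevels(subj_f) < 2L) stop("need at least 2 subjects")
  sb_f <- if (ranef) {
    factor(paste(data[[subject]], data[[block]], sep = ":"))
  } else subj_f
  subj_i <- as.integer(subj_f) - 1L
  sb_i <- as.integer(sb_f) - 1L

  # cutpoint initialization from empirical cumulative category proportions
  props <- cumsum(tabulate(y, K) / length(y))[seq_len(K - 1L)]
  props <- pmin(pmax(props, 1 / (2 * length(y))), 1 - 1 / (2 * length(y)))
  tau0 <- stats::qnorm(props)
  tau0 <- sort(tau0 + cumsum(rep(1e-3, K - 1L)))

  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    beta0 <- stats::rnorm(ncol(X), 0, 0.1)
    tau_ch <- sort(tau0 + stats::rnorm(K - 1L, 0, 0.05))
    chains[[ch]] <- ordinal_gibbs_cpp(
      y = y, X = X, subj = subj_i, sb = sb_i,
      n_subj = nlevels(subj_f), n_sb = nlevels(sb_f), K = K,
      warmup = spec$warmup, keep = spec$iter,
      beta = beta0, tau = tau_ch,
      prior_beta_sd = spec$prior_beta_sd,
      prior_tau_sd = spec$prior_tau_sd,
      prior_sigma_sd = spec$prior_sigma_sd,
      sample_ranef = ranef)
  }

  par_names <- c(colnames(X), paste0("tau", seq_len(K - 1L)),
                 if (ranef) c("sd_subject", "sd_subject_block"))
  draw_mat <- function(ch) {
    if (ranef) cbind(ch$beta, ch$tau, ch$sigma) else cbind(ch$beta, ch$tau)
  }
  draws <- array(NA_real_, c(spec$iter, spec$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(spec$chains)) draws[, ch, ] <- draw_mat(chains[[ch]])

  fit <- structure(list(
    draws = draws,
    bayes_r2_draws = unlist(lapply(chains, `[[`, "bayes_r2")),
    u_subject = do.call(rbind, lapply(chains, `[[`, "u_subject")),
    u_subject_block = do.call(rbind, lapply(chains, `[[`, "u_subject_block")),
    subject_levels = levels(subj_f), sb_levels = levels(sb_f),
    terms = colnames(X), K = K, n = nrow(X), spec = spec,
    formula = formula
  ), class = "probit_fit")

  fit$summary <- summarize_probit(fit)
  fit$converged <- all(fit$summary$rhat < spec$rhat_max, na.rm = TRUE) &&
    all(fit$summary$ess > spec$ess_min, na.rm = TRUE)
  if (spec$gate == "strict" && !fit$converged) {
    warning("sampler did not pass the convergence gate (R-hat < ",
            spec$rhat_max, ", ESS > ", spec$ess_min,
            "); treat summaries with caution", call. = FALSE)
  }
  fit
}

summarize_probit <- function(fit) {
  pars <- dimnames(fit$draws)[[3]]
  out <- lapply(pars, function(p) {
    d <- fit$draws[, , p, drop = TRUE]
    v <- as.numeric(d)
    ci <- hdi(v)
    data.frame(
      parameter = p, mean = mean(v), sd = stats::sd(v),
      hdi_lower = ci[1], hdi_upper = ci[2],
      er_pos = evidence_ratio(v, "+"), er_neg = evidence_ratio(v, "-"),
      rhat = rhat(d), ess = ess_bulk(d),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior-mean Bayes R2 of a fitted ordered-probit model
#'
#' Per draw, the variance of the latent linear predictor (fixed plus random
#' effects, over the fitted rows) divided by that variance plus the unit
#' residual variance; summarized by the posterior mean.
#'
#' @param fit a `probit_fit`.
#' @param summary return the posterior mean (default) or all draws.
#' @return scalar, or vector of per-draw values.
#' @export
bayes_r2 <- function(fit, summary = TRUE) {
  stopifnot(inherits(fit, "probit_fit"))
  if (summary) mean(fit$bayes_r2_draws) else fit$bayes_r2_draws
}

#' @export
print.probit_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Hierarchical ordered-probit fit: %d obs, %d categories, %d chains x %d draws\n",
    x$n, x$K, x$spec$chains, x$spec$iter))
  cat(sprintf("Convergence gate %s; Bayes R2 = %.3f\n",
              if (isTRUE(x$converged)) "passed" else "NOT passed",
              bayes_r2(x)))
  print(format_summary(x$summary, digits))
  invisible(x)
}

format_summary <- function(s, digits = 3) {
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], digits)
  s
}

#' @export
summary.probit_fit <- function(object, ...) {
  if (!isTRUE(object$converged) && object$spec$gate == "strict") {
    warning("fit did not converge; summaries withheld from reports",
            call. = FALSE)
  }
  object$summary
}

#' Draws of one parameter across all chains
#'
#' @param fit a `probit_fit`.
#' @param parameter parameter name as in `fit$summary$parameter`.
#' @return numeric vector of pooled posterior draws.
#' @export
probit_draws <- function(fit, parameter) {
  pars <- dimnames(fit$draws)[[3]]
  if (!parameter %in% pars) {
    stop("unknown parameter `", parameter, "`; available: ",
         paste(pars, collapse = ", "))
  }
  as.numeric(fit$draws[, , parameter])
}

#' Joint ordinal model for two studies with study-level interactions
#'
#' Binds two probe-feature tables, adds a `study` indicator (0 = first,
#' 1 = second), and fits one ordered-probit model in which the study
#' indicator enters as a main effect and interacts with BV, AE, Trial and
#' BV x AE. A study-interaction HDI excluding zero flags heterogeneity
#' between the studies.
#'
#' @param features_a,features_b probe-feature tables sharing the covariate
#'   schema (columns `response`, `bv`, `ae`, `trial`, `subject_id`,
#'   `block`).
#' @param spec a [probit_spec()].
#' @param seed integer seed.
#' @return `probit_fit` with a `heterogeneity` element: per study-interaction
#'   coefficient, whether its 95% HDI excludes zero.
#' @export
combine_studies <- function(features_a, features_b, spec = probit_spec(),
                            seed = NULL) {
  need <- c("response", "bv", "ae", "trial", "subject_id", "block")
  for (tab in list(features_a, features_b)) {
    if (!is.data.frame(tab) || nrow(tab) == 0L) {
      stop("both feature tables must be non-empty data frames")
    }
    if (!all(need %in% names(tab))) {
      stop("feature table missing columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    }
  }
  a <- features_a[, need]
  b <- features_b[, need]
  a$study <- 0
  b$study <- 1
  b$subject_id <- paste0("B_", b$subject_id)
  dat <- rbind(a, b)
  fit <- fit_ordered_probit(
    response ~ bv * ae + trial + study + study:(bv + ae + trial + bv:ae),
    data = dat, spec = spec, seed = seed)
  inter <- grep("^(bv|ae|trial|study).*:", fit$summary$parameter, value = TRUE)
  inter <- union(inter, grep("study", fit$summary$parameter, value = TRUE))
  rows <- fit$summary[fit$summary$parameter %in% inter, ]
  fit$heterogeneity <- data.frame(
    parameter = rows$parameter,
    excludes_zero = rows$hdi_lower > 0 | rows$hdi_upper < 0,
    stringsAsFactors = FALSE
  )
  fit
}
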