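short_spec <- function(chains = 2L, iter = 400L, warmup = 300L,
                       gate = "none") {
  probit_spec(chains = chains, iter = iter, warmup = warmup, gate = gate)
}

test_that("hdi: analytic cases", {
  x <- withr::with_seed(1, rnorm(2e5))
  ci <- hdi(x)
  expect_equal(ci[1], -1.96, tolerance = 0.02)
  expect_equal(ci[2], 1.96, tolerance = 0.02)
  expect_equal(hdi(rep(3.5, 200)), c(3.5, 3.5))
  u <- withr::with_seed(2, runif(1e5))
  expect_equal(diff(hdi(u)), 0.95, tolerance = 0.01)
  expect_error(hdi(rnorm(50)), "at least 100")
})

test_that("evidence ratios count posterior mass by side", {
  x <- c(rep(1, 95), rep(-1, 5))
  expect_equal(evidence_ratio(x, "+"), 19)
  expect_equal(evidence_ratio(x, "-"), 1 / 19)
  expect_identical(evidence_ratio(rep(1, 100), "+"), Inf)
  sym <- withr::with_seed(3, rnorm(2e5))
  expect_equal(evidence_ratio(sym, "+"), 1, tolerance = 0.05)
  # ER+ * ER- = 1 whenever both finite
  expect_equal(evidence_ratio(x, "+") * evidence_ratio(x, "-"), 1)
})

test_that("split R-hat and ESS behave on known chains", {
  good <- withr::with_seed(4, matrix(rnorm(4000), 1000, 4))
  expect_lt(rhat(good), 1.01)
  expect_gt(ess_bulk(good), 2000)
  # chains at different levels must be flagged
  bad <- good + rep(c(0, 0, 0, 3), each = 1000)
  expect_gt(rhat(bad), 1.5)
  # strongly autocorrelated chain has small ESS
  ar <- matrix(as.numeric(arima.sim(list(ar = 0.99), 4000)), 1000, 4)
  expect_lt(ess_bulk(ar), 400)
})

test_that("posterior mean matches the ML ordered-probit oracle at large n", {
  set.seed(10)
  n <- 4000
  x <- rnorm(n)
  tau_true <- c(-0.8, 0.2, 1.1)
  ystar <- 0.5 * x + rnorm(n)
  y <- findInterval(ystar, tau_true) + 1L
  dat <- data.frame(response = y, x = x, subject_id = "s1", block = 1L)
  fit <- fit_ordered_probit(response ~ x, dat, ranef = FALSE,
                            spec = short_spec(chains = 2L, iter = 600L),
                            seed = 12)
  ml <- ml_ordered_probit(y, matrix(x, ncol = 1), 4L)
  expect_equal(fit$summary$mean[fit$summary$parameter == "x"], ml$beta,
               tolerance = 0.02)
  expect_equal(fit$summary$mean[grep("^tau", fit$summary$parameter)], ml$tau,
               tolerance = 0.03)
})

test_that("threshold ordering holds in every retained draw", {
  dat <- simulate_probe_data(n_per_group = 8L, probes_per_block = c(6L, 6L),
                             seed = 13)
  fit <- fit_ordered_probit(response ~ bv + ae + trial + block2, dat,
                            spec = short_spec(), seed = 14)
  taus <- fit$draws[, , grep("^tau", dimnames(fit$draws)[[3]])]
  expect_true(all(taus[, , 1] < taus[, , 2]))
  expect_true(all(taus[, , 2] < taus[, , 3]))
})

test_that("probit symmetry: negated covariates and reversed categories flip signs", {
  dat <- simulate_probe_data(n_per_group = 15L, probes_per_block = c(10L, 10L),
                             seed = 15)
  neg <- dat
  neg$bv <- -neg$bv; neg$ae <- -neg$ae; neg$trial <- -neg$trial
  neg$response <- 5L - neg$response
  f <- response ~ bv + ae + trial
  fit1 <- fit_ordered_probit(f, dat, spec = short_spec(), seed = 16)
  fit2 <- fit_ordered_probit(f, neg, spec = short_spec(), seed = 17)
  for (p in c("bv", "ae", "trial")) {
    m1 <- fit1$summary[fit1$summary$parameter == p, ]
    m2 <- fit2$summary[fit2$summary$parameter == p, ]
    expect_lt(abs(m1$mean - m2$mean), 4 * sqrt(m1$sd^2 + m2$sd^2))
  }
})

test_that("pure-noise fits keep fixed-effect HDIs around zero", {
  truth0 <- ground_truth(beta = c(bv = 0, ae = 0, bv_ae = 0, trial = 0,
                                  block2 = 0, group = 0, group_block2 = 0))
  cover <- unlist(lapply(1:6, function(s) {
    dat <- simulate_probe_data(n_per_group = 8L,
                               probes_per_block = c(8L, 8L),
                               truth = truth0, seed = 100 + s)
    fit <- fit_ordered_probit(response ~ bv + ae + trial + block2, dat,
                              spec = probit_spec(chains = 1L, iter = 400L,
                                                 warmup = 300L, gate = "none"),
                              seed = 200 + s)
    rows <- fit$summary[fit$summary$parameter %in%
                          c("bv", "ae", "trial", "block2"), ]
    rows$hdi_lower <= 0 & rows$hdi_upper >= 0
  }))
  expect_gte(mean(cover), 0.9)
})

test_that("bayes R2 is zero without effects and grows with effect size", {
  truth0 <- ground_truth(beta = c(bv = 0, ae = 0, bv_ae = 0, trial = 0,
                                  block2 = 0, group = 0, group_block2 = 0),
                         sd_subject = 0, sd_subject_block = 0)
  dat0 <- simulate_probe_data(12L, c(8L, 8L), truth0, seed = 31)
  fit0 <- fit_ordered_probit(response ~ bv + trial, dat0, ranef = FALSE,
                             spec = short_spec(chains = 1L), seed = 32)
  expect_lt(bayes_r2(fit0), 0.05)

  r2 <- vapply(c(0.3, 1.0, 2.0), function(b) {
    tr <- ground_truth(beta = c(bv = b, ae = 0, bv_ae = 0, trial = 0,
                                block2 = 0, group = 0, group_block2 = 0),
                       sd_subject = 0, sd_subject_block = 0)
    dat <- simulate_probe_data(12L, c(8L, 8L), tr, seed = 33)
    fit <- fit_ordered_probit(response ~ bv + trial, dat, ranef = FALSE,
                              spec = short_spec(chains = 1L), seed = 34)
    bayes_r2(fit)
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("parameter recovery at the default ground truth (small scale)", {
  truth <- ground_truth()
  dat <- simulate_probe_data(n_per_group = 20L, probes_per_block = c(15L, 15L),
                             truth = truth, seed = 41)
  fit <- fit_ordered_probit(two_block_formula_test(), dat,
                            spec = short_spec(chains = 2L, iter = 500L),
                            seed = 42)
  for (p in c("bv", "ae", "trial", "block2")) {
    row <- fit$summary[fit$summary$parameter == p, ]
    expect_lt(abs(row$mean - truth$beta[[p]]), 3 * row$sd)
  }
})

test_that("combine_studies detects injected heterogeneity and errors on empty input", {
  truth_a <- ground_truth()
  truth_b <- ground_truth(beta = c(bv = 0.09, ae = -0.07, bv_ae = 0,
                                   trial = 0.81, block2 = 0.27, group = 0,
                                   group_block2 = 0))
  a <- simulate_probe_data(15L, c(8L, 12L), truth_a, seed = 51)
  b <- simulate_probe_data(15L, c(8L, 12L), truth_b, seed = 52)
  fit <- combine_studies(a, b, spec = short_spec(chains = 2L), seed = 53)
  row <- fit$summary[fit$summary$parameter == "bv:study", ]
  expect_lt(abs(row$mean - (-0.10)), 3 * row$sd)
  expect_error(combine_studies(a, a[0, ]), "non-empty")
})
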