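#' Highest-density interval of a sample
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' computed by the sorted-draws sliding-window method.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param mass probability mass (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws for an HDI")
  stopifnot(mass > 0, mass < 1)
  x <- sort(draws)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1L):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Evidence ratio for a directional effect
#'
#' `ER+` is the posterior mass above zero divided by the mass at or below
#' zero (and `ER-` the inverse); interpretable as the posterior odds of a
#' positive (negative) effect. All draws on one side gives `Inf`.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param direction `"+"` or `"-"`.
#' @return a single ratio in `[0, Inf]`.
#' @export
evidence_ratio <- function(draws, direction = c("+", "-")) {
  direction <- match.arg(direction)
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100L) stop("need at least 100 draws for an evidence ratio")
  npos <- sum(draws > 0)
  nneg <- length(draws) - npos
  if (direction == "+") {
    if (nneg == 0L) Inf else npos / nneg
  } else {
    if (npos == 0L) Inf else nneg / npos
  }
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Classic Gelman-Rubin R-hat computed on chains split in half, so
#' within-chain trends register as between-chain variance.
#'
#' @param draws iterations-by-chains matrix (a vector is treated as one
#'   chain).
#' @return scalar R-hat.
#' @export
rhat <- function(draws) {
  draws <- split_chains(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  means <- colMeans(draws)
  vars <- apply(draws, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size
#'
#' Effective sample size from chain-averaged autocorrelations with Geyer's
#' initial monotone positive sequence truncation, on split chains.
#'
#' @param draws iterations-by-chains matrix.
#' @return scalar ESS.
#' @export
ess_bulk <- function(draws) {
  draws <- split_chains(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  vars <- apply(draws, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(colMeans(draws))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(m * n)
  # chain-averaged autocovariances
  acov <- sapply(seq_len(m), function(j) {
    x <- draws[, j] - mean(draws[, j])
    stats::acf(x, lag.max = n - 2L, plot = FALSE, type = "covariance",
               demean = FALSE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus       # rho[1] is lag 0
  # Geyer initial monotone positive sequence over lag pairs
  # Gamma_k = rho(2k) + rho(2k+1); tau = 2 * sum_k Gamma_k - rho_0
  s <- 0
  last <- Inf
  k <- 0L
  while (2L * k + 2L <= length(rho)) {
    g <- rho[2L * k + 1L] + rho[2L * k + 2L]
    if (g < 0) break
    g <- min(g, last)
    last <- g
    s <- s + g
    k <- k + 1L
  }
  tau <- max(2 * s - rho[1], 1 / log10(m * n + 1))
  m * n / tau
}

split_chains <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  n <- nrow(draws)
  half <- floor(n / 2)
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[(n - half + 1L):n, , drop = FALSE])
}
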