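#' Approximate entropy of a symbol sequence
#'
#' Computes ApEn(m) for a discrete symbol sequence with exact block matching
#' (tolerance zero), the convention appropriate for binary button sequences
#' where the Pincus tolerance `r` has no meaning. Self-matches are included so
#' no log of zero can occur.
#'
#' ApEn(m) = Phi^m - Phi^(m+1), where
#' Phi^m = (N - m + 1)^(-1) * sum_i log C_i^m and C_i^m is the fraction of
#' the N - m + 1 length-m blocks that exactly equal block i. Natural
#' logarithms are used throughout, so for a binary alphabet the statistic is
#' bounded by log(2) in the long-sequence limit.
#'
#' @param x vector of symbols (any atomic type; compared with `==` semantics
#'   via integer recoding, so `NA` is not allowed).
#' @param m block length (default 2, the value used for 25-tap pre-probe
#'   windows in FT-RSGT analyses).
#' @return approximate entropy in nats (scalar).
#' @examples
#' approximate_entropy(rep("A", 10), m = 2)           # 0
#' approximate_entropy(strsplit("ABABAB", "")[[1]])   # 0.0201
#' @export
approximate_entropy <- function(x, m = 2L) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be a positive integer")
  if (anyNA(x)) stop("sequence contains NA symbols")
  n <- length(x)
  if (n <= m + 1L) {
    stop(sprintf("sequence too short for ApEn(m=%d): need length > %d, got %d",
                 m, m + 1L, n))
  }
  sym <- as.integer(factor(x))
  phi(sym, m) - phi(sym, m + 1L)
}

# Phi^m: mean log relative frequency of each overlapping length-m block.
# Blocks are encoded as integers in base `k` (alphabet size) so counting is a
# single tabulate() pass rather than pairwise comparison.
phi <- function(sym, m) {
  n <- length(sym)
  k <- max(sym)
  n_blocks <- n - m + 1L
  code <- sym[seq_len(n_blocks)] - 1L
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      code <- code * k + (sym[(1L + j):(n_blocks + j)] - 1L)
    }
  }
  counts <- tabulate(code + 1L, nbins = k^m)
  freq <- counts[code + 1L] / n_blocks
  mean(log(freq))
}

#' Transform raw approximate entropy to an unbounded scale
#'
#' Applies `-log(log(2) - ae_raw)`, mapping the binary-bounded ApEn scale
#' onto the real line. On short windows (25 symbols) finite-sample ApEn can
#' reach or exceed log(2); the input is clamped to `log(2) - 1e-10` so the
#' transform stays finite instead of erroring, since no such windows are
#' excluded from analysis.
#'
#' @param ae_raw raw approximate entropy in nats (vectorized).
#' @return transformed entropy (unitless).
#' @export
transform_ae <- function(ae_raw) {
  -log(log(2) - pmin(ae_raw, log(2) - 1e-10))
}
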