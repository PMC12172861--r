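#' Behavioral variability of tap timing
#'
#' Standard deviation (denominator n - 1) of the inter-tap intervals of a tap
#' stream, in the units of `tap_times`. No intervals are excluded: a missed
#' tap lengthens one interval and a double-tap adds a near-zero one, both of
#' which inflate the measure by design.
#'
#' @param tap_times numeric vector of tap onset times (ms), sorted ascending.
#' @return standard deviation of successive differences (ms); `NA_real_`
#'   (with attribute `reason`) when fewer than 3 taps are available.
#' @export
behavioral_variability <- function(tap_times) {
  if (length(tap_times) < 3L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 3 taps"
    return(out)
  }
  if (is.unsorted(tap_times)) tap_times <- sort(tap_times)
  stats::sd(diff(tap_times))
}

#' Per-probe behavioral features of an FT-RSGT session
#'
#' For every thought probe in an event log, takes the last `n_back` taps
#' strictly before probe onset and computes behavioral variability (BV,
#' standard deviation of inter-tap intervals) and approximate entropy
#' (ApEn, m = 2) of the button sequence, plus the transformed entropy
#' `-log(log 2 - AE)`. BV and transformed AE are z-scored across all usable
#' probes of all subjects in the log; the Trial covariate is the within-block
#' probe index, z-scored over the same rows.
#'
#' "Last `n_back` taps" counts tap events, not metronome trials: omissions
#' push the window further back in time and double-taps shorten it, matching
#' how the raw measures are defined.
#'
#' @param events event log data frame (see [simulate_task_events()]): columns
#'   `time_ms`, `kind`, `block`, `button`, `response`, `subject_id`, `group`.
#' @param n_back number of taps preceding each probe to use (default 25).
#' @param m ApEn block length (default 2).
#' @return data frame with one row per probe: `subject_id`, `group`, `block`,
#'   `probe_index` (within block), `probe_time_ms`, `response`, `n_taps`,
#'   `bv_raw`, `ae_raw`, `ae_trans`, `bv`, `ae`, `trial`, `usable`. Rows with
#'   too few taps have `usable = FALSE` and NA features; they are retained so
#'   exclusions are visible, but z-scores are computed over usable rows only.
#' @export
extract_probe_features <- function(events, n_back = 25L, m = 2L) {
  stopifnot(is.data.frame(events))
  need <- c("time_ms", "kind", "block", "subject_id")
  if (!all(need %in% names(events))) {
    stop("event log is missing columns: ",
         paste(setdiff(need, names(events)), collapse = ", "))
  }
  n_back <- as.integer(n_back)
  if (n_back < m + 2L) stop("`n_back` too small for ApEn(m=", m, ")")

  probes <- events[events$kind == "probe", , drop = FALSE]
  if (nrow(probes) == 0L) {
    return(empty_probe_features())
  }
  rows <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    pr <- probes[i, ]
    taps <- events[events$kind == "tap" &
                     events$subject_id == pr$subject_id &
                     events$time_ms < pr$time_ms, , drop = FALSE]
    taps <- taps[order(taps$time_ms), , drop = FALSE]
    if (nrow(taps) > n_back) {
      taps <- taps[(nrow(taps) - n_back + 1L):nrow(taps), , drop = FALSE]
    }
    n_taps <- nrow(taps)
    usable <- n_taps >= max(3L, m + 2L)
    bv_raw <- if (n_taps >= 3L) as.numeric(behavioral_variability(taps$time_ms)) else NA_real_
    ae_raw <- if (n_taps > m + 1L) approximate_entropy(taps$button, m = m) else NA_real_
    rows[[i]] <- data.frame(
      subject_id = pr$subject_id,
      group = if ("group" %in% names(pr)) pr$group else NA_character_,
      block = pr$block,
      probe_time_ms = pr$time_ms,
      response = if ("response" %in% names(pr)) pr$response else NA_integer_,
      n_taps = n_taps,
      bv_raw = bv_raw,
      ae_raw = ae_raw,
      usable = usable && is.finite(bv_raw) && is.finite(ae_raw),
      stringsAsFactors = FALSE
    )
  }
  feat <- do.call(rbind, rows)
  # within-block probe index per subject, in time order
  feat <- feat[order(feat$subject_id, feat$block, feat$probe_time_ms), ]
  feat$probe_index <- stats::ave(
    feat$probe_time_ms, feat$subject_id, feat$block,
    FUN = function(t) rank(t, ties.method = "first")
  )
  feat$ae_trans <- transform_ae(feat$ae_raw)
  ok <- feat$usable
  feat$bv <- zscore_over(feat$bv_raw, ok)
  feat$ae <- zscore_over(feat$ae_trans, ok)
  feat$trial <- zscore_over(feat$probe_index, ok)
  feat$n_back <- n_back
  rownames(feat) <- NULL
  feat
}

zscore_over <- function(x, ok) {
  mu <- mean(x[ok])
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) s <- 1
  (x - mu) / s
}

empty_probe_features <- function() {
  data.frame(
    subject_id = character(), group = character(), block = integer(),
    probe_time_ms = numeric(), response = integer(), n_taps = integer(),
    bv_raw = numeric(), ae_raw = numeric(), usable = logical(),
    probe_index = numeric(), ae_trans = numeric(), bv = numeric(),
    ae = numeric(), trial = numeric(), n_back = integer(),
    stringsAsFactors = FALSE
  )
}
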