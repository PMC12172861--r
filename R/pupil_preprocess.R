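#' Velocity-based blink detection
#'
#' Flags intervals where the smoothed diameter velocity crosses a steep
#' negative onset threshold and later recovers past a positive offset
#' threshold -- the signature of the partial-occlusion transients around
#' eyelid closures. Samples already missing in the recording are always
#' enclosed in some interval, and detected intervals are padded by a margin
#' on each side.
#'
#' Thresholds are in trace units per second and should be tuned to the
#' transient steepness of the tracker; `Inf` disables velocity detection
#' (missing samples are still wrapped).
#'
#' @param rec a `pupil_recording`.
#' @param vel_onset negative velocity threshold (units/s) starting a blink.
#' @param vel_offset positive velocity threshold ending it.
#' @param margin_ms padding added to each side of a detected interval.
#' @param smooth_ms width of the moving-average velocity smoother.
#' @return two-column matrix of (start, end) times in ms, non-overlapping,
#'   increasing. Zero rows when nothing is detected.
#' @export
detect_blinks <- function(rec, vel_onset = -50, vel_offset = 50,
                          margin_ms = 30, smooth_ms = 10) {
  stopifnot(inherits(rec, "pupil_recording"))
  x <- rec$diameter
  n <- length(x)
  if (all(is.na(x))) {
    return(matrix(c(rec$time_ms[1], rec$time_ms[n]), 1, 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  flag <- is.na(x) | rec$missing == 1L

  if (is.finite(vel_onset)) {
    xi <- x
    xi[is.na(xi)] <- stats::approx(rec$time_ms[!is.na(x)], x[!is.na(x)],
                                   xout = rec$time_ms[is.na(x)], rule = 2)$y
    w <- max(1L, round(smooth_ms * rec$fs / 1000))
    if (w > 1L) xi <- stats::filter(xi, rep(1 / w, w), sides = 2)
    xi <- as.numeric(xi)
    # fill filter edge NAs
    xi[is.na(xi)] <- x[is.na(xi)]
    vel <- c(0, diff(xi)) * rec$fs
    i <- 1L
    while (i <= n) {
      if (!is.na(vel[i]) && vel[i] < vel_onset) {
        j <- i
        # advance to recovery: first positive-going crossing back under offset
        while (j < n && !(isTRUE(vel[j] > vel_offset))) j <- j + 1L
        while (j < n && isTRUE(vel[j] > vel_offset)) j <- j + 1L
        flag[i:j] <- TRUE
        i <- j + 1L
      } else i <- i + 1L
    }
  }

  pad <- round(margin_ms * rec$fs / 1000)
  if (pad > 0 && any(flag)) {
    idx <- which(flag)
    for (k in -pad:pad) {
      shifted <- idx + k
      shifted <- shifted[shifted >= 1L & shifted <= n]
      flag[shifted] <- TRUE
    }
  }
  runs_to_intervals(flag, rec$time_ms)
}

runs_to_intervals <- function(flag, time_ms) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- cbind(start = time_ms[starts[keep]], end = time_ms[ends[keep]])
  if (!nrow(out)) out <- matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("start", "end")))
  out
}

#' Merge nearby blink intervals and interpolate across them
#'
#' Intervals separated by less than `gap_ms` are merged (interpolating short
#' inter-blink islands would create artifacts), then the trace is linearly
#' interpolated across each merged interval. The missing mask is updated to
#' mark every interpolated sample.
#'
#' @param rec a `pupil_recording`.
#' @param intervals matrix from [detect_blinks()].
#' @param gap_ms merge threshold (default 100 ms).
#' @return the recording with `diameter` gap-free, `missing` updated, and
#'   the merged intervals stored as `blink_intervals`.
#' @export
merge_and_interpolate <- function(rec, intervals, gap_ms = 100) {
  stopifnot(inherits(rec, "pupil_recording"))
  n <- length(rec$diameter)
  if (nrow(intervals)) {
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    merged <- intervals[1, , drop = FALSE]
    for (i in seq_len(nrow(intervals) - 1L) + 1L) {
      if (intervals[i, 1] - merged[nrow(merged), 2] < gap_ms) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], intervals[i, 2])
      } else {
        merged <- rbind(merged, intervals[i, , drop = FALSE])
      }
    }
  } else merged <- intervals

  mask <- rec$missing == 1L | is.na(rec$diameter)
  for (i in seq_len(nrow(merged))) {
    mask[rec$time_ms >= merged[i, 1] & rec$time_ms <= merged[i, 2]] <- TRUE
  }
  if (all(mask)) stop("blink intervals cover the whole recording")
  x <- rec$diameter
  x[mask] <- NA_real_
  good <- which(!is.na(x))
  x <- stats::approx(rec$time_ms[good], x[good], xout = rec$time_ms,
                     rule = 2)$y
  rec$diameter <- x
  rec$missing <- as.integer(mask)
  rec$blink_intervals <- merged
  rec
}

#' Low-pass filter a pupil recording
#'
#' Zero-phase Butterworth low-pass (default 5 Hz, order 4) applied to the
#' interpolated trace; see [butterworth()] for the implementation.
#'
#' @param rec a `pupil_recording` with no remaining NAs.
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order.
#' @return the recording with `diameter` filtered.
#' @export
pupil_lowpass <- function(rec, cutoff = 5, order = 4L) {
  stopifnot(inherits(rec, "pupil_recording"))
  rec$diameter <- butterworth(rec$diameter, rec$fs, high = cutoff,
                              order = order)
  rec
}

#' Pick the eye with the least missing data
#'
#' @param recordings list of `pupil_recording` objects (one per eye).
#' @return the recording with the smallest missing fraction.
#' @export
select_eye <- function(recordings) {
  stopifnot(length(recordings) >= 1L)
  frac <- vapply(recordings,
                 function(r) mean(r$missing == 1L | is.na(r$diameter)),
                 numeric(1))
  recordings[[which.min(frac)]]
}
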