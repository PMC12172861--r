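#' FT-RSGT task design
#'
#' Container for the structural parameters of the finger-tapping
#' random-sequence-generation task: a metronome tone every 750 ms, three
#' blocks of 800/1600/800 tones, thought probes at uniform random intervals
#' of 40-80 s (10/20/10 per block), and, in the third block only, oddball
#' tones roughly every 8-12 stimuli with exclusion zones covering the first
#' 10 tones after block start or after any probe.
#'
#' @param n_tones_per_block integer vector, tones per block.
#' @param isi_ms inter-stimulus interval in ms.
#' @param tone_dur_ms tone duration in ms (carried as metadata).
#' @param tone_hz,oddball_hz standard and oddball pitches (metadata).
#' @param oddball_spacing integer range (min, max) of tones between oddballs.
#' @param oddball_exclusion number of tones after block start / probe in
#'   which no oddball may occur.
#' @param oddball_blocks which blocks contain oddballs.
#' @param probe_interval_s numeric (min, max) of the uniform inter-probe gap.
#' @param n_probes_per_block integer vector, probes per block.
#' @param likert_levels number of probe response categories.
#' @return object of class `task_design` (a named list).
#' @export
task_design <- function(n_tones_per_block = c(800L, 1600L, 800L),
                        isi_ms = 750,
                        tone_dur_ms = 75,
                        tone_hz = 440,
                        oddball_hz = 880,
                        oddball_spacing = c(8L, 12L),
                        oddball_exclusion = 10L,
                        oddball_blocks = 3L,
                        probe_interval_s = c(40, 80),
                        n_probes_per_block = c(10L, 20L, 10L),
                        likert_levels = 4L) {
  d <- list(
    n_tones_per_block = as.integer(n_tones_per_block),
    isi_ms = isi_ms,
    tone_dur_ms = tone_dur_ms,
    tone_hz = tone_hz,
    oddball_hz = oddball_hz,
    oddball_spacing = as.integer(oddball_spacing),
    oddball_exclusion = as.integer(oddball_exclusion),
    oddball_blocks = as.integer(oddball_blocks),
    probe_interval_s = probe_interval_s,
    n_probes_per_block = as.integer(n_probes_per_block),
    likert_levels = as.integer(likert_levels)
  )
  stopifnot(
    all(d$n_tones_per_block > 0L),
    length(d$n_probes_per_block) == length(d$n_tones_per_block),
    all(d$n_probes_per_block >= 0L),
    d$isi_ms > 0,
    length(d$probe_interval_s) == 2L,
    d$probe_interval_s[1] > 0,
    d$probe_interval_s[1] <= d$probe_interval_s[2],
    length(d$oddball_spacing) == 2L,
    d$oddball_spacing[1] >= 1L,
    d$oddball_spacing[1] <= d$oddball_spacing[2],
    d$likert_levels >= 2L
  )
  class(d) <- "task_design"
  d
}

#' Generate the event log of one FT-RSGT session
#'
#' Lays out tone onsets on the metronome grid (`k * isi` within each block),
#' draws probe times with independent uniform(40, 80) s gaps, and flags
#' oddball tones in the designated block(s) with 8-12 tone spacing, skipping
#' the exclusion zones after block start and after each probe.
#'
#' Probe gaps are drawn uniformly on the configured interval; when the
#' remaining block time gets tight, the draw is constrained to the largest
#' sub-interval that still lets all remaining probes fit, so every gap
#' respects the configured bounds. A block too short to hold its probes at
#' the minimum gap is an error.
#'
#' Oddball spacing is drawn from the configured integer range; a drawn
#' position falling inside an exclusion zone is pushed to the first allowed
#' tone, so inter-oddball gaps can exceed the nominal maximum only across an
#' exclusion zone and are never shorter than the minimum.
#'
#' @param design a [task_design()].
#' @param seed integer seed; the same seed reproduces the log bit for bit.
#' @param subject_id,group identifiers stamped on every event row.
#' @return event log data frame with columns `time_ms`, `kind`
#'   (tone/tap/probe), `block`, `oddball`, `button`, `response`,
#'   `subject_id`, `group`. Tap rows are added by [simulate_behavior()].
#' @export
simulate_task_events <- function(design = task_design(), seed = NULL,
                                 subject_id = "s01", group = "sham") {
  stopifnot(inherits(design, "task_design"))
  if (!is.null(seed)) withr::local_seed(seed)

  n_blocks <- length(design$n_tones_per_block)
  block_dur_ms <- design$n_tones_per_block * design$isi_ms
  block_start_ms <- cumsum(c(0, block_dur_ms[-n_blocks]))

  logs <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    n_tones <- design$n_tones_per_block[b]
    tone_t <- block_start_ms[b] + (seq_len(n_tones) - 1L) * design$isi_ms
    probe_t <- draw_probe_times(
      n_probes = design$n_probes_per_block[b],
      block_dur_ms = block_dur_ms[b],
      gap_ms = design$probe_interval_s * 1000
    ) + block_start_ms[b]

    oddball <- rep(0L, n_tones)
    if (b %in% design$oddball_blocks) {
      oddball <- draw_oddballs(
        n_tones = n_tones,
        tone_t = tone_t,
        probe_t = probe_t,
        spacing = design$oddball_spacing,
        exclusion = design$oddball_exclusion
      )
    }
    logs[[b]] <- rbind(
      data.frame(time_ms = tone_t, kind = "tone", block = b,
                 oddball = oddball, stringsAsFactors = FALSE),
      if (length(probe_t)) {
        data.frame(time_ms = probe_t, kind = "probe", block = b,
                   oddball = 0L, stringsAsFactors = FALSE)
      }
    )
  }
  ev <- do.call(rbind, logs)
  ev <- ev[order(ev$time_ms, ev$kind), ]
  ev$button <- NA_character_
  ev$response <- NA_integer_
  ev$subject_id <- subject_id
  ev$group <- group
  rownames(ev) <- NULL
  attr(ev, "design") <- design
  ev
}

# Sequential uniform gaps, constrained near the block end so that all
# requested probes fit with every gap inside [gap_min, gap_max].
draw_probe_times <- function(n_probes, block_dur_ms, gap_ms) {
  if (n_probes == 0L) return(numeric(0))
  if (n_probes * gap_ms[1] > block_dur_ms) {
    stop(sprintf(
      "block of %.0f ms cannot hold %d probes at a minimum gap of %.0f ms",
      block_dur_ms, n_probes, gap_ms[1]))
  }
  t <- 0
  out <- numeric(n_probes)
  for (i in seq_len(n_probes)) {
    remaining <- n_probes - i            # probes still to place after this one
    hi <- min(gap_ms[2], block_dur_ms - t - remaining * gap_ms[1])
    if (hi < gap_ms[1]) {
      stop("internal error: probe placement became infeasible")
    }
    t <- t + stats::runif(1, gap_ms[1], hi)
    out[i] <- t
  }
  out
}

draw_oddballs <- function(n_tones, tone_t, probe_t, spacing, exclusion) {
  # excluded[i] is TRUE when tone i is among the first `exclusion` tones of
  # the block or among the first `exclusion` tones after any probe
  excluded <- seq_len(n_tones) <= exclusion
  for (pt in probe_t) {
    after <- which(tone_t > pt)
    excluded[utils::head(after, exclusion)] <- TRUE
  }
  flags <- rep(0L, n_tones)
  pos <- 0L
  repeat {
    pos <- pos + sample(spacing[1]:spacing[2], 1L)
    while (pos <= n_tones && excluded[pos]) pos <- pos + 1L
    if (pos > n_tones) break
    flags[pos] <- 1L
  }
  flags
}
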