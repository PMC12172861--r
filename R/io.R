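#' Read and write event logs
#'
#' Event logs are tab-separated text with columns `time_ms`, `kind`
#' (tone/tap/probe), `block`, `oddball`, `button`, `response`,
#' `subject_id`, `group`.
#'
#' @param events event log data frame.
#' @param path file path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the data frame.
#' @export
write_event_log <- function(events, path) {
  cols <- c("time_ms", "kind", "block", "oddball", "button", "response",
            "subject_id", "group")
  missing_cols <- setdiff(cols, names(events))
  for (m in missing_cols) events[[m]] <- NA
  utils::write.table(events[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  need <- c("time_ms", "kind", "block", "subject_id")
  if (!all(need %in% names(ev))) {
    stop("not an event log: missing ", paste(setdiff(need, names(ev)),
                                             collapse = ", "))
  }
  ev
}

#' Read and write pupil recordings
#'
#' The trace goes to a tab-separated file (`time_ms`, `diameter`,
#' `missing`) and metadata (sampling rate, ground truth when present) to a
#' `.json` sidecar next to it.
#'
#' @param rec a `pupil_recording`.
#' @param path path of the `.tsv` file.
#' @return `write_pupil` returns `path` invisibly; `read_pupil` the
#'   recording.
#' @export
write_pupil <- function(rec, path) {
  stopifnot(inherits(rec, "pupil_recording"))
  utils::write.table(
    data.frame(time_ms = rec$time_ms, diameter = rec$diameter,
               missing = rec$missing),
    path, sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  meta <- list(fs = rec$fs)
  if (!is.null(rec$ground_truth)) {
    meta$ground_truth <- rec$ground_truth[c("event_times_ms", "amplitudes",
                                            "noise_sd")]
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pupil
#' @export
read_pupil <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", na.strings = "NA")
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list(fs = 1000 / stats::median(diff(tab$time_ms)))
  structure(list(time_ms = tab$time_ms, diameter = tab$diameter,
                 missing = tab$missing, fs = meta$fs,
                 blink_intervals = matrix(numeric(0), 0, 2),
                 ground_truth = meta$ground_truth),
            class = "pupil_recording")
}

sidecar_path <- function(path) paste0(sub("\\.tsv$", "", path), ".json")

#' Run configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_replication()], [run_robustness()] and the CLI, and serializes it
#' to JSON so every artifact can be written next to the exact settings
#' that produced it.
#'
#' @param mode one of `"simulate"`, `"analyze"`, `"power"`.
#' @param seed integer master seed.
#' @param n_subjects subjects simulated in `simulate` mode.
#' @param n_back_list pre-probe window lengths for the robustness sweep.
#' @param sampler list of [probit_spec()] overrides.
#' @param power list: `b`, `n_per_group`, `n_sims`.
#' @param out_dir output directory.
#' @param ... further fields stored verbatim.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "analyze", "power"),
                       seed = 1L, n_subjects = 20L,
                       n_back_list = c(10L, 15L, 20L, 25L),
                       sampler = list(), power = list(b = -0.23,
                                                      n_per_group = 50L,
                                                      n_sims = 100L),
                       out_dir = tempdir(), ...) {
  cfg <- list(mode = match.arg(mode), seed = as.integer(seed),
              n_subjects = as.integer(n_subjects),
              n_back_list = as.integer(n_back_list),
              sampler = sampler, power = power, out_dir = out_dir, ...)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}
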