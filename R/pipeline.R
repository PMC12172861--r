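#' End-to-end replication run
#'
#' Simulates (or ingests) a multi-subject FT-RSGT study, extracts per-probe
#' behavioral features, and fits the ordered-probit model twice: on the
#' first two blocks (baseline vs. stimulation) and on all blocks present
#' (time-on-task across the session). Outputs are written as tab-separated
#' summary tables plus a JSON report carrying the config snapshot.
#'
#' @param config a [run_config()].
#' @param events optional pre-built event log (otherwise simulated from
#'   `config$seed` and `config$n_subjects`).
#' @param write write outputs under `config$out_dir` (default TRUE).
#' @return list of class `replication_report`: `features`, `fit_two_block`,
#'   `fit_all_blocks`, `config`, and coefficient tables.
#' @export
run_replication <- function(config = run_config(), events = NULL,
                            write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(events)) {
    events <- simulate_study(config$n_subjects, seed = config$seed)
  }
  n_blocks <- length(unique(events$block))
  feats <- extract_probe_features(events, n_back = max(config$n_back_list))
  feats <- prepare_model_frame(feats)

  spec <- do.call(probit_spec, config$sampler)
  two <- feats[feats$block %in% c(1L, 2L), , drop = FALSE]
  if (length(unique(two$block)) < 2L) stop("need blocks 1 and 2 for the two-block fit")
  fit2 <- fit_ordered_probit(two_block_formula(), two, spec = spec,
                             seed = config$seed + 1L)
  fit_all <- NULL
  if (n_blocks >= 3L) {
    fit_all <- fit_ordered_probit(
      response ~ bv + ae + bv_ae + trial + block2 + block3 + group +
        group:block2 + group:block3,
      feats, spec = spec, seed = config$seed + 2L)
  }

  report <- structure(list(
    features = feats,
    fit_two_block = fit2,
    fit_all_blocks = fit_all,
    coefficients_two_block = fit2$summary,
    coefficients_all_blocks = if (!is.null(fit_all)) fit_all$summary,
    bayes_r2 = bayes_r2(fit2),
    converged = fit2$converged && (is.null(fit_all) || fit_all$converged),
    config = config
  ), class = "replication_report")

  if (write) write_report(report, config)
  report
}

# features -> modeling frame: drop unusable rows, add block/group indicators
prepare_model_frame <- function(feats) {
  dat <- feats[feats$usable, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no usable probes")
  dat$bv_ae <- dat$bv * dat$ae
  dat$group <- as.integer(dat$group == "real")
  for (b in sort(unique(dat$block))[-1]) {
    dat[[paste0("block", b)]] <- as.numeric(dat$block == b)
  }
  dat
}

write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$coefficients_two_block,
                     file.path(config$out_dir, "coefficients_two_block.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$coefficients_all_blocks)) {
    utils::write.table(report$coefficients_all_blocks,
                       file.path(config$out_dir, "coefficients_all_blocks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_config(config, file.path(config$out_dir, "config.json"))
  jsonlite::write_json(
    list(bayes_r2 = report$bayes_r2, converged = report$converged,
         n_probes = nrow(report$features), seed = config$seed),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("replication run: %d usable probes, Bayes R2 %.3f, %s\n",
              nrow(x$features), x$bayes_r2,
              if (x$converged) "converged" else "NOT converged"))
  print(format_summary(x$coefficients_two_block))
  invisible(x)
}

#' Robustness of coefficients to the pre-probe window length
#'
#' Re-extracts features and refits the two-block model for each `n_back`
#' value, returning one row per coefficient per window length. Duplicate
#' `n_back` values are de-duplicated with a warning.
#'
#' @param config a [run_config()]; `config$n_back_list` drives the sweep.
#' @param events optional pre-built event log.
#' @return data frame of posterior means and HDIs by coefficient and
#'   `n_back`, of class `robustness_table`.
#' @export
run_robustness <- function(config = run_config(), events = NULL) {
  stopifnot(inherits(config, "run_config"))
  n_backs <- config$n_back_list
  if (anyDuplicated(n_backs)) {
    warning("duplicate n_back values removed", call. = FALSE)
    n_backs <- unique(n_backs)
  }
  if (is.null(events)) {
    events <- simulate_study(config$n_subjects, seed = config$seed)
  }
  spec <- do.call(probit_spec, config$sampler)
  out <- lapply(n_backs, function(nb) {
    feats <- extract_probe_features(events, n_back = nb)
    dat <- prepare_model_frame(feats)
    dat <- dat[dat$block %in% c(1L, 2L), , drop = FALSE]
    fit <- fit_ordered_probit(two_block_formula(), dat, spec = spec,
                              seed = config$seed + nb)
    s <- fit$summary
    s$n_back <- nb
    s
  })
  res <- do.call(rbind, out)
  class(res) <- c("robustness_table", class(res))
  res
}

#' Command-line interface
#'
#' Subcommand-style entry point:
#' `simulate`, `features`, `fit`, `robustness`, `power`, `pupil`, `eeg`,
#' `report`. Global flags: `--config <json>`, `--seed <int>`,
#' `--out <dir>`, `--n-subjects <int>`. Designed to be called from an
#' `Rscript -e 'ftrsgt::ftrsgt_cli()'` wrapper; see the package README.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
ftrsgt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: ftrsgt <simulate|features|fit|robustness|power|report> [--config f] [--seed n] [--out dir] [--n-subjects n]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else run_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  if (!is.null(opts$`n-subjects`)) cfg$n_subjects <- as.integer(opts$`n-subjects`)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  status <- 0L
  switch(cmd,
    simulate = {
      ev <- simulate_study(cfg$n_subjects, seed = cfg$seed)
      write_event_log(ev, file.path(cfg$out_dir, "events.tsv"))
      write_config(cfg, file.path(cfg$out_dir, "config.json"))
      message("wrote ", file.path(cfg$out_dir, "events.tsv"))
    },
    features = {
      ev <- read_event_log(opts$events %||% file.path(cfg$out_dir, "events.tsv"))
      feats <- extract_probe_features(ev, n_back = max(cfg$n_back_list))
      utils::write.table(feats, file.path(cfg$out_dir, "features.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      message("wrote ", file.path(cfg$out_dir, "features.tsv"))
    },
    fit = ,
    report = {
      ev <- if (!is.null(opts$events)) read_event_log(opts$events)
      rep <- tryCatch(run_replication(cfg, events = ev),
                      error = function(e) e)
      if (inherits(rep, "error")) {
        message("FIT FAILED: ", conditionMessage(rep))
        status <- 1L
      } else if (!rep$converged) {
        message("fit flagged: convergence gate not passed")
        status <- 1L
      }
    },
    robustness = {
      tab <- run_robustness(cfg)
      utils::write.table(tab, file.path(cfg$out_dir, "robustness.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    },
    power = {
      pw <- estimate_power(b = cfg$power$b,
                           n_per_group = cfg$power$n_per_group,
                           n_sims = cfg$power$n_sims, seed = cfg$seed)
      jsonlite::write_json(unclass(pw), file.path(cfg$out_dir, "power.json"),
                           auto_unbox = TRUE, digits = NA)
      print(pw)
    },
    {
      message("unknown subcommand: ", cmd)
      status <- 1L
    })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  opts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
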