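#' End-to-end pipeline configuration
#'
#' @param out_dir Output directory for serialized artifacts (`NULL` for
#'   in-memory only).
#' @param seed Global seed; stage sub-seeds are derived deterministically.
#' @param alpha Study-wide significance level (0.01).
#' @param gen A [gen_config()] for the synthetic session (ignored when a
#'   session is supplied to [run_pipeline()]).
#' @param stages Character vector of stages to run, in dependency order
#'   from `c("generate", "warp", "unit_stats", "decoding", "profiles",
#'   "psychometrics", "dpca", "rnn", "ablation")`.
#' @param n_constrained `Nc` for the network stage (`NULL` = all units).
#' @param rnn_max_iters Training iteration cap for the network stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL,
                            seed = 1L,
                            alpha = 0.01,
                            gen = NULL,
                            stages = c("generate", "warp", "unit_stats",
                                       "decoding", "profiles",
                                       "psychometrics", "dpca"),
                            n_constrained = NULL,
                            rnn_max_iters = 2000L) {
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
      gen = gen, stages = stages,
      n_constrained = n_constrained, rnn_max_iters = rnn_max_iters
    ),
    class = "pipeline_config"
  )
}

stage_seed <- function(seed, stage) {
  offsets <- c(
    generate = 11L, warp = 23L, unit_stats = 37L, decoding = 41L,
    profiles = 53L, psychometrics = 67L, dpca = 71L, rnn = 83L,
    ablation = 97L
  )
  (seed * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Run the analysis pipeline on a synthetic or supplied session
#'
#' Executes the enabled stages in dependency order: session generation
#' (or ingestion), event warping, per-unit statistics, decoding,
#' coding-type classification, psychometrics, demixed PCA, and optionally
#' network training plus the ablation battery. Deterministic under a
#' fixed seed. When `config$out_dir` is set, tabular artifacts are
#' written as CSV/JSON alongside a `report.json` summary.
#'
#' @param config A [pipeline_config()].
#' @param session Optional `taste_session`; when `NULL` and the
#'   `generate` stage is enabled a synthetic session is generated.
#' @return A named list of stage results (`session`, `ground_truth`,
#'   `warped`, `unit_stats`, `decoding`, `profiles`, `psychometric`,
#'   `dpca`, `rnn`, `ablation` as enabled) plus `report`, a flat summary
#'   list.
#' @export
run_pipeline <- function(config = pipeline_config(), session = NULL) {
  stages <- config$stages
  res <- list()
  report <- list(seed = config$seed, alpha = config$alpha)

  if (is.null(session)) {
    if (!"generate" %in% stages) stop("no session supplied and 'generate' stage disabled")
    gen <- config$gen %||% gen_config(seed = stage_seed(config$seed, "generate"))
    g <- generate_session(gen)
    res$session <- g$session
    res$ground_truth <- g$ground_truth
  } else {
    res$session <- validate_session(session)
  }
  report$n_trials <- nrow(res$session$trials)
  report$n_units <- res$session$n_units
  report$accuracy <- mean(res$session$trials$outcome == "correct")

  needs_warp <- any(c("warp", "unit_stats", "decoding", "profiles", "dpca", "rnn") %in% stages)
  if (needs_warp) {
    res$warped <- build_psths(res$session)
  }
  if ("unit_stats" %in% stages) {
    res$unit_stats <- unit_stats_table(res$session, res$warped)
    report$n_selective_sampling <- sum(res$unit_stats$selective_sampling, na.rm = TRUE)
  }
  if ("decoding" %in% stages) {
    res$decoding <- dplyr::bind_rows(
      decode_summary(res$warped, "stimulus", alpha = config$alpha),
      decode_summary(res$warped, "choice", alpha = config$alpha)
    )
    report$decoding_peaks <- stats::setNames(
      res$decoding$peak_accuracy, res$decoding$labeling
    )
  }
  if ("profiles" %in% stages) {
    res$profiles <- coding_timecourse(res$warped)
    res$multiplex <- multiplex_summary(res$profiles, res$warped$axis)
    report$n_coding_units <- attr(res$multiplex, "n_coding")
  }
  if ("psychometrics" %in% stages) {
    res$psychometric <- fit_psychometric(psychometric_points(res$session$trials))
    report$psychometric <- list(
      p1 = res$psychometric$p1, p2 = res$psychometric$p2,
      p3 = res$psychometric$p3, p4 = res$psychometric$p4
    )
  }
  if ("dpca" %in% stages) {
    ct <- impute_missing(condition_tensor(res$warped))
    res$dpca <- fit_dpca(ct)
    report$dpca_axis_overlap <- axis_overlap(
      res$dpca$stimulus_axis, res$dpca$choice_axis
    )
  }
  if ("rnn" %in% stages) {
    nc <- config$n_constrained %||% res$session$n_units
    res$rnn <- rnn_train(
      res$warped, n_constrained = nc,
      seed = stage_seed(config$seed, "rnn"),
      max_iters = config$rnn_max_iters
    )
    report$rnn_final_loss <- res$rnn$loss_history$loss[res$rnn$n_iters]
  }
  if ("ablation" %in% stages) {
    if (is.null(res$rnn)) stop("ablation stage requires the rnn stage")
    cal <- calibrate_noise(
      res$rnn, target_accuracy = report$accuracy,
      seed = stage_seed(config$seed, "ablation")
    )
    res$calibration <- cal
    res$ablation <- ablation_report(
      res$rnn, cal$sigma, seed = stage_seed(config$seed, "ablation")
    )
    report$calibrated_sigma <- cal$sigma
    report$ablation_accuracy <- stats::setNames(
      res$ablation$summary$accuracy, res$ablation$summary$condition
    )
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session(res$session, file.path(config$out_dir, "session"))
    if (!is.null(res$ground_truth)) {
      utils::write.csv(res$ground_truth,
                       file.path(config$out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$unit_stats)) {
      utils::write.csv(res$unit_stats, file.path(config$out_dir, "unit_stats.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$profiles)) {
      utils::write.csv(res$profiles, file.path(config$out_dir, "coding_labels.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$decoding)) {
      utils::write.csv(res$decoding, file.path(config$out_dir, "decoding.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$rnn)) {
      write_rnn(res$rnn, file.path(config$out_dir, "model.json"))
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res$report <- report
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
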