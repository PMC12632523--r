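# Overall accuracy of simulated choices against the stimulus side.
sim_accuracy <- function(sim) {
  correct <- (sim$stim_s > 50) == (sim$choice == "sucrose_side")
  mean(correct)
}

#' Calibrate the input-noise level to a target accuracy
#'
#' Searches the input-noise SD `sigma` so that the trained model's overall
#' simulated accuracy falls within `tolerance` (5 percentage points) of
#' the target (typically the accuracy of the session the model was
#' trained on). A coarse grid over \[0.05, 1.5\] in steps of 0.05 is
#' scanned with a fixed seed per candidate (first hit wins); if no grid
#' point lands inside the tolerance, bisection refines between the
#' bracketing candidates.
#'
#' @param fit An `rnn_fit`.
#' @param target_accuracy Target overall accuracy in (0.5, 1\].
#' @param n_per_stim Trials per mixture per candidate (default 20).
#' @param grid Candidate sigmas.
#' @param tolerance Acceptance tolerance on |achieved - target|.
#' @param seed Base seed (same for every candidate, so the search is
#'   matched across sigmas).
#' @param max_bisect Bisection refinement budget.
#' @return A `calibration_result` list: `sigma`, `achieved_accuracy`,
#'   `target_accuracy`, `tolerance`, `trace` (tibble of every candidate
#'   tried), `converged`. Errors (with the trace attached) if the search
#'   fails.
#' @export
calibrate_noise <- function(fit, target_accuracy,
                            n_per_stim = 20L,
                            grid = seq(0.05, 1.5, by = 0.05),
                            tolerance = 0.05,
                            seed = 1L,
                            max_bisect = 12L) {
  stopifnot(target_accuracy > 0.5, target_accuracy <= 1)
  stim_s <- rep(fit$stimulus_set, each = n_per_stim)
  try_sigma <- function(sigma) {
    sim <- simulate_trials(fit$params, fit$config, stim_s, sigma, seed = seed)
    sim_accuracy(sim)
  }
  trace <- list()
  result <- NULL
  accs <- numeric(0)
  for (sigma in grid) {
    acc <- try_sigma(sigma)
    trace[[length(trace) + 1]] <- tibble::tibble(sigma = sigma, accuracy = acc)
    accs <- c(accs, acc)
    if (abs(acc - target_accuracy) <= tolerance) {
      result <- list(sigma = sigma, achieved = acc)
      break
    }
    # accuracy decreases with sigma on average; once we are clearly below
    # target the bracket is behind us
    if (acc < target_accuracy - tolerance && length(accs) >= 2) break
  }
  if (is.null(result)) {
    # bisection between the last candidate above target and the first below
    hi_idx <- which(accs >= target_accuracy)
    lo_idx <- which(accs < target_accuracy)
    if (length(hi_idx) == 0 || length(lo_idx) == 0) {
      lo <- min(grid)
      hi <- max(grid)
    } else {
      lo <- grid[max(hi_idx)] # sigma with accuracy above target
      hi <- grid[min(lo_idx)]
    }
    for (j in seq_len(max_bisect)) {
      mid <- (lo + hi) / 2
      acc <- try_sigma(mid)
      trace[[length(trace) + 1]] <- tibble::tibble(sigma = mid, accuracy = acc)
      if (abs(acc - target_accuracy) <= tolerance) {
        result <- list(sigma = mid, achieved = acc)
        break
      }
      if (acc > target_accuracy) lo <- mid else hi <- mid
    }
  }
  trace <- dplyr::bind_rows(trace)
  if (is.null(result)) {
    cond <- simpleError("noise calibration failed to reach the target accuracy")
    cond$trace <- trace
    stop(cond)
  }
  structure(
    list(
      sigma = result$sigma,
      achieved_accuracy = result$achieved,
      target_accuracy = target_accuracy,
      tolerance = tolerance,
      trace = trace,
      converged = TRUE
    ),
    class = "calibration_result"
  )
}

#' Simulate a batch of trials and cast it as a warped session
#'
#' Runs `n_per_stim` trials per mixture (20 by default, 160 total) at the
#' calibrated input-noise level and packages the rate trajectories and
#' choices in the same `warped_session` shape produced by [build_psths()],
#' so every analysis (auROC, decoding, dPCA, response profiles,
#' psychometrics) applies to model data unchanged. Model steps 1..117
#' play the role of the warped bins; T maps to stimulus onset and D to
#' the decision time.
#'
#' @param fit An `rnn_fit`.
#' @param sigma Input-noise SD (e.g., from [calibrate_noise()]).
#' @param n_per_stim Trials per mixture.
#' @param seed Integer seed.
#' @param clamp 1-based unit indices to ablate (rates clamped to zero).
#' @return A `warped_session` with `trials`, `tensor_raw`,
#'   `tensor_smooth`, `psth`, `psth_n`, plus `choice_activity` (trial x
#'   step matrix of `c`).
#' @export
run_batch <- function(fit, sigma, n_per_stim = 20L, seed = 1L, clamp = integer(0)) {
  stim_s <- rep(fit$stimulus_set, each = n_per_stim)
  sim <- simulate_trials(fit$params, fit$config, stim_s, sigma,
                         seed = seed, clamp = clamp)
  choice <- sim$choice
  outcome <- ifelse((stim_s > 50) == (choice == "sucrose_side"), "correct", "error")
  axis <- warp_axis()
  trials <- tibble::tibble(
    trial = seq_along(stim_s) - 1L,
    stim_pct_sucrose = stim_s,
    choice = choice,
    outcome = outcome,
    t_central = fit$config$stim_onset,
    t_lateral = fit$config$decision_time
  )
  tensor <- sim$rates
  n_u <- dim(tensor)[2]
  tensor_smooth <- tensor
  for (k in seq_len(dim(tensor)[1])) {
    tensor_smooth[k, , ] <- smooth_matrix_rows(matrix(tensor[k, , ], nrow = n_u))
  }
  ws <- structure(
    list(
      trials = trials,
      tensor_raw = tensor,
      tensor_smooth = tensor_smooth,
      axis = axis,
      stimulus_set = stimulus_levels(),
      choice_activity = sim$c
    ),
    class = "warped_session"
  )
  ps <- psth_from_tensor(ws)
  ws$psth <- ps$psth
  ws$psth_n <- ps$n
  ws
}

#' Resolve ablation unit sets from control-simulation coding labels
#'
#' Runs the response-profile classifier on the control batch and returns,
#' per condition, the units labeled with that coding type in at least one
#' moving window (the `other` set is every unit never labeled linear,
#' step-perception or step-choice).
#'
#' @param control_ws A control `warped_session` from [run_batch()].
#' @param alpha Per-template significance level for the classifier.
#' @return A list with `timecourse` (the label table) and `sets`, a named
#'   list of 1-based unit index vectors for `linear`, `step_perception`,
#'   `step_choice`, `other`.
#' @export
ablation_sets <- function(control_ws, alpha = 0.005) {
  tc <- coding_timecourse(control_ws, alpha = alpha)
  mv <- tc[tc$window_kind == "moving", ]
  units_with <- function(lbl) sort(unique(mv$unit[mv$label == lbl])) + 1L
  sets <- list(
    linear = units_with("linear"),
    step_perception = units_with("step_perception"),
    step_choice = units_with("step_choice")
  )
  coding <- sort(unique(unlist(sets)))
  all_units <- seq_len(dim(control_ws$tensor_raw)[2])
  sets$other <- setdiff(all_units, coding)
  list(timecourse = tc, sets = sets)
}

#' Run the virtual-ablation battery on a trained model
#'
#' Simulates a matched-seed control batch and one batch per ablation
#' condition (rates of the condition's unit set clamped to zero for all
#' time, affecting recurrence and the decision readout alike), then
#' summarizes accuracy, psychometrics, projections of post-ablation
#' activity on the control-fit dPCA axes, and overlaps between control
#' and re-fit axes. Models lacking at least 2 trials of each chosen
#' direction under every condition are flagged excluded.
#'
#' @param fit An `rnn_fit`.
#' @param sigma Calibrated input-noise SD.
#' @param n_per_stim Trials per mixture per condition.
#' @param seed Base seed; every condition uses the same seeds as control.
#' @param alpha Classifier significance level for the ablation sets.
#' @param mu dPCA regularization for control and re-fit axes.
#' @return An `ablation_report` list: `summary` tibble (per condition:
#'   accuracy, n units ablated, mean |projection| on control stimulus and
#'   choice axes, overlaps of re-fit axes with control), `sets`,
#'   `sessions` (the simulated `warped_session`s), `psychometrics`,
#'   `excluded` flag, `control_dpca`.
#' @export
ablation_report <- function(fit, sigma, n_per_stim = 20L, seed = 1L,
                            alpha = 0.005, mu = 0) {
  control <- run_batch(fit, sigma, n_per_stim, seed = seed)
  ab <- ablation_sets(control, alpha = alpha)
  conditions <- c("control", names(ab$sets))
  sessions <- list(control = control)
  for (cond in names(ab$sets)) {
    sessions[[cond]] <- run_batch(fit, sigma, n_per_stim, seed = seed,
                                  clamp = ab$sets[[cond]])
  }
  # model-exclusion rule: >= 2 trials per chosen direction in all conditions
  excluded <- any(vapply(sessions, function(ws) {
    any(table(factor(ws$trials$choice,
                     levels = c("nacl_side", "sucrose_side"))) < 2)
  }, logical(1)))

  ct0 <- condition_tensor(control)
  dp0 <- fit_dpca(ct0, mu = mu)

  rows <- list()
  psychos <- list()
  for (cond in conditions) {
    ws <- sessions[[cond]]
    ct <- condition_tensor(ws)
    ct <- impute_missing(ct)
    proj_s <- dpca_project(ct$xbar, dp0$stimulus_axis)
    proj_c <- dpca_project(ct$xbar, dp0$choice_axis)
    refit <- tryCatch(fit_dpca(ct, mu = mu), error = function(e) NULL)
    pts <- psychometric_points(ws$trials)
    psy <- tryCatch(fit_psychometric(pts), error = function(e) NULL)
    psychos[[cond]] <- psy
    rows[[cond]] <- tibble::tibble(
      condition = cond,
      n_ablated = if (cond == "control") 0L else length(ab$sets[[cond]]),
      accuracy = mean(ws$trials$outcome == "correct"),
      mean_abs_proj_stimulus = mean(abs(proj_s$projection)),
      mean_abs_proj_choice = mean(abs(proj_c$projection)),
      overlap_stimulus = if (is.null(refit)) NA_real_ else
        axis_overlap(dp0$stimulus_axis, refit$stimulus_axis),
      overlap_choice = if (is.null(refit)) NA_real_ else
        axis_overlap(dp0$choice_axis, refit$choice_axis),
      psycho_slope = if (is.null(psy)) NA_real_ else psy$p2
    )
  }
  structure(
    list(
      summary = dplyr::bind_rows(rows),
      sets = ab$sets,
      sessions = sessions,
      psychometrics = psychos,
      excluded = excluded,
      control_dpca = dp0
    ),
    class = "ablation_report"
  )
}
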