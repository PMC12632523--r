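#' Tuning-curve (response profile) of a unit in a time window
#'
#' The unit's pre-processed (warped, smoothed) firing rate is averaged
#' over the window's bins and then over trials of each stimulus with the
#' requested outcome, giving an 8-point curve of rate vs %Sucrose.
#'
#' @param ws A `warped_session`.
#' @param unit 0-based unit id.
#' @param window Integer bin indices (1-based on the warped axis).
#' @param outcome `"correct"` or `"error"`.
#' @param smoothed Use smoothed single-trial rates (default `TRUE`).
#' @return A tibble `stimulus, rate, n_trials`; stimuli with no
#'   contributing trials have `rate = NA`.
#' @export
response_profile <- function(ws, unit, window, outcome = c("correct", "error"),
                             smoothed = TRUE) {
  outcome <- match.arg(outcome)
  if (length(window) == 0) stop("window must contain at least one bin")
  tensor <- if (smoothed) ws$tensor_smooth else ws$tensor_raw
  tr <- ws$trials
  win_mean <- rowMeans(matrix(tensor[, unit + 1L, window], nrow = nrow(tr)))
  purrr::map_dfr(ws$stimulus_set, function(s) {
    sel <- tr$stim_pct_sucrose == s & tr$outcome == outcome
    tibble::tibble(
      stimulus = s,
      rate = if (any(sel)) mean(win_mean[sel]) else NA_real_,
      n_trials = sum(sel)
    )
  })
}

# Constrained least-squares line fit r ~ p1*s + p2 subject to f(s) >= 0 at
# all profile stimuli. For a line on [min(s), max(s)] nonnegativity at the
# two extreme stimuli implies it everywhere in between, so the feasible
# set has two linear boundaries; the tiny QP is solved exactly by checking
# the unconstrained optimum, the two boundary-constrained optima and the
# corner.
solve_constrained_line <- function(s, r) {
  lo <- min(s); hi <- max(s)
  cands <- list()
  # unconstrained OLS
  sx <- s - mean(s)
  p1 <- sum(sx * (r - mean(r))) / sum(sx^2)
  p2 <- mean(r) - p1 * mean(s)
  cands[[1]] <- c(p1, p2)
  # boundary f(lo) = 0: p2 = -lo*p1; minimize over p1 of sum (r - p1*(s-lo))^2
  u <- s - lo
  cands[[2]] <- local({
    p1b <- sum(r * u) / sum(u^2)
    c(p1b, -lo * p1b)
  })
  # boundary f(hi) = 0: p2 = -hi*p1
  v <- s - hi
  cands[[3]] <- local({
    p1b <- sum(r * v) / sum(v^2)
    c(p1b, -hi * p1b)
  })
  cands[[4]] <- c(0, 0)
  feasible <- function(p) min(p[1] * lo + p[2], p[1] * hi + p[2]) >= -1e-12
  sse <- function(p) sum((r - (p[1] * s + p[2]))^2)
  ok <- Filter(feasible, cands)
  best <- ok[[which.min(vapply(ok, sse, numeric(1)))]]
  list(p1 = best[1], p2 = best[2], sse = sse(best))
}

extra_ss_f <- function(sse_null, sse_fit, n_d, n_p) {
  df_num <- n_p - 1
  df_den <- n_d - n_p
  if (sse_fit <= 1e-12) {
    if (sse_null <= 1e-12) {
      return(list(fstat = 0, p_value = 1, degenerate = "constant"))
    }
    return(list(fstat = Inf, p_value = 0, degenerate = "perfect"))
  }
  fstat <- (sse_null - sse_fit) / sse_fit * df_den / df_num
  fstat <- max(fstat, 0)
  list(
    fstat = fstat,
    p_value = stats::pf(fstat, df_num, df_den, lower.tail = FALSE),
    degenerate = "none"
  )
}

#' Fit the 2-parameter line template to a response profile
#'
#' Least squares for `f(s) = p1 s + p2` constrained to be nonnegative at
#' every profile stimulus, compared against the mean-only null with the
#' extra-sum-of-squares F statistic (numerator df `Np - 1 = 1`, denominator
#' `Nd - Np`).
#'
#' @param profile A [response_profile()] tibble (NA points dropped;
#'   >= 3 points required).
#' @return A `shape_fit` list: `template = "line"`, `p1` (slope), `p2`
#'   (intercept), `sse_null`, `sse`, `fstat`, `p_value`, `degenerate`.
#' @export
fit_line <- function(profile) {
  pr <- profile[!is.na(profile$rate), ]
  if (nrow(pr) < 3) stop("need at least 3 profile points for the line fit")
  fit <- solve_constrained_line(pr$stimulus, pr$rate)
  sse_null <- sum((pr$rate - mean(pr$rate))^2)
  f <- extra_ss_f(sse_null, fit$sse, nrow(pr), 2)
  structure(
    list(
      template = "line", p1 = fit$p1, p2 = fit$p2,
      sse_null = sse_null, sse = fit$sse,
      fstat = f$fstat, p_value = f$p_value, degenerate = f$degenerate
    ),
    class = "shape_fit"
  )
}

#' Fit the 3-parameter step template to a response profile
#'
#' The inflection `p3` ranges over 40, 50, 60 (%Sucrose); for each, the
#' optimal low/high levels are the means of the profile on either side
#' (`p1` for `s < p3`, `p2` for `s >= p3`), and the best candidate by SSE
#' wins (smallest `p3` on ties). F statistic uses `Np = 3`.
#'
#' @param profile A [response_profile()] tibble.
#' @return A `shape_fit` list: `template = "step"`, `p1`, `p2`, `p3`,
#'   `sse_null`, `sse`, `fstat`, `p_value`, `degenerate`.
#' @export
fit_step <- function(profile) {
  pr <- profile[!is.na(profile$rate), ]
  if (nrow(pr) < 3) stop("need at least 3 profile points for the step fit")
  best <- NULL
  for (p3 in c(40, 50, 60)) {
    lo <- pr$rate[pr$stimulus < p3]
    hi <- pr$rate[pr$stimulus >= p3]
    if (length(lo) == 0 || length(hi) == 0) next
    p1 <- mean(lo)
    p2 <- mean(hi)
    sse <- sum((lo - p1)^2) + sum((hi - p2)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(p1 = p1, p2 = p2, p3 = p3, sse = sse)
    }
  }
  if (is.null(best)) stop("no candidate inflection has points on both sides")
  sse_null <- sum((pr$rate - mean(pr$rate))^2)
  f <- extra_ss_f(sse_null, best$sse, nrow(pr), 3)
  structure(
    list(
      template = "step", p1 = best$p1, p2 = best$p2, p3 = best$p3,
      sse_null = sse_null, sse = best$sse,
      fstat = f$fstat, p_value = f$p_value, degenerate = f$degenerate
    ),
    class = "shape_fit"
  )
}

#' Assign a coding-type label from correct- and error-trial profiles
#'
#' Fits both templates to the correct-trial profile; the template with the
#' larger F statistic wins if its p value is below `alpha` (0.005 by
#' default: 0.01 Bonferroni-corrected for the two templates), otherwise
#' the label is `"other"`. A winning step is sub-classified using the
#' correct/error firing-rate differences
#' `delta_x = <r_x(s)>_{s>50} - <r_x(s)>_{s<50}`: an inflection at 50 with
#' `delta_correct * delta_error < 0` is `"step_choice"` (the unit follows
#' the chosen side, so the tuning flips on error trials); consistent signs
#' give `"step_perception"`; a missing error side leaves the step
#' `"step_unresolved"`. A constant correct profile (both fits degenerate)
#' is `"other"`.
#'
#' @param profile_correct Complete 8-point correct-trial profile.
#' @param profile_error Error-trial profile (may have missing points).
#' @param alpha Per-template significance level (default 0.005).
#' @return A `coding_label` list: `label`, `fit_line`, `fit_step`,
#'   `delta_correct`, `delta_error`, `incomplete` flag.
#' @export
classify_profile <- function(profile_correct, profile_error = NULL, alpha = 0.005) {
  complete <- !any(is.na(profile_correct$rate)) &&
    nrow(profile_correct) == length(stimulus_levels())
  if (!complete) {
    return(structure(
      list(
        label = "other", fit_line = NULL, fit_step = NULL,
        delta_correct = NA_real_, delta_error = NA_real_, incomplete = TRUE
      ),
      class = "coding_label"
    ))
  }
  fl <- fit_line(profile_correct)
  fs <- fit_step(profile_correct)
  if (fl$degenerate == "constant" && fs$degenerate == "constant") {
    winner <- NULL
  } else if (fs$fstat > fl$fstat) {
    winner <- fs
  } else {
    winner <- fl
  }
  delta_of <- function(profile) {
    if (is.null(profile)) return(NA_real_)
    hi <- profile$rate[profile$stimulus > 50]
    lo <- profile$rate[profile$stimulus < 50]
    if (all(is.na(hi)) || all(is.na(lo))) return(NA_real_)
    mean(hi, na.rm = TRUE) - mean(lo, na.rm = TRUE)
  }
  dc <- delta_of(profile_correct)
  de <- delta_of(profile_error)
  label <- "other"
  if (!is.null(winner) && winner$p_value < alpha) {
    if (winner$template == "line") {
      label <- "linear"
    } else if (is.na(de)) {
      label <- "step_unresolved"
    } else if (winner$p3 == 50 && dc * de < 0) {
      label <- "step_choice"
    } else {
      label <- "step_perception"
    }
  }
  structure(
    list(
      label = label, fit_line = fl, fit_step = fs,
      delta_correct = dc, delta_error = de, incomplete = FALSE
    ),
    class = "coding_label"
  )
}

#' Moving-window coding-type time course for every unit
#'
#' Applies [classify_profile()] in 4-bin (~200 ms) windows stepped by 4
#' bins over the warped axis (the final window is 1 bin wide when the bin
#' count is not divisible by 4), plus the two fixed windows: the 10 middle
#' bins after T (sampling) and the 10 before D (delay).
#'
#' @param ws A `warped_session`.
#' @param alpha Per-template significance level.
#' @param smoothed Use smoothed single-trial rates.
#' @return A tibble `unit, window_id, window_start_bin, window_end_bin,
#'   window_kind, label, fstat_line, fstat_step, p3, delta_correct,
#'   delta_error`. Moving windows have `window_kind = "moving"`; the fixed
#'   windows are `"sampling"` and `"delay"`.
#' @export
coding_timecourse <- function(ws, alpha = 0.005, smoothed = TRUE) {
  nb <- ws$axis$total_bins
  starts <- seq(1L, nb, by = 4L)
  wins <- lapply(starts, function(s) s:min(s + 3L, nb))
  fixed <- warped_windows(ws$axis)
  all_wins <- c(wins, list(fixed$sampling, fixed$delay))
  kinds <- c(rep("moving", length(wins)), "sampling", "delay")
  n_u <- dim(ws$tensor_raw)[2]
  tensor <- if (smoothed) ws$tensor_smooth else ws$tensor_raw
  tr <- ws$trials
  stims <- ws$stimulus_set
  rows <- vector("list", n_u * length(all_wins))
  i <- 0
  for (u in seq_len(n_u) - 1L) {
    unit_rates <- matrix(tensor[, u + 1L, ], nrow = nrow(tr))
    for (w in seq_along(all_wins)) {
      window <- all_wins[[w]]
      win_mean <- rowMeans(unit_rates[, window, drop = FALSE])
      prof <- function(oc) {
        purrr::map_dfr(stims, function(s) {
          sel <- tr$stim_pct_sucrose == s & tr$outcome == oc
          tibble::tibble(
            stimulus = s,
            rate = if (any(sel)) mean(win_mean[sel]) else NA_real_,
            n_trials = sum(sel)
          )
        })
      }
      cl <- classify_profile(prof("correct"), prof("error"), alpha = alpha)
      i <- i + 1
      rows[[i]] <- tibble::tibble(
        unit = u,
        window_id = w,
        window_start_bin = window[1],
        window_end_bin = window[length(window)],
        window_kind = kinds[w],
        label = cl$label,
        fstat_line = if (is.null(cl$fit_line)) NA_real_ else cl$fit_line$fstat,
        fstat_step = if (is.null(cl$fit_step)) NA_real_ else cl$fit_step$fstat,
        p3 = if (is.null(cl$fit_step)) NA_real_ else cl$fit_step$p3,
        delta_correct = cl$delta_correct,
        delta_error = cl$delta_error
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Multiplexing summary: combinations of coding types per unit
#'
#' Restricted to moving windows overlapping the inter-event (T to D)
#' period, collects for each unit the set of coding labels it takes in at
#' least one window and counts units in each non-empty subset of
#' \{linear, step_perception, step_choice\} (`step_unresolved` counts as
#' neither step sub-type and is ignored, mirroring un-sub-classified
#' steps).
#'
#' @param timecourse Output of [coding_timecourse()].
#' @param axis The [warp_axis()] used (default layout assumed otherwise).
#' @return A tibble `combination, n_units` covering the 7 non-empty
#'   subsets, plus attribute `n_coding` (units with >= 1 coding label).
#' @export
multiplex_summary <- function(timecourse, axis = warp_axis()) {
  mid <- (axis$n_pre + 1L):(axis$n_pre + axis$n_warp)
  tc <- timecourse[timecourse$window_kind == "moving" &
                     timecourse$window_end_bin >= mid[1] &
                     timecourse$window_start_bin <= mid[length(mid)], ]
  types <- c("linear", "step_perception", "step_choice")
  sets <- tapply(tc$label, tc$unit, function(l) sort(unique(intersect(l, types))))
  combos <- unlist(lapply(1:3, function(k) {
    apply(utils::combn(types, k), 2, paste, collapse = "+")
  }))
  key <- vapply(sets, paste, collapse = "+", FUN.VALUE = character(1))
  counts <- table(factor(key[key != ""], levels = combos))
  out <- tibble::tibble(
    combination = combos,
    n_units = as.integer(counts)
  )
  attr(out, "n_coding") <- sum(key != "")
  out
}
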