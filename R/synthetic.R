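#' Four-parameter logistic psychometric curve
#'
#' `y(s) = p4 + (p1 - p4) / (1 + exp(-p2 (s - p3)))`: the probability of a
#' sucrose-side choice as a function of the %Sucrose of the mixture, with
#' upper asymptote `p1`, slope `p2`, inflection `p3` and lower asymptote
#' `p4`.
#'
#' @param s %Sucrose values in \[0, 100\].
#' @param params Numeric vector `c(p1, p2, p3, p4)`.
#' @return Choice probabilities, same length as `s`.
#' @export
logistic4 <- function(s, params) {
  p1 <- params[1]; p2 <- params[2]; p3 <- params[3]; p4 <- params[4]
  p4 + (p1 - p4) / (1 + exp(-p2 * (s - p3)))
}

#' Generator configuration for synthetic sessions
#'
#' Defaults emulate the study conditions the analyses were developed for:
#' 137 trials over the 8 mixtures (0/100 ... 100/0), 27 simultaneously
#' recorded units with a mix of coding types, choices following a
#' 4-parameter logistic psychometric whose slope (0.08/%Sucrose) and
#' asymptotes imply ~77% overall accuracy, and inter-event intervals
#' (first central lick T to first lateral lick D) averaging 3.85 s.
#'
#' @param n_trials Number of trials (default 137).
#' @param n_units Number of units (default 27).
#' @param stimulus_set %Sucrose values (default the 8 task mixtures).
#' @param psycho_params Generating 4PL `c(p1, p2, p3, p4)`
#'   (default `c(0.95, 0.08, 50, 0.05)`).
#' @param iei_mean,iei_sd Mean and SD (s) of the truncated-normal
#'   inter-event interval D - T (defaults 3.85 and 0.6; floor 1 s).
#' @param pre_T_window Seconds of simulated activity before T (default
#'   3.5 s, covering the long pre-stimulus baseline windows).
#' @param post_D_window Seconds simulated after D (default 1 s).
#' @param coding_mix Named proportions over coding types `linear`,
#'   `step_perception`, `step_choice`, `other_responsive`, `other_flat`;
#'   must sum to 1. Unit counts use largest-remainder rounding.
#' @param baseline_range Uniform range (Hz) for per-unit baseline rates.
#' @param gain Tuning gain (Hz) of coding units.
#' @param envelope_width Temporal envelope width (s).
#' @param seed Integer seed; the whole session is reproducible given the
#'   config (including the seed).
#' @return A `gen_config` list.
#' @export
gen_config <- function(n_trials = 137L,
                       n_units = 27L,
                       stimulus_set = stimulus_levels(),
                       psycho_params = c(0.95, 0.08, 50, 0.05),
                       iei_mean = 3.85,
                       iei_sd = 0.6,
                       pre_T_window = 3.5,
                       post_D_window = 1.0,
                       coding_mix = c(
                         linear = 0.25, step_perception = 0.25,
                         step_choice = 0.20, other_responsive = 0.15,
                         other_flat = 0.15
                       ),
                       baseline_range = c(2, 8),
                       gain = 10,
                       envelope_width = 0.8,
                       seed = 1L) {
  stopifnot(iei_mean > 0, n_trials >= 1, n_units >= 0)
  if (abs(sum(coding_mix) - 1) > 1e-8) stop("coding_mix proportions must sum to 1")
  p <- psycho_params
  if (p[1] < 0 || p[1] > 1 || p[4] < 0 || p[4] > 1 || p[3] < 15 || p[3] > 85) {
    stop("psycho_params outside the fitting constraints (0<=p1<=1, 15<=p3<=85, 0<=p4<=1)")
  }
  structure(
    list(
      n_trials = as.integer(n_trials), n_units = as.integer(n_units),
      stimulus_set = stimulus_set, psycho_params = psycho_params,
      iei_mean = iei_mean, iei_sd = iei_sd,
      pre_T_window = pre_T_window, post_D_window = post_D_window,
      coding_mix = coding_mix, baseline_range = baseline_range,
      gain = gain, envelope_width = envelope_width, seed = as.integer(seed)
    ),
    class = "gen_config"
  )
}

#' Draw a single choice from the generating psychometric
#'
#' @param stimulus_s %Sucrose in \[0, 100\].
#' @param psycho_params 4PL parameters `c(p1, p2, p3, p4)`.
#' @return `"sucrose_side"` or `"nacl_side"` (Bernoulli with
#'   `P(sucrose_side) = logistic4(stimulus_s, psycho_params)`).
#' @export
draw_choice <- function(stimulus_s, psycho_params) {
  stopifnot(stimulus_s >= 0, stimulus_s <= 100)
  pr <- logistic4(stimulus_s, psycho_params)
  ifelse(stats::runif(length(stimulus_s)) < pr, "sucrose_side", "nacl_side")
}

# Largest-remainder apportionment of n into proportions p (named).
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# Temporal envelopes on the per-trial clock, vectorized over t.
# sampling: half-Gaussian decaying from T (tuning expressed just after taste
#   sampling onset); delay: linear ramp rising into D; both: their pointwise max.
envelope_value <- function(envelope, t, T, D, width) {
  samp <- ifelse(t >= T, exp(-(t - T)^2 / (2 * width^2)), 0)
  dely <- ifelse(t <= D, pmax(0, 1 - (D - t) / width), 0)
  switch(envelope,
    sampling = samp,
    delay = dely,
    both = pmax(samp, dely),
    stop("unknown envelope: ", envelope)
  )
}

#' Instantaneous firing rate of a synthetic unit
#'
#' Implements the ground-truth tuning models: `linear` units scale with the
#' mixture composition (`baseline + gain * s/100 * envelope(t)`);
#' `step_perception` units jump at the 50/50 boundary with the stimulus side
#' on correct and error trials alike; `step_choice` units are elevated
#' whenever the unit's preferred side is chosen, regardless of stimulus;
#' `other_responsive` units have stimulus- and choice-independent bumps at
#' T and D; `other_flat` units hold their baseline. Rates are clipped at 0.
#'
#' @param spec One row of a ground-truth unit table (list or 1-row data
#'   frame) with fields `coding_type`, `baseline_rate`, `gain`, `envelope`,
#'   `envelope_width`, `preferred_side`, `high_side`.
#' @param trial A 1-row trial record with `stim_pct_sucrose`, `choice`,
#'   `t_central`, `t_lateral`.
#' @param t Time points (s, per-trial clock), vectorized.
#' @return Rates in Hz, same length as `t`.
#' @export
unit_rate <- function(spec, trial, t) {
  T <- trial$t_central
  D <- trial$t_lateral
  s <- trial$stim_pct_sucrose
  w <- spec$envelope_width
  base <- spec$baseline_rate
  drive <- switch(spec$coding_type,
    linear = spec$gain * (s / 100) *
      envelope_value(spec$envelope, t, T, D, w),
    step_perception = {
      side_high <- if (spec$high_side == "sucrose_side") s > 50 else s < 50
      spec$gain * as.numeric(side_high) *
        envelope_value(spec$envelope, t, T, D, w)
    },
    step_choice = spec$gain * as.numeric(trial$choice == spec$preferred_side) *
      envelope_value(spec$envelope, t, T, D, w),
    other_responsive = spec$gain * (
      exp(-(t - T)^2 / (2 * 0.3^2)) + exp(-(t - D)^2 / (2 * 0.3^2))
    ),
    other_flat = rep(0, length(t)),
    stop("unknown coding_type: ", spec$coding_type)
  )
  r <- base + drive
  if (any(r < 0)) {
    warning("negative computed rate clipped to 0")
    r <- pmax(r, 0)
  }
  r
}

#' Generate a synthetic session with known ground truth
#'
#' Per trial the stimulus is drawn uniformly from the stimulus set, the
#' choice from the generating psychometric (error trials arise naturally
#' from its stochasticity), T sits at a session-constant offset
#' (`pre_T_window`), and D = T + a truncated-normal inter-event interval
#' (floor 1 s). Spikes are drawn from an inhomogeneous Poisson process for
#' each unit's ground-truth rate via thinning on a 1 ms grid.
#'
#' @param config A [gen_config()].
#' @return A list with `session` (a `taste_session`) and `ground_truth`
#'   (a tibble: one row per unit with its coding type and tuning
#'   parameters, plus the generating psychometric as an attribute
#'   `psycho_params`).
#' @export
generate_session <- function(config = gen_config()) {
  withr::local_seed(config$seed)
  n_tr <- config$n_trials
  n_u <- config$n_units

  stim <- sample(config$stimulus_set, n_tr, replace = TRUE)
  choice <- draw_choice(stim, config$psycho_params)
  outcome <- ifelse(
    (stim > 50) == (choice == "sucrose_side"), "correct", "error"
  )
  T0 <- config$pre_T_window
  iei <- pmax(1, stats::rnorm(n_tr, config$iei_mean, config$iei_sd))
  trials <- tibble::tibble(
    trial = seq_len(n_tr) - 1L,
    stim_pct_sucrose = stim,
    choice = choice,
    outcome = outcome,
    t_central = T0,
    t_lateral = T0 + iei
  )

  counts <- largest_remainder(n_u, config$coding_mix)
  if (any(abs(n_u * config$coding_mix - counts) > 1e-9)) {
    message("coding_mix * n_units not integral; largest-remainder rounding applied")
  }
  types <- rep(names(counts), counts)
  envelopes <- ifelse(
    stats::runif(n_u) < 0.5, "sampling", "delay"
  )
  ground_truth <- tibble::tibble(
    unit = seq_len(n_u) - 1L,
    coding_type = types,
    baseline_rate = stats::runif(n_u, config$baseline_range[1], config$baseline_range[2]),
    gain = ifelse(grepl("^other", types), ifelse(types == "other_responsive", config$gain, 0), config$gain),
    envelope = envelopes,
    envelope_width = config$envelope_width,
    preferred_side = sample(c("sucrose_side", "nacl_side"), n_u, replace = TRUE),
    high_side = sample(c("sucrose_side", "nacl_side"), n_u, replace = TRUE)
  )
  attr(ground_truth, "psycho_params") <- config$psycho_params

  # Poisson thinning on a 1 ms grid, vectorized per unit over (grid x trials).
  dt <- 1e-3
  t_end <- T0 + iei + config$post_D_window
  max_end <- max(t_end)
  grid <- seq(dt / 2, max_end, by = dt)
  spikes_list <- vector("list", n_u)
  for (u in seq_len(n_u)) {
    gspec <- as.list(ground_truth[u, ])
    unit_spikes <- vector("list", n_tr)
    for (k in seq_len(n_tr)) {
      tk <- grid[grid < t_end[k]]
      r <- unit_rate(gspec, as.list(trials[k, ]), tk)
      fire <- stats::runif(length(tk)) < r * dt
      if (any(fire)) {
        unit_spikes[[k]] <- tibble::tibble(
          unit = gspec$unit, trial = k - 1L, spike_time = tk[fire]
        )
      }
    }
    spikes_list[[u]] <- dplyr::bind_rows(unit_spikes)
  }
  spikes <- dplyr::bind_rows(spikes_list)
  if (nrow(spikes) == 0) {
    spikes <- tibble::tibble(unit = integer(), trial = integer(), spike_time = double())
  }

  session <- new_session(
    trials, spikes,
    session_id = sprintf("synthetic-seed%d", config$seed),
    n_units = n_u
  )
  list(session = session, ground_truth = ground_truth)
}
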