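#' Area under the ROC curve between two firing-rate samples
#'
#' Computed as the normalized Mann-Whitney U statistic of `sample_b` over
#' `sample_a` (ties contribute 1/2): 0 means rates in `sample_a`
#' (predominantly-sucrose trials) are always greater, 1 means rates in
#' `sample_b` (predominantly-NaCl trials) are always greater, and 0.5 is
#' complete overlap of the two distributions.
#'
#' @param sample_a,sample_b Numeric vectors (e.g., firing rates on
#'   predominantly-sucrose and predominantly-NaCl trials).
#' @return A value in \[0, 1\]; `NA` if either sample is empty.
#' @export
auroc <- function(sample_a, sample_b) {
  na <- length(sample_a)
  nb <- length(sample_b)
  if (na == 0 || nb == 0) return(NA_real_)
  r <- rank(c(sample_a, sample_b))
  u_b <- sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2
  u_b / (na * nb)
}

#' Per-unit auROC discrimination time courses
#'
#' For each unit and warped-axis bin, the auROC between firing rates on
#' correct predominantly-sucrose (s > 50) and correct predominantly-NaCl
#' (s < 50) trials, with the orientation of [auroc()] (values above 0.5:
#' NaCl trials fire more). The peak is the bin with the greatest absolute
#' deviation from 0.5 (earliest bin on ties); units are labeled
#' NaCl-preferring when the peak value exceeds 0.5, sucrose-preferring when
#' below, and unlabeled in the degenerate all-0.5 case.
#'
#' @param ws A `warped_session` from [build_psths()] or [run_batch()].
#' @param smoothed Use the smoothed single-trial tensor (default `TRUE`).
#' @return A list with `values` (matrix unit x bin) and `summary`, a tibble
#'   `unit, peak_auroc, peak_bin, preference`.
#' @export
auroc_timecourse <- function(ws, smoothed = TRUE) {
  tensor <- if (smoothed) ws$tensor_smooth else ws$tensor_raw
  tr <- ws$trials
  suc <- which(tr$stim_pct_sucrose > 50 & tr$outcome == "correct")
  nacl <- which(tr$stim_pct_sucrose < 50 & tr$outcome == "correct")
  n_u <- dim(tensor)[2]
  nb <- dim(tensor)[3]
  vals <- matrix(NA_real_, n_u, nb)
  for (u in seq_len(n_u)) {
    for (b in seq_len(nb)) {
      vals[u, b] <- auroc(tensor[suc, u, b], tensor[nacl, u, b])
    }
  }
  summary <- purrr::map_dfr(seq_len(n_u), function(u) {
    v <- vals[u, ]
    if (all(is.na(v))) {
      return(tibble::tibble(
        unit = u - 1L, peak_auroc = NA_real_, peak_bin = NA_integer_,
        preference = NA_character_
      ))
    }
    dev <- abs(v - 0.5)
    pk <- which.max(dev) # earliest bin on ties
    pref <- if (dev[pk] == 0) {
      NA_character_
    } else if (v[pk] > 0.5) "nacl_preferring" else "sucrose_preferring"
    tibble::tibble(
      unit = u - 1L, peak_auroc = v[pk], peak_bin = as.integer(pk),
      preference = pref
    )
  })
  list(values = vals, summary = summary)
}

#' Label a unit's stimulus preference from its auROC time course
#'
#' @param values auROC values per bin (may contain `NA`).
#' @return A list `peak_bin`, `peak_auroc`, `preference`
#'   (`"sucrose_preferring"`, `"nacl_preferring"`, or `NA` when the time
#'   course never deviates from 0.5 or is all missing).
#' @export
preference_label <- function(values) {
  if (all(is.na(values))) {
    return(list(peak_bin = NA_integer_, peak_auroc = NA_real_, preference = NA_character_))
  }
  dev <- abs(values - 0.5)
  pk <- which.max(dev)
  pref <- if (dev[pk] == 0) {
    NA_character_
  } else if (values[pk] > 0.5) "nacl_preferring" else "sucrose_preferring"
  list(peak_bin = as.integer(pk), peak_auroc = values[pk], preference = pref)
}

# Trial-wise mean rate of one unit in a real-time window [w1, w2) relative
# to the per-trial clock, computed from raw spikes.
window_rates <- function(session, unit, w_start, w_end) {
  tr <- session$trials
  sp <- session$spikes[session$spikes$unit == unit, ]
  vapply(seq_len(nrow(tr)), function(k) {
    s <- sp$spike_time[sp$trial == tr$trial[k]]
    lo <- w_start[k]
    hi <- w_end[k]
    sum(s >= lo & s < hi) / (hi - lo)
  }, numeric(1))
}

#' Responsivity and selectivity classification of units
#'
#' Units are responsive in the sampling period (\[T, T + 0.5 s\]) or delay
#' period (\[D - 0.5 s, D\]) when their trial-wise window rates differ from
#' baseline (two-sided Mann-Whitney at `alpha`); responsive units are
#' additionally selective when rates differ between correct
#' predominantly-sucrose and predominantly-NaCl trials within the period.
#' Selectivity is only tested for responsive units. Only correct trials
#' enter any comparison.
#'
#' Experimental-format baselines are \[T - 3, T - 2.5 s\] (sampling) and
#' \[D - 5.5, D - 5 s\] (delay); for simulated data with short pre-stimulus
#' epochs use `baseline = "short"`, which takes \[T - 0.5 s, T\] for both.
#'
#' @param session A `taste_session`.
#' @param alpha Significance level (default 0.01).
#' @param baseline `"long"` (experimental windows) or `"short"`.
#' @return A tibble with one row per unit: responsivity/selectivity flags
#'   and p-values for both periods. Windows falling before the recorded
#'   data produce `NA` flags.
#' @export
responsivity_selectivity <- function(session, alpha = 0.01, baseline = c("long", "short")) {
  baseline <- match.arg(baseline)
  tr <- session$trials
  correct <- tr$outcome == "correct"
  suc <- correct & tr$stim_pct_sucrose > 50
  nacl <- correct & tr$stim_pct_sucrose < 50
  T <- tr$t_central
  D <- tr$t_lateral
  wins <- list(
    sampling = list(w = cbind(T, T + 0.5),
                    base = if (baseline == "long") cbind(T - 3, T - 2.5) else cbind(T - 0.5, T)),
    delay = list(w = cbind(D - 0.5, D),
                 base = if (baseline == "long") cbind(D - 5.5, D - 5) else cbind(T - 0.5, T))
  )
  mw_p <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (length(unique(c(a, b))) == 1) return(1)
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  purrr::map_dfr(seq_len(session$n_units) - 1L, function(u) {
    row <- list(unit = u)
    for (period in names(wins)) {
      wdef <- wins[[period]]
      # trials whose windows precede the recorded data are dropped
      avail <- wdef$base[, 1] >= 0 & wdef$w[, 1] >= 0
      if (sum(avail & correct) < 2) {
        row[[paste0("responsive_", period)]] <- NA
        row[[paste0("selective_", period)]] <- NA
        row[[paste0("p_responsive_", period)]] <- NA_real_
        row[[paste0("p_selective_", period)]] <- NA_real_
        next
      }
      rate_w <- window_rates(session, u, wdef$w[, 1], wdef$w[, 2])
      rate_b <- window_rates(session, u, wdef$base[, 1], wdef$base[, 2])
      p_resp <- mw_p(rate_w[correct & avail], rate_b[correct & avail])
      responsive <- !is.na(p_resp) && p_resp < alpha
      p_sel <- NA_real_
      selective <- FALSE
      if (responsive) {
        p_sel <- mw_p(rate_w[suc & avail], rate_w[nacl & avail])
        selective <- !is.na(p_sel) && p_sel < alpha
      }
      row[[paste0("responsive_", period)]] <- responsive
      row[[paste0("selective_", period)]] <- selective
      row[[paste0("p_responsive_", period)]] <- p_resp
      row[[paste0("p_selective_", period)]] <- p_sel
    }
    tibble::as_tibble(row)
  })
}

#' Per-unit discrimination summary table
#'
#' Convenience wrapper joining the auROC peak summary with the
#' responsivity/selectivity screen.
#'
#' @param session A `taste_session`.
#' @param ws Its `warped_session` (computed if missing).
#' @param baseline Passed to [responsivity_selectivity()].
#' @return A tibble, one row per unit.
#' @export
unit_stats_table <- function(session, ws = NULL, baseline = "long") {
  if (is.null(ws)) ws <- build_psths(session)
  a <- auroc_timecourse(ws)$summary
  r <- responsivity_selectivity(session, baseline = baseline)
  dplyr::left_join(a, r, by = "unit")
}
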