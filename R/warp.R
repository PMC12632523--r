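#' Event-warped time axis
#'
#' The analysis axis for trial-aligned firing rates: a fixed number of
#' 50 ms bins before the first central lick T and after the first lateral
#' lick D, and 77 bins of trial-dependent width covering the inter-event
#' interval \[T, D) so that rates align to both events across trials. With
#' the default 20 + 77 + 20 layout the axis has 117 bins; at the dataset's
#' 3.85 s mean inter-event interval the middle bins average 50 ms.
#'
#' @param n_pre,n_warp,n_post Bin counts before T, between T and D, after D.
#' @param fixed_bin Width (s) of the pre/post bins.
#' @return A `warp_axis` list with the counts, `fixed_bin` and `total_bins`.
#' @export
warp_axis <- function(n_pre = 20L, n_warp = 77L, n_post = 20L, fixed_bin = 0.05) {
  stopifnot(fixed_bin > 0, n_warp >= 1)
  structure(
    list(
      n_pre = as.integer(n_pre), n_warp = as.integer(n_warp),
      n_post = as.integer(n_post), fixed_bin = fixed_bin,
      total_bins = as.integer(n_pre + n_warp + n_post)
    ),
    class = "warp_axis"
  )
}

warp_edges <- function(T, D, axis) {
  c(
    T - axis$fixed_bin * (axis$n_pre:1),
    T + (D - T) * (0:(axis$n_warp - 1)) / axis$n_warp,
    D + axis$fixed_bin * (0:axis$n_post)
  )
}

#' Warp one trial's spike train onto the event-aligned axis
#'
#' Bins are half-open `[left, right)`; a spike exactly at T enters the
#' first middle bin. Rates are spike count divided by the actual bin
#' duration, so the middle bins (each `(D - T) / n_warp` long) integrate
#' back to the exact spike count in \[T, D).
#'
#' @param spike_times Sorted spike times (s) on the trial clock.
#' @param T,D First central and lateral lick times (s), `D > T`.
#' @param axis A [warp_axis()].
#' @return Numeric vector of rates (Hz), length `axis$total_bins`.
#' @export
warp_trial <- function(spike_times, T, D, axis = warp_axis()) {
  if (D <= T) stop("D must exceed T")
  edges <- warp_edges(T, D, axis)
  widths <- diff(edges)
  idx <- findInterval(spike_times, edges)
  idx <- idx[idx >= 1 & idx <= axis$total_bins]
  counts <- tabulate(idx, nbins = axis$total_bins)
  counts / widths
}

#' Smooth a rate vector with an edge-renormalized Gaussian kernel
#'
#' Acausal discrete Gaussian smoothing over a window of
#' `2 * kernel_halfwidth_bins + 1` bins (11 by default). At the edges the
#' kernel is renormalized over its in-range support, so a constant input
#' is preserved exactly. `NA` bins propagate.
#'
#' @param rates Numeric vector.
#' @param kernel_halfwidth_bins Half-width in bins (default 5).
#' @param sd_bins Kernel SD in bins (default 2); `sd_bins <= 0` returns
#'   the input unchanged with a warning.
#' @return Smoothed vector, same length.
#' @export
smooth_rates <- function(rates, kernel_halfwidth_bins = 5L, sd_bins = 2) {
  if (sd_bins <= 0) {
    warning("sd_bins <= 0; returning input unchanged")
    return(rates)
  }
  n <- length(rates)
  hw <- kernel_halfwidth_bins
  w <- exp(-((-hw):hw)^2 / (2 * sd_bins^2))
  out <- numeric(n)
  norm <- numeric(n)
  for (j in (-hw):hw) {
    src <- seq_len(n) + j
    ok <- src >= 1 & src <= n
    out[ok] <- out[ok] + w[j + hw + 1] * rates[src[ok]]
    norm[ok] <- norm[ok] + w[j + hw + 1]
  }
  out / norm
}

smooth_matrix_rows <- function(m, kernel_halfwidth_bins = 5L, sd_bins = 2) {
  t(apply(m, 1, smooth_rates, kernel_halfwidth_bins = kernel_halfwidth_bins, sd_bins = sd_bins))
}

#' Build warped rate tensors and condition PSTHs for a session
#'
#' Computes per-trial warped firing rates for every unit (raw and
#' Gaussian-smoothed single-trial tensors) and trial-averaged PSTHs per
#' (stimulus, outcome) condition. PSTHs are averaged over raw single-trial
#' rates and then smoothed; conditions with no trials are `NA`, never 0.
#'
#' @param session A `taste_session`.
#' @param axis A [warp_axis()].
#' @param sd_bins,kernel_halfwidth_bins Smoothing kernel parameters.
#' @return A `warped_session` list:
#'   * `trials` — the session's trial table;
#'   * `tensor_raw`, `tensor_smooth` — arrays `(trial, unit, bin)`;
#'   * `psth` — array `(stimulus, outcome, unit, bin)` of smoothed means;
#'   * `psth_n` — trial counts per `(stimulus, outcome)`;
#'   * `axis`, `stimulus_set`.
#' @export
build_psths <- function(session, axis = warp_axis(),
                        sd_bins = 2, kernel_halfwidth_bins = 5L) {
  validate_session(session)
  tr <- session$trials
  n_tr <- nrow(tr)
  n_u <- session$n_units
  nb <- axis$total_bins
  tensor <- array(0, dim = c(n_tr, n_u, nb))
  sp <- session$spikes
  sp_by <- split(seq_len(nrow(sp)), list(sp$trial, sp$unit), drop = TRUE)
  trial_pos <- stats::setNames(seq_len(n_tr), tr$trial)
  for (key in names(sp_by)) {
    rows <- sp_by[[key]]
    k <- trial_pos[[as.character(sp$trial[rows[1]])]]
    u <- sp$unit[rows[1]] + 1L
    tensor[k, u, ] <- warp_trial(
      sp$spike_time[rows], tr$t_central[k], tr$t_lateral[k], axis
    )
  }
  tensor_smooth <- tensor
  for (k in seq_len(n_tr)) {
    if (n_u > 0) {
      tensor_smooth[k, , ] <- smooth_matrix_rows(
        matrix(tensor[k, , ], nrow = n_u),
        kernel_halfwidth_bins, sd_bins
      )
    }
  }
  out <- structure(
    list(
      trials = tr,
      tensor_raw = tensor,
      tensor_smooth = tensor_smooth,
      axis = axis,
      stimulus_set = stimulus_levels()
    ),
    class = "warped_session"
  )
  ps <- psth_from_tensor(out, sd_bins = sd_bins,
                         kernel_halfwidth_bins = kernel_halfwidth_bins)
  out$psth <- ps$psth
  out$psth_n <- ps$n
  out
}

# Condition PSTHs (smoothed after trial averaging) from a warped_session.
psth_from_tensor <- function(ws, sd_bins = 2, kernel_halfwidth_bins = 5L) {
  tr <- ws$trials
  stims <- ws$stimulus_set
  n_u <- dim(ws$tensor_raw)[2]
  nb <- dim(ws$tensor_raw)[3]
  psth <- array(NA_real_,
    dim = c(length(stims), 2, n_u, nb),
    dimnames = list(stims, c("correct", "error"), NULL, NULL)
  )
  n <- matrix(0L, length(stims), 2, dimnames = list(stims, c("correct", "error")))
  for (si in seq_along(stims)) {
    for (oi in 1:2) {
      oc <- c("correct", "error")[oi]
      sel <- which(tr$stim_pct_sucrose == stims[si] & tr$outcome == oc)
      n[si, oi] <- length(sel)
      if (length(sel) > 0 && n_u > 0) {
        m <- apply(ws$tensor_raw[sel, , , drop = FALSE], c(2, 3), mean)
        psth[si, oi, , ] <- smooth_matrix_rows(m, kernel_halfwidth_bins, sd_bins)
      }
    }
  }
  list(psth = psth, n = n)
}

#' Bin indices of the fixed analysis windows on the warped axis
#'
#' The sampling window is the first 10 middle bins after T (about
#' T to T + 0.5 s at the mean inter-event interval) and the delay window
#' the last 10 middle bins before D.
#'
#' @param axis A [warp_axis()].
#' @return List with integer bin vectors `sampling` and `delay`
#'   (1-based on the warped axis).
#' @export
warped_windows <- function(axis = warp_axis()) {
  first_mid <- axis$n_pre + 1L
  last_mid <- axis$n_pre + axis$n_warp
  list(
    sampling = first_mid:(first_mid + 9L),
    delay = (last_mid - 9L):last_mid
  )
}
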