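#' Class-balanced leave-one-out nearest-centroid decoding
#'
#' Each trial is held out in turn; class centroids (mean population rate
#' vectors) are recomputed without it, and the held-out trial is assigned
#' the label of the nearest centroid in Euclidean distance (ties broken
#' toward the smallest label value). Accuracy is class-balanced: the mean
#' over labels of the per-label hit rate. Labels with fewer than 2 trials
#' are dropped with a warning (their centroid would be undefined after
#' hold-out).
#'
#' @param x Numeric matrix, trials x features (population rate vectors).
#' @param labels Vector of class labels, one per trial.
#' @return A list: `accuracy` (class-balanced), `per_label` tibble
#'   (`label, n, hits, hit_rate`), `predicted` (per retained trial),
#'   `n_labels`.
#' @export
min_distance_loo <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  tab <- table(labels)
  keep_labels <- names(tab)[tab >= 2]
  if (length(keep_labels) < length(tab)) {
    warning("dropping label(s) with a single trial: ",
            paste(setdiff(names(tab), keep_labels), collapse = ", "))
  }
  keep <- labels %in% keep_labels
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  ulab <- sort(unique(labels))
  if (length(ulab) < 2) stop("need at least 2 labels with >= 2 trials each")
  n <- nrow(x)
  # per-label sums for O(1) centroid exclusion
  lab_idx <- match(labels, ulab)
  sums <- rowsum(x, group = lab_idx)
  counts <- as.vector(table(factor(lab_idx, levels = seq_along(ulab))))
  pred <- integer(n)
  for (i in seq_len(n)) {
    d2 <- vapply(seq_along(ulab), function(u) {
      if (u == lab_idx[i]) {
        cu <- (sums[u, ] - x[i, ]) / (counts[u] - 1)
      } else {
        cu <- sums[u, ] / counts[u]
      }
      sum((x[i, ] - cu)^2)
    }, numeric(1))
    pred[i] <- which.min(d2) # which.min takes the first (smallest label) on ties
  }
  per_label <- tibble::tibble(
    label = ulab,
    n = counts,
    hits = vapply(seq_along(ulab), function(u) sum(pred == u & lab_idx == u), integer(1))
  )
  per_label$hit_rate <- per_label$hits / per_label$n
  list(
    accuracy = mean(per_label$hit_rate),
    per_label = per_label,
    predicted = ulab[pred],
    n_labels = length(ulab)
  )
}

#' Decoding accuracy time course over the warped axis
#'
#' Runs the leave-one-out nearest-centroid decoder per warped-axis bin on
#' the population vectors of a session, labeling trials by stimulus
#' (8 classes) or choice (2 classes).
#'
#' @param ws A `warped_session`.
#' @param what `"stimulus"` or `"choice"`.
#' @param smoothed Use smoothed single-trial rates (default `FALSE`).
#' @param bins Bins to decode (default all).
#' @return A tibble `bin, accuracy, chance` with attribute `"chance"`.
#' @export
decode_timecourse <- function(ws, what = c("stimulus", "choice"),
                              smoothed = FALSE, bins = NULL) {
  what <- match.arg(what)
  tensor <- if (smoothed) ws$tensor_smooth else ws$tensor_raw
  labels <- switch(what,
    stimulus = ws$trials$stim_pct_sucrose,
    choice = ws$trials$choice
  )
  chance <- switch(what, stimulus = 1 / 8, choice = 1 / 2)
  if (is.null(bins)) bins <- seq_len(dim(tensor)[3])
  acc <- vapply(bins, function(b) {
    suppressWarnings(min_distance_loo(tensor[, , b, drop = TRUE], labels)$accuracy)
  }, numeric(1))
  tibble::tibble(bin = bins, accuracy = acc, chance = chance)
}

#' One-tailed binomial significance threshold for decoding accuracy
#'
#' Returns `k / N` where `k` is the smallest hit count whose upper-tail
#' binomial probability (at chance `p` over `N` trials) falls below
#' `alpha`: `k = min x : P(Y >= x) < alpha` for `Y ~ Binomial(N, p)`.
#'
#' @param alpha Significance level in (0, 1).
#' @param N Trial count.
#' @param p Chance level (1/8 for stimulus, 1/2 for choice).
#' @return The threshold accuracy `k / N`.
#' @export
binomial_threshold <- function(alpha, N, p) {
  stopifnot(alpha > 0, alpha < 1, N >= 1, p > 0, p < 1)
  x <- 0:N
  tail <- stats::pbinom(x - 1, N, p, lower.tail = FALSE) # P(Y >= x)
  ok <- which(tail < alpha)
  if (length(ok) == 0) stop("threshold unattainable: no k <= N with upper tail < alpha")
  k <- x[ok[1]]
  k / N
}

#' Window-averaged decoding summary for a session
#'
#' Averages the decoding time course within the sampling window (first 10
#' middle bins after T) and delay window (last 10 middle bins before D),
#' subtracting the theoretical chance level, and reports the peak.
#'
#' @param ws A `warped_session`.
#' @param what `"stimulus"` or `"choice"`.
#' @param alpha Significance level for the binomial threshold.
#' @param smoothed Passed to [decode_timecourse()].
#' @return A tibble with one row: chance, threshold, peak accuracy/bin and
#'   chance-subtracted window means.
#' @export
decode_summary <- function(ws, what = c("stimulus", "choice"), alpha = 0.01,
                           smoothed = FALSE) {
  what <- match.arg(what)
  tc <- decode_timecourse(ws, what, smoothed = smoothed)
  wins <- warped_windows(ws$axis)
  chance <- tc$chance[1]
  pk <- which.max(tc$accuracy)
  tibble::tibble(
    labeling = what,
    chance = chance,
    threshold = binomial_threshold(alpha, nrow(ws$trials), chance),
    peak_accuracy = tc$accuracy[pk],
    peak_bin = tc$bin[pk],
    sampling_minus_chance = mean(tc$accuracy[tc$bin %in% wins$sampling]) - chance,
    delay_minus_chance = mean(tc$accuracy[tc$bin %in% wins$delay]) - chance
  )
}
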