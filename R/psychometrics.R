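#' Fit a 4-parameter logistic psychometric to choice data
#'
#' Bounded least squares on the per-stimulus mean probabilities of a
#' sucrose-side choice (the psychometric is always fitted to the
#' session-/model-averaged response, not trial-wise). Parameters are
#' constrained to `0 <= p1 <= 1`, `15 <= p3 <= 85`, `0 <= p4 <= 1`; the
#' slope `p2` is unbounded. A fixed multi-start grid over
#' `p2 in {+-0.02, +-0.1, +-0.5}` makes the fit deterministic.
#'
#' @param points A data frame with columns `s` (%Sucrose) and `p_sucrose`
#'   (mean probability of the sucrose-side choice); >= 5 points required.
#' @return A `psychometric_fit` list: `p1, p2, p3, p4`, `sse`, `n_points`,
#'   `fitted` (tibble with predictions).
#' @export
fit_psychometric <- function(points) {
  pts <- tibble::as_tibble(points)
  if (!all(c("s", "p_sucrose") %in% names(pts))) {
    stop("points must have columns 's' and 'p_sucrose'")
  }
  pts <- pts[stats::complete.cases(pts[, c("s", "p_sucrose")]), ]
  if (nrow(pts) < 5) stop("need at least 5 points to fit the 4 parameters")
  obj <- function(par) sum((pts$p_sucrose - logistic4(pts$s, par))^2)
  lower <- c(0, -Inf, 15, 0)
  upper <- c(1, Inf, 85, 1)
  p1_0 <- max(min(max(pts$p_sucrose), 1), 0)
  p4_0 <- max(min(min(pts$p_sucrose), 1), 0)
  best <- NULL
  for (p2_0 in c(0.02, -0.02, 0.1, -0.1, 0.5, -0.5)) {
    start <- c(p1_0, p2_0, 50, p4_0)
    fit <- tryCatch(
      stats::nlminb(start, obj, lower = lower, upper = upper,
                    control = list(iter.max = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective - 1e-12)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("psychometric fit failed from all starts")
  par <- best$par
  structure(
    list(
      p1 = par[1], p2 = par[2], p3 = par[3], p4 = par[4],
      sse = best$objective, n_points = nrow(pts),
      fitted = tibble::tibble(
        s = pts$s, p_sucrose = pts$p_sucrose,
        fitted = logistic4(pts$s, par)
      )
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit: p1=%.3f p2=%.4f p3=%.1f p4=%.3f, SSE=%.4g over %d points>\n",
    x$p1, x$p2, x$p3, x$p4, x$sse, x$n_points
  ))
  invisible(x)
}

#' Compare psychometric curves with an extra-sum-of-squares F-test
#'
#' SSE1 comes from one curve fitted to all points pooled, SSE2 from
#' separate fits per dataset; `F = ((SSE1 - SSE2)/SSE2) * df2/(df1 - df2)`
#' with `df1 = N - 4` and `df2 = N - 4 * n_curves`, and the p value is the
#' upper tail of `F(df1 - df2, df2)`. Bonferroni correction multiplies p
#' by `choose(K, 2)` for `K` total curves under consideration.
#'
#' @param datasets A list of >= 2 point sets (each with `s`, `p_sucrose`).
#' @param K Total number of curves considered (default `length(datasets)`).
#' @return A `curve_comparison` tibble row: SSEs, dfs, `fstat`, `p_value`,
#'   `p_adjusted`, `bonferroni_k`, `degenerate` flag (TRUE when SSE2 = 0).
#' @export
compare_psychometrics <- function(datasets, K = length(datasets)) {
  stopifnot(length(datasets) >= 2)
  fits <- lapply(datasets, fit_psychometric)
  pooled <- dplyr::bind_rows(lapply(datasets, tibble::as_tibble))
  joint <- fit_psychometric(pooled)
  sse1 <- joint$sse
  sse2 <- sum(vapply(fits, function(f) f$sse, numeric(1)))
  n <- nrow(pooled)
  df1 <- n - 4
  df2 <- n - 4 * length(datasets)
  if (df2 < 1) stop("not enough points for separate fits (df2 < 1)")
  kchoose2 <- choose(K, 2)
  degenerate <- sse2 <= 1e-12
  if (degenerate) {
    fstat <- Inf
    p <- 0
  } else {
    fstat <- max(0, (sse1 - sse2) / sse2 * df2 / (df1 - df2))
    p <- stats::pf(fstat, df1 - df2, df2, lower.tail = FALSE)
  }
  tibble::tibble(
    sse_joint = sse1, sse_separate = sse2,
    df1 = df1, df2 = df2,
    fstat = fstat, p_value = p,
    bonferroni_k = kchoose2,
    p_adjusted = min(1, p * kchoose2),
    degenerate = degenerate
  )
}

#' Session-averaged psychometric points from a trial table
#'
#' @param trials A trial table (`stim_pct_sucrose`, `choice`).
#' @return A tibble `s, p_sucrose, n_trials` over the stimuli present.
#' @export
psychometric_points <- function(trials) {
  trials |>
    dplyr::group_by(s = .data$stim_pct_sucrose) |>
    dplyr::summarise(
      p_sucrose = mean(.data$choice == "sucrose_side"),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}
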