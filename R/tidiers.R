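#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit into one row per parameter
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A tibble `term, estimate` for p1 (upper asymptote), p2 (slope),
#'   p3 (inflection), p4 (lower asymptote).
#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("p1", "p2", "p3", "p4"),
    estimate = c(x$p1, x$p2, x$p3, x$p4)
  )
}

#' @rdname tidy.psychometric_fit
#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_points = x$n_points)
}

#' Tidy a shape-template fit
#'
#' @param x A `shape_fit` from [fit_line()] or [fit_step()].
#' @param ... Unused.
#' @return One-row tibble with the template, parameters, F statistic and
#'   p value.
#' @method tidy shape_fit
#' @export
tidy.shape_fit <- function(x, ...) {
  tibble::tibble(
    template = x$template,
    p1 = x$p1, p2 = x$p2,
    p3 = if (x$template == "step") x$p3 else NA_real_,
    sse_null = x$sse_null, sse = x$sse,
    fstat = x$fstat, p_value = x$p_value
  )
}

#' Tidy a demixed-PCA fit into per-marginalization variance rows
#'
#' @param x A `dpca_fit`.
#' @param ... Unused.
#' @return A tibble `marginalization, marginal_variance` (sum of squares
#'   of the marginalized matrix) and `n_components`.
#' @method tidy dpca_fit
#' @export
tidy.dpca_fit <- function(x, ...) {
  tibble::tibble(
    marginalization = names(x$fits),
    marginal_variance = vapply(x$fits, function(f) f$marg_var, numeric(1)),
    n_components = x$n_components
  )
}

#' @rdname tidy.dpca_fit
#' @method glance dpca_fit
#' @export
glance.dpca_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu,
    n_units = x$dims[1],
    n_components = x$n_components,
    stimulus_choice_overlap = axis_overlap(x$stimulus_axis, x$choice_axis)
  )
}

#' Glance at a trained network
#'
#' @param x An `rnn_fit`.
#' @param ... Unused.
#' @return One-row tibble: unit counts, iterations, final loss
#'   components.
#' @method glance rnn_fit
#' @export
glance.rnn_fit <- function(x, ...) {
  tibble::tibble(
    n_constrained = x$params$Nc,
    n_unconstrained = x$params$Nu,
    n_units = x$params$N,
    n_iters = x$n_iters,
    final_loss = x$loss_history$loss[nrow(x$loss_history)]
  )
}

#' Per-unit RMSE between a trained network's noiseless rates and targets
#'
#' Runs one noiseless-stimulus, noise-free pass per mixture and measures
#' the root-mean-squared error of each constrained unit's rate trajectory
#' against its target PSTH.
#'
#' @param fit An `rnn_fit` with targets attached.
#' @return A tibble `unit, rmse` (Hz) for the constrained units.
#' @export
rnn_unit_rmse <- function(fit) {
  if (is.null(fit$targets)) stop("fit has no targets attached")
  cfg0 <- fit$config
  cfg0$sigma_eta <- 0
  sim <- simulate_trials(fit$params, cfg0, fit$stimulus_set, 0, seed = 1L)
  Nc <- fit$params$Nc
  rmse <- vapply(seq_len(Nc), function(u) {
    sqrt(mean((sim$rates[, u, ] - fit$targets[, u, ])^2))
  }, numeric(1))
  tibble::tibble(unit = seq_len(Nc) - 1L, rmse = rmse)
}
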