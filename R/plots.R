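#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted psychometric curve with its data points
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot: probability of the sucrose-side choice vs %Sucrose,
#'   with the fitted 4PL curve.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  curve <- tibble::tibble(
    s = seq(0, 100, length.out = 201),
    p = logistic4(seq(0, 100, length.out = 201),
                  c(object$p1, object$p2, object$p3, object$p4))
  )
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$s, y = .data$p_sucrose)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p), color = "steelblue") +
    ggplot2::labs(x = "%Sucrose", y = "P(sucrose-side choice)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot decoding accuracy time courses
#'
#' @param timecourse Output of [decode_timecourse()] (optionally several,
#'   row-bound with a `labeling` column).
#' @param threshold Optional horizontal significance threshold.
#' @return A ggplot of accuracy vs warped-axis bin with the chance level
#'   dashed.
#' @export
plot_decoding <- function(timecourse, threshold = NULL) {
  p <- ggplot2::ggplot(timecourse, ggplot2::aes(x = .data$bin, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$chance), linetype = "dashed") +
    ggplot2::labs(x = "warped-axis bin", y = "decoding accuracy") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dotted")
  }
  p
}

#' Plot the coding-type prevalence time course
#'
#' Fraction of units given each coding label per moving window, the
#' moving-window counterpart of the fixed-window classification.
#'
#' @param timecourse Output of [coding_timecourse()].
#' @return A stacked-area ggplot over windows.
#' @export
plot_coding_timecourse <- function(timecourse) {
  tc <- timecourse[timecourse$window_kind == "moving", ]
  n_units <- length(unique(tc$unit))
  frac <- tc |>
    dplyr::filter(.data$label %in% c("linear", "step_perception", "step_choice")) |>
    dplyr::count(.data$window_start_bin, .data$label) |>
    dplyr::mutate(fraction = .data$n / n_units)
  ggplot2::ggplot(frac, ggplot2::aes(
    x = .data$window_start_bin, y = .data$fraction, fill = .data$label
  )) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "window start bin (warped axis)", y = "fraction of units") +
    ggplot2::theme_minimal()
}

#' Plot demixed-PCA projections per condition
#'
#' @param projections Output of [dpca_project()].
#' @param stimulus_set Stimulus values for labeling.
#' @return A ggplot of projection vs bin, colored by stimulus, linetype
#'   by choice.
#' @export
plot_dpca_projection <- function(projections, stimulus_set = stimulus_levels()) {
  df <- projections |>
    dplyr::mutate(
      stimulus = factor(stimulus_set[.data$stimulus_index]),
      choice = factor(c("nacl_side", "sucrose_side")[.data$choice_index])
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin, y = .data$projection,
    color = .data$stimulus, linetype = .data$choice
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "warped-axis bin", y = "projection") +
    ggplot2::theme_minimal()
}
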