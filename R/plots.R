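#' Population growth-trajectory panels
#'
#' Mean trait trajectories by cross type: one panel per trait (free y
#' scale), age on x. Expects the output of
#' `aggregate_means(level = "cross_type")`.
#'
#' @param means Tibble from [aggregate_means()].
#' @param traits Traits to panel (defaults to those present).
#' @return A ggplot.
#' @export
plot_growth_curves <- function(means,
                               traits = intersect(c("dbh", "height", "hdr",
                                                    "volume"),
                                                  names(means))) {
  check_columns(means, c("cross_type", "age", traits), what = "means table")
  long <- tidyr::pivot_longer(means, dplyr::all_of(traits),
                              names_to = "trait", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$value,
                                     colour = .data$cross_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL, colour = "cross") +
    ggplot2::theme_minimal()
}

#' MAI/PAI schedules with the maturity crossing
#'
#' One panel per clone: mean annual increment and periodic annual
#' increment against age, with a vertical mark at the detected
#' quantitative maturity age where available.
#'
#' @param increments Output of [compute_increments()].
#' @param qma Optional output of [detect_qma()] to mark crossings.
#' @return A ggplot.
#' @export
plot_increments <- function(increments, qma = NULL) {
  check_columns(increments, c("clone_id", "age", "mai", "pai"),
                what = "increment table")
  long <- tidyr::pivot_longer(increments, c("mai", "pai"),
                              names_to = "increment", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$value,
                                          colour = .data$increment)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~clone_id, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "volume increment (m3/year)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(qma)) {
    marks <- qma[!is.na(qma$qma_age), c("clone_id", "qma_age")]
    if (nrow(marks) > 0L) {
      p <- p + ggplot2::geom_vline(
        data = marks,
        ggplot2::aes(xintercept = .data$qma_age),
        linetype = "dashed", colour = "grey40"
      )
    }
  }
  p
}

#' Age-age correlation and early-selection efficiency profile
#'
#' The two opposing curves of the early-selection trade-off: the age-age
#' correlation rises with early age (ranking stabilizes) while the
#' efficiency score falls (less time saved), per cross type.
#'
#' @param rows Output of [age_age_table()].
#' @return A ggplot.
#' @export
plot_age_age <- function(rows) {
  check_columns(rows, c("cross_type", "early_age", "r", "ese"),
                what = "age-age table")
  long <- tidyr::pivot_longer(rows, c("r", "ese"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$early_age, .data$value,
                                     colour = .data$cross_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "early age (years)", y = NULL, colour = "cross") +
    ggplot2::theme_minimal()
}

#' Direct and indirect path coefficients of a fit
#'
#' @param object A `path_fit` from [path_decomposition()].
#' @param ... Unused.
#' @return A ggplot: paired bars of DPC and IPC per predictor.
#' @method autoplot path_fit
#' @export
autoplot.path_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("dpc", "ipc"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$predictor, .data$value,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "path coefficient", fill = NULL,
                  title = paste("paths into", object$response)) +
    ggplot2::theme_minimal()
}
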