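#' Plot measured and fitted time-activity curves for one fit
#'
#' Measured frame values (points at frame midpoints) overlaid with the
#' model-predicted TAC (line), the standard visual check of a kinetic fit.
#'
#' @param object A `"tac_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tac_fit
#' @export
autoplot.tac_fit <- function(object, ...) {
  sched <- tac_schedule(object$measured)
  mid <- frame_midpoints(sched)
  df <- tibble::tibble(time_min = mid,
                       measured = object$measured$value,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured), size = 1.2,
                        alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::labs(
      x = "time (min)", y = "activity (SUV)",
      title = sprintf("%s (%s)", object$voi_label, object$measure),
      subtitle = sprintf("Ki = %.4f, WRSS = %.3g, AICc = %.1f",
                         object$Ki, object$wrss, object$aicc)) +
    ggplot2::theme_minimal()
}

#' Plot a dual input-function pair
#'
#' @param inputs An input tibble (`time_min`, `c_ha`, `c_pv`).
#' @param t_max_min Right edge of the plotted window, minutes.
#' @return A ggplot object.
#' @export
plot_input_functions <- function(inputs, t_max_min = 10) {
  long <- tidyr::pivot_longer(
    dplyr::filter(inputs, .data$time_min <= t_max_min),
    c("c_ha", "c_pv"), names_to = "vessel", values_to = "suv")
  long$vessel <- ifelse(long$vessel == "c_ha", "hepatic artery (aorta)",
                        "portal vein")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$suv,
                                     colour = .data$vessel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "activity (SUV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the curves of a tidy TAC table
#'
#' @param tacs A tidy TAC tibble.
#' @return A ggplot object, one panel per measure, one colour per VOI.
#' @export
plot_tacs <- function(tacs) {
  df <- dplyr::mutate(tacs,
                      time_min = (.data$frame_start_s +
                                    .data$frame_duration_s / 2) / 60)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$value,
                                   colour = .data$voi_label)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "time (min)", y = "activity (SUV)", colour = "VOI") +
    ggplot2::theme_minimal()
}
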