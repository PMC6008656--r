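# ggplot2 methods for the main result types

#' Plot a postprandial response
#'
#' @param object A [postprandial_response()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_postprandial <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$time_min, .data$rel, colour = .data$class)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time after meal (min)",
      y = "plasma concentration (fold of fasting)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a postprandial decomposition
#'
#' @param object A [decompose_postprandial()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"time_min",
    names_to = "component", values_to = "delta_uM"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$time_min, .data$delta_uM, colour = .data$component)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time after meal (min)",
      y = "plasma total BA change from fasting (µM)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity ranking
#'
#' @param object A [local_sensitivity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_sensitivity <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$S, stats::reorder(.data$parameter, .data$S))
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sensitivity S", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a profile likelihood
#'
#' @param object A [profile_likelihood()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$nsse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = unique(object$parameter), y = "min nSSE given fixed value"
    ) +
    ggplot2::theme_minimal()
}
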