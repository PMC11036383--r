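# ggplot2 quick-look methods for the main result types.

#' Plot a filtration result
#'
#' Cumulative filtrate volume (mL) against time; the dryland end point is
#' marked.
#'
#' @param object A `filtration_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.filtration_result <- function(object, ...) {
  d <- object$series
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = m3_to_ml(.data$volume_m3))) +
    ggplot2::geom_line(color = "#D55E00") +
    ggplot2::labs(
      x = "time (s)", y = "cumulative filtrate volume (mL)",
      title = paste0("Constant-pressure filtration: ", object$scenario),
      subtitle = paste0("stopped at ", object$stopped_at)
    )
  if (identical(object$stopped_at, "dryland")) {
    p <- p + ggplot2::geom_point(
      data = d[nrow(d), ],
      ggplot2::aes(x = .data$time_s, y = m3_to_ml(.data$volume_m3)),
      shape = 21, size = 2.5
    )
  }
  p
}

#' Plot a washing curve
#'
#' Exit (or hold-up) concentration ratio against cumulative wash ratio, per
#' tracked species, colored by washing regime when the curve is labelled.
#'
#' @param object A `wash_curve` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.wash_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$wash_ratio, y = .data$c_over_c0))
  if ("regime" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$regime), size = 0.8)
  }
  p +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), scales = "free_y") +
    ggplot2::labs(x = "wash ratio W", y = "c / c0", title = "Washing curve")
}

#' Plot a design-space sweep
#'
#' Final-cake impurity concentration against the swept volume, per species,
#' on a log concentration scale.
#'
#' @param object A `sweep_result` from a single-volume sweep.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  vars <- attr(object, "sweep_variables")
  vv <- grep("volume_ml$", vars, value = TRUE)[1]
  if (is.na(vv)) abort_cw("autoplot needs a volume sweep", "invalid_sweep")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("conc_"),
    names_to = "species", values_to = "conc", names_prefix = "conc_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[vv]], y = .data$conc, color = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "wash volume (mL)", y = "final cake impurity conc. (kg/m3 liquor)",
      title = paste0("Design-space sweep: ", attr(object, "provenance")$scenario)
    )
}
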