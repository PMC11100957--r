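# ggplot2 visualizations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an IMU stream
#'
#' Acceleration and angular-rate components over time, faceted by sensor.
#'
#' @param object an [imu_stream()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.imu_stream <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "value") |>
    dplyr::mutate(
      sensor = ifelse(
        startsWith(.data$channel, "a"),
        "acceleration [m/s²]", "angular rate [°/s]"
      )
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
    colour = .data$channel
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~sensor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cueing session timeline
#'
#' Detected motion phases coloured by classification, on-demand cueing
#' intervals, and stimulation pulse trains — the at-a-glance view of what
#' the system did during a trial.
#'
#' @param object a `cueing_session` from [run_pipeline()].
#' @param episodes optional expert FoG episodes to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cueing_session <- function(object, episodes = NULL, ...) {
  lanes <- tibble::tibble(
    lane = c("motion phases", "cueing interval", "pulse trains"),
    y = c(3, 2, 1)
  )
  p <- ggplot2::ggplot() +
    ggplot2::scale_y_continuous(
      breaks = lanes$y, labels = lanes$lane, limits = c(0.5, 3.8)
    ) +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(episodes) && nrow(episodes) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = episodes,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end, ymin = 0.5, ymax = 3.8
      ),
      fill = "magenta", alpha = 0.12
    )
  }
  if (nrow(object$phases) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$phases,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end, ymin = 2.7, ymax = 3.3,
        fill = .data$class_label
      )
    ) +
      ggplot2::scale_fill_manual(
        values = c(normal = "forestgreen", fog = "orange", none = "grey60"),
        name = "classification"
      )
  }
  if (nrow(object$intervals) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end, ymin = 1.7, ymax = 2.3
      ),
      fill = "steelblue", alpha = 0.5
    )
  }
  if (nrow(object$trains) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$trains,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end, ymin = 0.7, ymax = 1.3
      ),
      fill = "red"
    )
  }
  p
}

#' Box plots of detection delays
#'
#' @param object a `fog_delays` from [delay_stats()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fog_delays <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$samples, dplyr::everything(),
    names_to = "measure", values_to = "seconds"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$measure, .data$seconds)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "delay [s]") +
    ggplot2::theme_minimal()
}
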