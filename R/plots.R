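#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cochlear centerline
#'
#' Top view (basal plane projection) of the spiral, coloured by unwound
#' angle, with optional landmark overlay.
#'
#' @param centerline A centerline from [build_centerline()].
#' @param landmarks Optional [landmark_set()] to overlay.
#' @return A ggplot object.
#' @export
plot_centerline <- function(centerline, landmarks = NULL) {
  p <- ggplot2::ggplot(centerline,
                       ggplot2::aes(.data$x_mm, .data$y_mm,
                                    colour = .data$angle_deg)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "angle (deg)",
                  title = "Cochlear centerline, apical view") +
    ggplot2::theme_minimal()
  if (!is.null(landmarks)) {
    p <- p +
      ggplot2::geom_point(data = landmarks, colour = "black", size = 2) +
      ggplot2::geom_text(data = landmarks,
                         ggplot2::aes(label = .data$label),
                         colour = "black", vjust = -0.8, size = 3)
  }
  p
}

#' Autoplot methods
#'
#' For a registration fit: the SSD descent over accepted iterations and the
#' per-landmark errors. For a case report: MAE against the number of
#' remaining landmarks across pruning steps.
#'
#' @param object A `cochlear_registration` or `cochlear_case_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cochlear_registration
#' @export
autoplot.cochlear_registration <- function(object, ...) {
  hist <- tibble::tibble(iteration = seq_along(object$ssd_history) - 1L,
                         ssd_mm2 = object$ssd_history)
  ggplot2::ggplot(hist, ggplot2::aes(.data$iteration, .data$ssd_mm2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "accepted iteration", y = "SSD (mm², log scale)",
                  title = sprintf("Quasi-Newton descent: MAE %.4f mm over %d landmarks",
                                  object$mae, object$n)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cochlear_registration
#' @method autoplot cochlear_case_report
#' @export
autoplot.cochlear_case_report <- function(object, ...) {
  df <- object$steps
  ggplot2::ggplot(df, ggplot2::aes(.data$n_landmarks, .data$mae_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "remaining landmarks", y = "MAE (mm per landmark)",
                  title = "Worst-landmark pruning") +
    ggplot2::theme_minimal()
}

#' Plot per-landmark registration errors
#'
#' @param fit A `cochlear_registration` object.
#' @return A ggplot object.
#' @export
plot_landmark_errors <- function(fit) {
  ggplot2::ggplot(fit$errors,
                  ggplot2::aes(factor(.data$label), .data$error_mm)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "landmark", y = "error (mm)",
                  title = sprintf("Per-landmark error (MAE %.4f mm)", fit$mae)) +
    ggplot2::theme_minimal()
}
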