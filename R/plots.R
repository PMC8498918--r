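# ggplot2 helpers for the main result types.

#' Plot reprojection-error distribution of a calibration
#'
#' @param x A `camera_calibration`.
#' @param object,... Standard autoplot arguments.
#' @return A ggplot.
#' @export
autoplot.camera_calibration <- function(object, ...) {
  df <- object$errors[is.finite(object$errors$error), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey30") +
    ggplot2::facet_wrap(~camera) +
    ggplot2::scale_x_continuous(trans = "sqrt") +
    ggplot2::labs(x = "reprojection error (px)", y = "detections",
                  title = sprintf("mean reprojection error %.3f px",
                                  object$summary$mean_error))
}

#' Plot a 3D trajectory as per-axis time series
#'
#' @param traj Tibble (frame, joint, x, y, z).
#' @param joints Optional subset of joints.
#' @return A ggplot.
#' @export
plot_trajectory <- function(traj, joints = NULL) {
  if (!is.null(joints)) traj <- traj[traj$joint %in% joints, ]
  long <- tidyr::pivot_longer(traj, dplyr::all_of(c("x", "y", "z")),
                              names_to = "axis", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value,
                                     color = .data$joint)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~axis, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "frame", y = "position (world units)")
}

#' Plot averaged power spectra from a reconstruction evaluation
#'
#' @param psd Tibble (freq, truth, recon) from
#'   [evaluate_reconstruction()].
#' @return A ggplot.
#' @export
plot_psd <- function(psd) {
  long <- tidyr::pivot_longer(psd, -"freq", names_to = "signal",
                              values_to = "power")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq, y = .data$power,
                                     color = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (cycles/sample)", y = "power density")
}

#' Plot joint-angle time series
#'
#' @param angles Tibble (frame, joint, kind, value_deg) from
#'   [chain_angles()].
#' @return A ggplot.
#' @export
plot_angles <- function(angles) {
  ggplot2::ggplot(angles, ggplot2::aes(x = .data$frame, y = .data$value_deg,
                                       color = .data$kind)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "angle (deg)")
}
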