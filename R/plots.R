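#' Plot the interplay DVH band of a scenario set
#'
#' The ten starting-phase interplay DVHs (thin red), their mean (blue
#' dashed) and the nominal motion-free DVH (black), the standard
#' per-plan interplay picture.
#'
#' @param object An `interplay_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interplay_result <- function(object, ...) {
  grid <- seq(0, max(object$scenarios, object$nominal) * 1.02,
              length.out = 512)
  scen <- purrr::map_dfr(seq_len(ncol(object$scenarios)), function(s) {
    dplyr::mutate(dvh_curve(object$scenarios[, s], grid),
                  curve = paste0("phase", s - 1))
  })
  nom <- dvh_curve(object$nominal, grid)
  avg <- mean_dvh(object$scenarios, grid)
  ggplot2::ggplot(scen,
                  ggplot2::aes(.data$dose_cgy, 100 * .data$volume_fraction)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$curve),
                       color = "red", alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_line(data = avg, color = "blue", linetype = "dashed") +
    ggplot2::geom_line(data = nom, color = "black") +
    ggplot2::labs(
      x = "Dose [cGy(RBE)]", y = "CTV volume [%]",
      title = sprintf("Interplay DVHs, VR%d (10 starting phases)",
                      object$n_paintings)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the metric trace of a repainting sweep
#'
#' One panel per evaluation metric as a function of the number of
#' paintings, with the CR1 (solid) and CR2 (dashed) thresholds.
#'
#' @param object A `repaint_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repaint_sweep <- function(object, ...) {
  td <- tidy(object)
  thr <- as_tibble(object$criteria)
  ggplot2::ggplot(td, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$class)) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$cr1),
                        linetype = "solid", color = "grey40") +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$cr2),
                        linetype = "dashed", color = "grey60") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = unique(td$x)) +
    ggplot2::labs(x = "Number of paintings X", y = NULL,
                  color = "criterion") +
    ggplot2::theme_minimal()
}

#' Plot a delivery timeline
#'
#' Energy versus time of every sub-spot, colored by painting — the
#' alternating "down"/"up" traversal is directly visible.
#'
#' @param ts A `timed_sequence`.
#' @param beam Beam to plot.
#' @return A ggplot object.
#' @export
plot_timeline <- function(ts, beam = 1) {
  stopifnot(inherits(ts, "timed_sequence"))
  d <- as_tibble(ts) %>% filter(.data$beam == !!beam)
  ggplot2::ggplot(d, ggplot2::aes(.data$t_start_s, .data$energy_mev,
                                  color = factor(.data$painting))) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = "Time [s]", y = "Energy [MeV]", color = "painting") +
    ggplot2::theme_minimal()
}
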