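#' Diagnostic plot for one fitted well
#'
#' Depth signal versus elapsed time with the fitted line(s) overlaid, the
#' breakpoint marked, and — when an NPQ rise was excised — the discarded
#' rise region shaded. Axes follow the assay convention:
#' sqrt(scaled RFU) x depth (mm) against elapsed minutes.
#'
#' @param results A `sink_assay_results` object from [run_assay()].
#' @param well Well ID to plot.
#' @param path Optional file path; when given the figure is written there
#'   (format from the extension) and the path returned invisibly.
#' @param width,height Device size in inches when writing to file.
#' @return A ggplot object (or `path`, invisibly, when writing).
#' @export
plot_well <- function(results, well, path = NULL, width = 6, height = 4) {
  stopifnot(inherits(results, "sink_assay_results"))
  if (!well %in% names(results$fits)) {
    abort(paste0("No successful fit stored for well ", well, "."))
  }
  f <- results$fits[[well]]
  fit <- f$primary$chosen
  trace <- f$trace
  full <- f$full_trace
  grid <- tibble::tibble(
    time_min = seq(min(trace$time_min), max(trace$time_min),
                   length.out = 200)
  )
  grid$fitted <- predict(fit, grid$time_min)
  p <- ggplot2::ggplot(trace,
                       ggplot2::aes(x = .data$time_min,
                                    y = .data$depth_signal)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fitted),
                       colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(
      x = "Elapsed time (min)",
      y = expression(sqrt("Scaled RFU") %*% "depth (mm)"),
      title = paste0("Well ", well, " (", fit$model, " fit)")
    ) +
    ggplot2::theme_minimal()
  if (inherits(fit, "sink_seg_fit")) {
    p <- p + ggplot2::geom_vline(xintercept = fit$breakpoint,
                                 linetype = "dashed", colour = "grey40")
  }
  if (isTRUE(f$npq$npq_corrected)) {
    p <- p +
      ggplot2::annotate("rect", xmin = min(full$time_min),
                        xmax = f$npq$rise_end_min, ymin = -Inf, ymax = Inf,
                        alpha = 0.12, fill = "#d6604d") +
      ggplot2::geom_point(data = full[full$time_min <= f$npq$rise_end_min, ],
                          shape = 1, colour = "#d6604d")
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(path))
  }
  p
}

#' Plot replicate-group sinking rates
#'
#' First-phase (and, where present, second-phase) rates per replicate group
#' with standard-error bars.
#'
#' @param object A `sink_assay_results` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sink_assay_results <- function(object, ...) {
  g <- object$groups |>
    tidyr::pivot_longer(
      cols = c("rate1_mean", "rate2_mean"),
      names_to = "phase", values_to = "rate"
    ) |>
    dplyr::mutate(
      se = ifelse(.data$phase == "rate1_mean", .data$rate1_se,
                  .data$rate2_se),
      phase = ifelse(.data$phase == "rate1_mean", "first", "second")
    ) |>
    dplyr::filter(is.finite(.data$rate))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$replicate_group, y = .data$rate,
                                  fill = .data$phase)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate - .data$se,
                   ymax = .data$rate + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      na.rm = TRUE
    ) +
    ggplot2::labs(x = "Replicate group",
                  y = expression("Sinking rate (m d"^-1 * ")"),
                  fill = "Phase") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Gompertz growth fit
#'
#' @param object A `gompertz_fit` object.
#' @param ... Unused.
#' @return A ggplot of the log-scale data and fitted curve.
#' @export
autoplot.gompertz_fit <- function(object, ...) {
  dat <- tibble::tibble(
    t = object$fit$m$getEnv()$t,
    y = object$fit$m$getEnv()$y
  )
  grid <- tibble::tibble(t = seq(min(dat$t), max(dat$t), length.out = 200))
  grid$y <- gompertz_value(grid$t, object$A, object$mu, object$lam)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(x = "Time (d)", y = "ln(RFU / RFU_min)") +
    ggplot2::theme_minimal()
}
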