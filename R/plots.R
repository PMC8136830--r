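#' Plot a dose-response curve
#'
#' @param object A [dose_response()].
#' @param ... Unused.
#' @return A ggplot (log-log axes).
#' @method autoplot dose_response
#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$input, y = .data$output)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = attr(object, "input_name") %||% "input",
                  y = attr(object, "output_name") %||% "output") +
    ggplot2::theme_minimal()
}

#' Plot a loop-strength sweep
#'
#' FCA, maximum sensitivity and MDL against the loop strength, one facet
#' per metric, with the FCA-optimal loop strength marked.
#'
#' @param object An `fs_sweep` from [sweep_fs()].
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fs_sweep
#' @export
autoplot.fs_sweep <- function(object, metrics = c("fca", "s_max", "mdl"),
                              ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fs, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "argmax_fca"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "loop strength Fs", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a transfer-function fit over its data
#'
#' @param object A `circuit_fit`.
#' @param n_curve Points on the fitted curve (default 200).
#' @param ... Unused.
#' @return A ggplot with data points and the fitted curve, log-log axes.
#' @method autoplot circuit_fit
#' @export
autoplot.circuit_fit <- function(object, n_curve = 200, ...) {
  grid <- log_grid(min(object$data$dose), max(object$data$dose), n_curve)
  curve <- tibble(dose = grid, response = predict(object, grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dose", y = "response",
                  subtitle = sprintf("%s fit: K1 = %.3g, n1 = %.3g",
                                     object$model, object$coef[["K1"]],
                                     object$coef[["n1"]])) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic experiment with replicate spread
#'
#' @param object A `synthetic_experiment` (or `ahl_sweep_experiment`).
#' @param ... Unused.
#' @return A ggplot of pooled geometric means with +/- one sd error bars,
#'   coloured by loop strength when several are present.
#' @method autoplot synthetic_experiment
#' @export
autoplot.synthetic_experiment <- function(object, ...) {
  pooled <- summarize_experiment(object)
  has_fs <- "fs" %in% names(pooled) && dplyr::n_distinct(pooled$fs) > 1L
  mapping <- if (has_fs) {
    ggplot2::aes(x = .data$dose, y = .data$geomean,
                 colour = factor(.data$fs), group = factor(.data$fs))
  } else {
    ggplot2::aes(x = .data$dose, y = .data$geomean)
  }
  ggplot2::ggplot(pooled, mapping) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$geomean - .data$sd_geomean,
                  .data$geomean * 1e-3),
      ymax = .data$geomean + .data$sd_geomean), size = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dose", y = "geometric mean fluorescence",
                  colour = "Fs") +
    ggplot2::theme_minimal()
}

#' @method autoplot ahl_sweep_experiment
#' @export
autoplot.ahl_sweep_experiment <- autoplot.synthetic_experiment

#' Plot a basal-level / loop-strength design diagram
#'
#' @param object A `design_diagram` from [design_diagram()].
#' @param ... Unused.
#' @return A ggplot tile map of the optimal-FCA / optimal-MDL regions.
#' @method autoplot design_diagram
#' @export
autoplot.design_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta, y = .data$fs,
                                       fill = .data$region)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      "both" = "#66c2a5", "optimal-FCA" = "#a6d854",
      "optimal-MDL" = "#ffd92f", "neither" = "grey90")) +
    ggplot2::labs(x = "basal level beta", y = "loop strength Fs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
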