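#' Plot an accuracy quantity against EPV
#'
#' Basic summary plot for study results: one line per estimator (and, where
#' present, per handling policy) of a chosen accuracy quantity as a
#' function of events per variable.
#'
#' @param summaries Summary tibble from [run_study()].
#' @param quantity Column to plot (`"bias"`, `"relative_bias"`,
#'   `"coverage"`, `"mean_ci_width"` or `"mse"`).
#' @return A ggplot object.
#' @export
plot_study <- function(summaries, quantity = "bias") {
  stopifnot(quantity %in% names(summaries))
  d <- dplyr::mutate(
    summaries,
    approach = paste(.data$estimator,
                     ifelse(is.na(.data$detector), "", .data$detector),
                     .data$policy))
  gg <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$epv, y = .data[[quantity]],
                    colour = .data$approach,
                    group = interaction(.data$approach, .data$beta1)))
  if (quantity == "coverage") {
    gg <- gg + ggplot2::geom_hline(yintercept = 0.90, linetype = 2,
                                   colour = "grey50")
  }
  if (quantity %in% c("bias", "relative_bias")) {
    gg <- gg + ggplot2::geom_hline(yintercept = 0, linetype = 2,
                                   colour = "grey50")
  }
  gg +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Events per variable (EPV)", y = quantity,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn detect_tracing Plot the scaled standard-error paths of the
#'   tracing diagnostics (one line per parameter, log scale).
#' @param object An `epv_tracing` object.
#' @param ... Unused.
#' @export
autoplot.epv_tracing <- function(object, ...) {
  paths <- sweep(object$se_paths, 2L, object$se_paths[1L, ], "/")
  d <- tibble::as_tibble(paths) |>
    dplyr::mutate(refit = dplyr::row_number()) |>
    tidyr::pivot_longer(-"refit", names_to = "parameter",
                        values_to = "scaled_se")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$refit, y = .data$scaled_se,
                                  colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Fisher scoring iteration cap",
                  y = "SE scaled to first iteration") +
    ggplot2::theme_minimal()
}
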