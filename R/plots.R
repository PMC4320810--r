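#' Bar chart of the pipeline funnel
#' @param pipeline an `lnc_pipeline` from [run_all()] (or its `funnel`
#'   tibble).
#' @return a ggplot object.
#' @export
plot_funnel <- function(pipeline) {
  funnel <- if (inherits(pipeline, "lnc_pipeline")) pipeline$funnel else pipeline
  check_cols(funnel, c("stage", "n"))
  funnel |>
    dplyr::mutate(stage = factor(.data$stage, levels = rev(.data$stage))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "records") +
    ggplot2::theme_minimal()
}

#' Scatter of H3K4me1 vs H3K4me3 densities colored by chromatin class
#' @param calls tibble from [classify_chromatin()].
#' @return a ggplot object.
#' @export
plot_chromatin_ratio <- function(calls) {
  check_cols(calls, c("me1_density", "me3_density", "chromatin_class"))
  ggplot2::ggplot(calls, ggplot2::aes(
    x = .data$me3_density, y = .data$me1_density,
    colour = .data$chromatin_class
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "H3K4me3 density", y = "H3K4me1 density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Positional class distribution of a catalog
#' @param object an `lnc_catalog` from [build_catalog()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.lnc_catalog <- function(object, ...) {
  tibble::as_tibble(object) |>
    dplyr::count(.data$position_class) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$position_class, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "lncRNAs") +
    ggplot2::theme_minimal()
}
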