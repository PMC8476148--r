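#' Plot a joint allele frequency spectrum
#'
#' Heatmap of the joint AFS on a log10 colour scale, the standard way
#' two-population spectra are displayed (masked entries are blank).
#'
#' @param object a `joint_spectrum`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.joint_spectrum <- function(object, ...) {
  mask <- attr(object, "mask")
  ns <- sample_sizes(object)
  df <- expand.grid(i = 0:ns[1], j = 0:ns[2])
  df$count <- as.vector(unclass(object))
  df$count[as.vector(mask)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = log10(.data$count + 1e-12))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 count", na.value = "grey90") +
    ggplot2::labs(
      x = "derived count, population 2",
      y = "derived count, population 1"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.joint_spectrum <- function(x, ...) print(autoplot.joint_spectrum(x, ...))

#' Plot robustness-suite results
#'
#' True correlation against fitted correlation per scenario, with the
#' identity line; the signature pattern of the robustness study is points
#' hugging the diagonal even when other DFE parameters are biased.
#'
#' @param results tibble from [run_robustness_suite()].
#' @return a ggplot object.
#' @export
plot_robustness <- function(results) {
  stopifnot(all(c("scenario", "w_true", "w_hat") %in% names(results)))
  ggplot2::ggplot(results, ggplot2::aes(.data$w_true, .data$w_hat, colour = .data$scenario)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "true DFE correlation", y = "inferred DFE correlation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
NULL
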