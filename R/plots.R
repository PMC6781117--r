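# Figures mirroring the standard presentation of randomisation mate-choice
# tests: null histograms with the observed value (solid line) and the
# two-tailed 95% CI cutoffs (dashed lines), and the fitted zygosity effect
# with its bootstrap band.

#' Null-distribution histograms for a hypothesis suite
#'
#' One panel per tested statistic: the Monte-Carlo null sample of means as
#' a histogram, the observed value as a solid vertical line, and the
#' 2.5/97.5 percentile cutoffs as dashed lines.
#'
#' @param suite Result tibble from [run_mate_choice_suite()] (must retain
#'   the `null` list-column).
#' @param bins Histogram bins per panel.
#' @return A ggplot object.
#' @export
plot_null_distributions <- function(suite, bins = 40) {
  stopifnot("null" %in% names(suite))
  suite <- dplyr::mutate(
    suite,
    panel = ifelse(is.na(.data$locus), .data$statistic,
                   paste0(.data$statistic, " (", .data$locus, ")")))
  nulls <- suite |>
    dplyr::select("panel", "null") |>
    tidyr::unnest("null")
  marks <- dplyr::select(suite, "panel", "observed", "ci_lower", "ci_upper")
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40", linewidth = 0.1) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$observed),
                        linewidth = 0.7) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$ci_lower),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$ci_upper),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "null sample of means", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Zygosity-effect plot for the reproductive-success model
#'
#' Predicted clutch size per male MHC zygosity class on the response scale,
#' with the cluster-bootstrap 95% band.
#'
#' @param boot_ci Output of [bootstrap_reproductive_ci()].
#' @return A ggplot object.
#' @export
plot_reproductive_effect <- function(boot_ci) {
  boot_ci <- dplyr::mutate(
    boot_ci,
    class = factor(.data$zygosity, levels = c(0, 1),
                   labels = c("homozygote", "heterozygote")))
  ggplot2::ggplot(boot_ci, ggplot2::aes(x = .data$class, y = .data$fitted)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.15, colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "male MHC genotype", y = "predicted offspring per clutch") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.mate_choice_report <- function(object, ...) {
  plot_null_distributions(object$suite, ...)
}
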