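#' Plot the LQV distribution of a GDI run
#'
#' Histogram of per-sample LQV scores with the outlier cutoff, the visual
#' check behind the sample-removal step.
#'
#' @param object A `gdi_result` from [apply_gdi()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gdi_result
#' @export
autoplot.gdi_result <- function(object, ...) {
  ggplot2::ggplot(object$lqv, ggplot2::aes(x = .data$lqv,
                                           fill = .data$outlier)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$config$lqv_outlier_max,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "LQV score (fraction of low-quality variants)",
                  y = "samples", fill = "outlier",
                  title = "Per-sample LQV distribution")
}

#' Plot stratified accuracy by regime and MAF bin
#'
#' Line plot of a chosen metric for a chosen genotype class across MAF
#' bins, one line per filter regime.
#'
#' @param object A `gdi_benchmark` from [run_benchmark()].
#' @param metric One of `"sensitivity"`, `"precision"`, `"nrc"`,
#'   `"dosage_r2"`.
#' @param class Genotype class for class-level metrics (default `"het"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gdi_benchmark
#' @export
autoplot.gdi_benchmark <- function(object, metric = "sensitivity",
                                   class = "het", ...) {
  d <- dplyr::filter(object$metrics, .data$class == !!class,
                     !is.na(.data[[metric]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$maf_bin, y = .data[[metric]],
                                  colour = .data$regime,
                                  group = .data$regime)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "panel MAF bin", y = metric,
                  title = paste0(class, " ", metric,
                                 " by MAF bin and filter regime"))
}

#' Plot the intact-site comparison
#'
#' Bar chart of fully intact variant counts (no missing genotype in any
#' sample) under GDI versus the per-sample max(GP) filter on the same kept
#' variant set — the cumulative-missingness contrast.
#'
#' @param bench A `gdi_benchmark`.
#' @return A ggplot object.
#' @export
plot_missingness <- function(bench) {
  ggplot2::ggplot(bench$missingness,
                  ggplot2::aes(x = .data$filter, y = .data$n_intact,
                               fill = .data$filter)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fully intact variants",
                  title = "Cumulative missingness: GDI vs per-sample GP filter") +
    ggplot2::theme(legend.position = "none")
}
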