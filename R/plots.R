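# ggplot2 views of the result objects.

#' @describeIn pr_curve Plot the precision-recall curve.
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                       y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Heatmap of binned copy numbers along the genome
#'
#' One row per track (clones, bulk-weighted truth, predictions), bins
#' along the x axis, fill showing gain/loss relative to diploid.
#'
#' @param bins A `cn_matrix` tibble from [bin_copy_numbers()] (tracks can
#'   be combined with `bind_rows()` first).
#' @param value Column to plot: `"total"`, `"major"` or `"minor"`.
#' @return A ggplot object.
#' @export
plot_cn_heatmap <- function(bins, value = "total") {
  stopifnot(value %in% c("total", "major", "minor"))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$start / 1e3,
                                     y = .data$track,
                                     fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_gradient2(midpoint = 2, low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  na.value = "grey80", name = value) +
    ggplot2::labs(x = "Position (kb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of true versus estimated CCFs
#'
#' @param cmp A comparison tibble (e.g. `tidy()` of a `ccf_eval`) with
#'   `true_ccf` and `estimated_ccf`.
#' @return A ggplot object with the identity line for reference.
#' @export
plot_ccf_comparison <- function(cmp) {
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$true_ccf,
                                    y = .data$estimated_ccf)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "True CCF", y = "Estimated CCF") +
    ggplot2::theme_minimal()
}
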