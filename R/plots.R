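#' Manhattan plot of a genome-wide scan
#'
#' @param results Scan tibble with chrom, pos and a -log10 p column.
#' @param p_col Column to plot (default `log10p_joint`).
#' @param threshold Significance line (default 5e-8).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, p_col = "log10p_joint", threshold = 5e-8) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$pos, y = .data[[p_col]], color = .data$chrom)
  ) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a null covariance matrix
#'
#' @param object A [null_cov()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_cov
#' @export
autoplot.null_cov <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$trait1, .data$trait2, fill = .data$omega)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(Omega)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of cross-ancestry locus intersections
#'
#' @param object An `overlap_table` from [bin_loci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot overlap_table
#' @export
autoplot.overlap_table <- function(object, ...) {
  as_tibble(object) |>
    mutate(subset = stats::reorder(.data$subset, -.data$count)) |>
    ggplot2::ggplot(ggplot2::aes(.data$subset, .data$count, fill = .data$has_new)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "ancestry subset", y = "1 Mbp loci",
                  fill = "has joint-only") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of multi-trait signal similarity
#'
#' @param similarity Output of [signal_similarity()].
#' @return A ggplot object.
#' @export
plot_similarity <- function(similarity) {
  ggplot2::ggplot(similarity, ggplot2::aes(.data$r2)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::labs(x = expression(R^2 ~ "of multi-trait z vectors"),
                  y = "lead SNP pairs") +
    ggplot2::theme_minimal()
}

#' Specificity curve under simulated downsampling
#'
#' @param curve Output of [downsample_specificity()].
#' @return A ggplot object.
#' @export
plot_specificity <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$fraction, .data$specificity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "simulated sample-size fraction",
                  y = "fraction of loci remaining specific") +
    ggplot2::theme_minimal()
}
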