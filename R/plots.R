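#' Plot a gene coverage profile with its circRNA interval
#'
#' Per-base read depth across the host gene, with the back-splice interval
#' overlaid as a black bar — the classic per-gene panel for inspecting
#' circRNA excess over the linear background.
#'
#' @param object A [coverage_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circleaf_coverage <- function(object, ...) {
  g <- attr(object, "gene")
  j <- attr(object, "junction")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = pos, y = depth)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.8) +
    ggplot2::labs(
      x = paste0(object$chrom[1], " position"), y = "read depth",
      title = if (!is.null(g)) g$gene_id else NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(j)) {
    ymax <- max(object$depth, 1)
    p <- p + ggplot2::annotate(
      "rect", xmin = j$start, xmax = j$end,
      ymin = -0.06 * ymax, ymax = -0.02 * ymax, fill = "black"
    )
  }
  p
}

#' Plot a replicate-reproducibility spectrum
#'
#' @param spectrum A [reproducibility_spectrum()] tibble, or several bound
#'   together with a `genotype` column.
#' @return A ggplot object.
#' @export
plot_reproducibility <- function(spectrum) {
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(x = factor(n_detected), y = fraction)) +
    ggplot2::labs(x = "replicates in which detected", y = "fraction of circRNAs") +
    ggplot2::theme_minimal()
  if ("genotype" %in% names(spectrum)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = genotype), position = "dodge")
  } else {
    p + ggplot2::geom_col(fill = "grey30")
  }
}

#' Scatter plot of a differential circRNA test
#'
#' Wild-type versus mutant normalized means on log scales, significant
#' circRNAs highlighted — the standard two-genotype accumulation panel.
#'
#' @param records A [circ_fold_change_test()] tibble.
#' @param pseudocount Offset for the log axes.
#' @return A ggplot object.
#' @export
plot_differential <- function(records, pseudocount = 0.5) {
  ggplot2::ggplot(
    records,
    ggplot2::aes(x = mean_ref + pseudocount, y = mean_mut + pseudocount,
                 colour = significant)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "reference (normalized + c)", y = "mutant (normalized + c)") +
    ggplot2::theme_minimal()
}
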