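#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a genome-wide extrapolation estimate
#'
#' Bar chart of the estimated genome-wide number of strong high-order-LD
#' predictor pairs per distance class, with error bars showing the
#' estimation error (spread of the per-window estimates).
#'
#' @param object An `extrapolation_estimate` ([extrapolate_genome()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.extrapolation_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$class, y = .data$genome_estimate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$genome_estimate - .data$estimation_error, 0),
        ymax = .data$genome_estimate + .data$estimation_error
      ),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = NULL, y = "estimated strong pairs, genome-wide",
      title = "Genome-wide extrapolation of strong high-order LD"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the second-order LD distribution of a triplet scan
#'
#' Histogram of the retained second-order r-squared values, faceted by
#' cis/trans class, with the strong threshold marked.
#'
#' @param object A `triplet_scan` ([scan_triplets()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triplet_scan <- function(object, ...) {
  ggplot2::ggplot(object$triplets, ggplot2::aes(x = .data$second_order_r2)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(
      xintercept = object$thresholds$strong_r2, linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(
      x = expression("second-order LD " * r^2), y = "retained triplets"
    ) +
    ggplot2::theme_minimal()
}

#' Phenotype distributions of the four two-locus genotype classes
#'
#' Boxplots of a quantitative phenotype by the four two-locus genotype
#' classes of a marker pair — the standard display for inspecting a
#' statistical-epistasis signal (e.g. an intermediate / intermediate /
#' low / high pattern that suggests high-order LD with a hidden locus
#' rather than functional interaction).
#'
#' @param y Numeric phenotype aligned with the genotype columns.
#' @param g1,g2 Genotype code vectors in `{0, 1, NA}`.
#' @param labels Optional length-2 character vector naming the markers.
#' @return A ggplot object.
#' @export
plot_pair_phenotypes <- function(y, g1, g2, labels = c("M1", "M2")) {
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  cls <- paste0(
    ifelse(g1[ok] == 0, "0", "1"), "/", ifelse(g2[ok] == 0, "0", "1")
  )
  dat <- tibble::tibble(class = cls, value = y[ok])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(
      x = paste0("two-locus genotype (", labels[1], "/", labels[2], ")"),
      y = "phenotype"
    ) +
    ggplot2::theme_minimal()
}
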