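#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom tibble as_tibble
#' @importFrom ggplot2 autoplot
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @export
tibble::as_tibble

#' @export
ggplot2::autoplot

#' Plot replication-timing profiles
#'
#' One line per sample along a chromosome, in the matrix's current units
#' (copies for raw states, Z for smoothed).
#'
#' @param object An [rt_matrix()].
#' @param chrom Chromosome to plot (default: first).
#' @param samples Samples to plot (default: first 5).
#' @param peaks Optional peak tibble; cluster centers drawn as dashed
#'   lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rt_matrix
#' @export
autoplot.rt_matrix <- function(object, chrom = NULL, samples = NULL,
                               peaks = NULL, ...) {
  chrom <- chrom %||% object$grid$chrom[1]
  samples <- samples %||% utils::head(rownames(object$values), 5)
  df <- as_tibble(object) |>
    dplyr::filter(.data$chrom == !!chrom, .data$sample %in% samples)
  p <- ggplot2::ggplot(df, ggplot2::aes((.data$start + .data$end) / 2e6,
                                        .data$value,
                                        colour = .data$sample)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom),
                  y = switch(object$state, smoothed = "timing (Z)",
                             "copy number"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    pk <- peaks[peaks$chrom == chrom, ]
    p <- p + ggplot2::geom_vline(xintercept = pk$center / 1e6,
                                 linetype = "dashed", alpha = 0.4)
  }
  p
}

#' Plot pooled additivity of early-replicating alleles
#'
#' @param object An `rt_additivity` fit.
#' @param ... Unused.
#' @return A ggplot object: timing by early-allele count with the fitted
#'   regression line.
#' @method autoplot rt_additivity
#' @export
autoplot.rt_additivity <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$n_early, .data$timing)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.35, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "firebrick") +
    ggplot2::labs(x = "early-replicating alleles",
                  y = if (object$scale == "relative")
                    "relative timing (Z)" else "timing (Z)") +
    ggplot2::theme_minimal()
}

#' Plot feature enrichment folds
#'
#' @param enrichment Tibble of [feature_enrichment()] rows with a
#'   `feature` column.
#' @param alpha Significance highlight level on the stored p-values.
#' @return A ggplot bar chart of fold enrichment.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.05) {
  df <- dplyr::mutate(enrichment,
                      significant = .data$p < alpha,
                      feature = stats::reorder(.data$feature, .data$fold))
  ggplot2::ggplot(df, ggplot2::aes(.data$fold, .data$feature,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "fold enrichment", y = NULL,
                  fill = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a prediction ROC curve
#'
#' @param roc Result of [roc_curve()].
#' @return A ggplot object with the AUC annotated.
#' @export
plot_roc <- function(roc) {
  df <- roc$roc
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         alpha = 0.5) +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
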