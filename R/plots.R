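#' Plot per-class variant fractions
#'
#' Bar chart of the common/shared/private composition of regionally detected
#' variants.
#'
#' @param classification A `variant_classification`.
#' @return A ggplot.
#' @export
plot_class_fractions <- function(classification) {
  cf <- concordance_fractions(classification)
  cf$class <- factor(cf$class, levels = c("common", "shared", "private"))
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$class, y = .data$fraction,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "fraction of detected variants") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_class_fractions VAF distribution by class (boxplot of the
#'   maximum regional VAF).
#' @param x A `variant_classification`.
#' @param ... Unused.
#' @export
autoplot.variant_classification <- function(x, ...) {
  d <- dplyr::filter(tibble::as_tibble(x), .data$class != "absent")
  d$class <- factor(d$class, levels = c("common", "shared", "private"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$max_regional_vaf,
                                  fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "maximum regional VAF") +
    ggplot2::theme_minimal()
}

#' Pooled versus mean regional VAF scatter plot
#'
#' One point per variant detected in at least one region: mean regional VAF
#' against the observed VAF in the pooled (or mixed) sample, with the
#' identity line and the Pearson correlation in the subtitle.
#'
#' @param classification A `variant_classification`.
#' @param pooled_calls `call_set` of the pooled (or mixed) sample.
#' @return A ggplot.
#' @export
plot_pooled_vaf <- function(classification, pooled_calls) {
  regional <- classification$class != "absent"
  d <- tibble(
    mean_regional_vaf = classification$mean_regional_vaf[regional],
    pooled_vaf = pooled_calls$vaf[regional],
    class = classification$class[regional]
  )
  r <- suppressWarnings(vaf_correlation(classification, pooled_calls)$r[1])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_regional_vaf,
                                  y = .data$pooled_vaf,
                                  colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean regional VAF", y = "pooled VAF",
                  subtitle = sprintf("Pearson r = %.3f", r)) +
    ggplot2::theme_minimal()
}

#' @describeIn pca_variant_profiles Scatter plot of the first two
#'   variant-profile principal components, labelled by sample.
#' @param x A `variant_pca`.
#' @param ... Unused.
#' @export
autoplot.variant_pca <- function(x, ...) {
  ggplot2::ggplot(tibble::as_tibble(x),
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' @describeIn compare_expression Grouped bar chart of fold-change fractions
#'   per sample pair and threshold.
#' @param x An `expression_comparison`.
#' @param ... Unused.
#' @export
autoplot.expression_comparison <- function(x, ...) {
  d <- mutate(x$foldchange,
              pair = paste(.data$sample_a, .data$sample_b, sep = " vs "),
              threshold = factor(paste0("> ", .data$threshold, "-fold")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$fraction,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~threshold, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fraction of genes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a detection-power sweep
#'
#' Power curves from [sweep_detection()]: detection probability against true
#' regional VAF for the home region, a random single biopsy, and the
#' equal-weight pooled sample, faceted by depth.
#'
#' @param power Tibble returned by [sweep_detection()].
#' @return A ggplot.
#' @export
plot_power_sweep <- function(power) {
  d <- tidyr::pivot_longer(power, dplyr::starts_with("power_"),
                           names_to = "sample", values_to = "power") %>%
    mutate(sample = sub("^power_", "", .data$sample))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vaf, y = .data$power,
                                  colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~depth, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "true regional VAF", y = "detection power",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
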