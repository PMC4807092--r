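#' Tidy and glance methods for mrpool result objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per variant, per class, per sample pair), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name mrpool-tidiers
NULL

#' @rdname mrpool-tidiers
#' @export
tidy.variant_classification <- function(x, ...) {
  as_tibble(x)
}

#' @rdname mrpool-tidiers
#' @export
glance.variant_classification <- function(x, ...) {
  cf <- concordance_fractions(x)
  tibble(
    n_variants = nrow(x),
    n_detected = sum(cf$n),
    n_common = cf$n[cf$class == "common"],
    n_shared = cf$n[cf$class == "shared"],
    n_private = cf$n[cf$class == "private"],
    fraction_common = cf$fraction[cf$class == "common"],
    fraction_shared = cf$fraction[cf$class == "shared"],
    fraction_private = cf$fraction[cf$class == "private"]
  )
}

#' @rdname mrpool-tidiers
#' @export
tidy.pooled_detection_stats <- function(x, ...) {
  tidyr::pivot_longer(x$by_class, c("pooled_rate", "mixed_rate"),
                      names_to = "sample", values_to = "detection_rate") %>%
    mutate(sample = sub("_rate$", "", .data$sample))
}

#' @rdname mrpool-tidiers
#' @export
glance.pooled_detection_stats <- function(x, ...) {
  b <- x$by_class
  tibble(
    pooled_detection_common = b$pooled_rate[b$class == "common"],
    pooled_detection_shared = b$pooled_rate[b$class == "shared"],
    pooled_detection_private = b$pooled_rate[b$class == "private"],
    missed_moderate_fraction = x$missed_moderate_fraction,
    single_biopsy_rate = x$single_biopsy_rate
  )
}

#' @rdname mrpool-tidiers
#' @export
tidy.expression_comparison <- function(x, ...) {
  x$foldchange
}

#' @rdname mrpool-tidiers
#' @export
glance.expression_comparison <- function(x, ...) {
  pool_cols <- if (!is.null(x$pooled_id)) {
    colnames(x$correlations) == x$pooled_id
  } else rep(FALSE, ncol(x$correlations))
  rr <- x$correlations[!pool_cols, !pool_cols, drop = FALSE]
  tibble(
    n_genes_retained = length(x$retained_genes),
    n_genes_total = x$n_genes_total,
    mean_cor_regions = mean(rr[upper.tri(rr)]),
    min_cor = min(x$correlations[upper.tri(x$correlations)]),
    max_foldchange_fraction = max(x$foldchange$fraction)
  )
}

#' @rdname mrpool-tidiers
#' @export
tidy.mrpool_experiment <- function(x, ...) {
  tibble(statistic = names(x$summary),
         value = vapply(x$summary, as.numeric, numeric(1)))
}

#' @rdname mrpool-tidiers
#' @export
glance.mrpool_experiment <- function(x, ...) {
  as_tibble(x$summary)
}
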