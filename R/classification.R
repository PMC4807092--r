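#' Classify variants across regional call sets
#'
#' Applies the common/shared/private taxonomy to variants observed across
#' regional samples: a variant detected (and passing all filters) in all `n`
#' regions is *common*, in exactly one region *private*, in at least 2 but
#' at most `n - 1` regions *shared*, and in none *absent*. Also records each
#' variant's per-region detection vector, maximum regional VAF and mean
#' regional VAF (mean over all regions; regions where the variant is not a
#' passing call contribute 0 — the arithmetic that governs dilution in a
#' pool).
#'
#' @param regional_callsets List of >= 2 `call_set` objects over identical
#'   loci (one per region).
#' @param zero_undetected Should regions without a passing detection
#'   contribute VAF 0 to the mean (default), rather than their raw observed
#'   alt fraction?
#' @return A `variant_classification`: a tibble with columns `variant_id`,
#'   `class`, `n_regions_detected`, `max_regional_vaf`, `mean_regional_vaf`.
#'   The per-region detection and VAF matrices are kept as attributes
#'   `"detection"` and `"vaf_matrix"`.
#' @examples
#' truth <- make_truth(sim_config(seed = 7, n_genes = 50))
#' calls <- lapply(simulate_tumor(truth), function(r)
#'   apply_variant_filters(detect_variants(r), truth$variants))
#' cls <- classify_variants(calls)
#' dplyr::count(cls, class)
#' @export
classify_variants <- function(regional_callsets, zero_undetected = TRUE) {
  if (length(regional_callsets) < 2) {
    abort("need call sets from at least 2 regions")
  }
  ids <- regional_callsets[[1]]$variant_id
  for (cs in regional_callsets[-1]) {
    if (!identical(cs$variant_id, ids)) {
      abort(sprintf("call sets cover inconsistent loci (sample '%s')",
                    cs$sample_id[1] %||% "?"))
    }
  }
  nr <- length(regional_callsets)
  det <- vapply(regional_callsets,
                function(cs) cs$detected & cs$filter_status == "PASS",
                logical(length(ids)))
  vafs <- vapply(regional_callsets, function(cs) cs$vaf, numeric(length(ids)))
  dimnames(det) <- dimnames(vafs) <-
    list(ids, vapply(regional_callsets, function(cs) cs$sample_id[1], character(1)))

  eff_vaf <- if (zero_undetected) vafs * det else vafs
  ndet <- rowSums(det)
  out <- tibble(
    variant_id = ids,
    class = dplyr::case_when(
      ndet == nr ~ "common",
      ndet == 1 ~ "private",
      ndet >= 2 ~ "shared",
      TRUE ~ "absent"
    ),
    n_regions_detected = as.integer(ndet),
    max_regional_vaf = apply(eff_vaf, 1, max),
    mean_regional_vaf = rowMeans(eff_vaf)
  )
  class(out) <- c("variant_classification", class(out))
  attr(out, "detection") <- det
  attr(out, "vaf_matrix") <- vafs
  attr(out, "n_regions") <- nr
  out
}

#' Per-class concordance fractions
#'
#' Fraction of regionally detected variants (detected in >= 1 region) that
#' are common, shared or private — the regional concordance summary.
#'
#' @param classification A `variant_classification`.
#' @return Tibble with columns `class`, `n`, `fraction`; fractions sum to 1
#'   over the three classes (absent variants are excluded).
#' @export
concordance_fractions <- function(classification) {
  stopifnot(inherits(classification, "variant_classification"))
  det <- dplyr::filter(tibble::as_tibble(classification), .data$class != "absent")
  total <- nrow(det)
  tibble(class = c("common", "shared", "private")) %>%
    left_join(dplyr::count(det, .data$class), by = "class") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           fraction = if (total > 0) .data$n / total else NA_real_)
}

#' Detection of regionally identified variants in pooled and mixed samples
#'
#' Quantifies what pooling detects and misses: per class, the fraction of
#' regionally detected variants that are also passing calls in the pooled
#' (and optionally the in-silico mixed) sample; the fraction of
#' moderate-VAF variants (max regional VAF above `vaf_threshold`) missed by
#' the pool; and the single-biopsy expectation — the average over regions of
#' the fraction of regionally detected variants that would be found by
#' sampling that one region (for private variants spread uniformly over 4
#' regions this is 25%).
#'
#' @param classification A `variant_classification`.
#' @param pooled_calls `call_set` of the pooled sample over the same loci.
#' @param mixed_calls Optional `call_set` of the mixed sample.
#' @param vaf_threshold Moderate-VAF cutoff, default 0.20 (strict `>`).
#' @param shared_only Restrict the missed-moderate-VAF statistic to shared
#'   variants (`FALSE` by default: all regionally detected variants count).
#' @return A `pooled_detection_stats` object: list with `by_class` (tibble:
#'   `class`, `n`, `pooled_rate`, `mixed_rate`), `missed_moderate_fraction`,
#'   `single_biopsy_rate`, `vaf_threshold`.
#' @export
pooled_detection_stats <- function(classification, pooled_calls,
                                   mixed_calls = NULL, vaf_threshold = 0.20,
                                   shared_only = FALSE) {
  stopifnot(inherits(classification, "variant_classification"),
            inherits(pooled_calls, "call_set"))
  ids <- classification$variant_id
  if (!identical(pooled_calls$variant_id, ids)) {
    abort("pooled call set covers different loci than the classification")
  }
  pool_det <- pooled_calls$detected & pooled_calls$filter_status == "PASS"
  mix_det <- if (!is.null(mixed_calls)) {
    if (!identical(mixed_calls$variant_id, ids)) {
      abort("mixed call set covers different loci than the classification")
    }
    mixed_calls$detected & mixed_calls$filter_status == "PASS"
  }

  regional <- classification$class != "absent"
  by_class <- tibble(class = c("common", "shared", "private")) %>%
    left_join(
      tibble(class = classification$class[regional],
             pooled = pool_det[regional],
             mixed = if (is.null(mix_det)) NA else mix_det[regional]) %>%
        group_by(.data$class) %>%
        summarise(n = n(),
                  pooled_rate = mean(.data$pooled),
                  mixed_rate = mean(.data$mixed)),
      by = "class") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))

  moderate <- regional & classification$max_regional_vaf > vaf_threshold
  if (shared_only) moderate <- moderate & classification$class == "shared"
  missed <- if (any(moderate)) mean(!pool_det[moderate]) else NA_real_

  det <- attr(classification, "detection")
  single <- mean(colMeans(det[regional, , drop = FALSE]))

  structure(
    list(by_class = by_class,
         missed_moderate_fraction = missed,
         single_biopsy_rate = single,
         vaf_threshold = vaf_threshold,
         shared_only = shared_only),
    class = "pooled_detection_stats"
  )
}

#' @export
print.pooled_detection_stats <- function(x, ...) {
  cat("<pooled_detection_stats>\n")
  print(x$by_class)
  cat(sprintf("  missed moderate-VAF (> %.0f%%) fraction: %s\n",
              100 * x$vaf_threshold,
              ifelse(is.na(x$missed_moderate_fraction), "NA",
                     sprintf("%.3f", x$missed_moderate_fraction))))
  cat(sprintf("  single-biopsy expectation: %.3f\n", x$single_biopsy_rate))
  invisible(x)
}

#' Correlation between mean regional VAF and pooled (or mixed) VAF
#'
#' Pearson correlation, over variants detected in at least one region,
#' between the mean regional VAF and the observed VAF of the pooled sample
#' (and optionally the mixed sample). Variants undetected in the pool
#' contribute their observed pooled alt fraction (possibly 0).
#'
#' @param classification A `variant_classification`.
#' @param pooled_calls `call_set` of the pooled sample.
#' @param mixed_calls Optional `call_set` of the mixed sample.
#' @return Tibble with columns `comparison` (`"pooled"`, `"mixed"`), `r` and
#'   `n_variants`. Zero-variance (degenerate) input yields `NA` with a
#'   warning.
#' @export
vaf_correlation <- function(classification, pooled_calls, mixed_calls = NULL) {
  stopifnot(inherits(classification, "variant_classification"))
  regional <- classification$class != "absent"
  x <- classification$mean_regional_vaf[regional]

  one <- function(calls, label) {
    if (!identical(calls$variant_id, classification$variant_id)) {
      abort(sprintf("%s call set covers different loci than the classification", label))
    }
    if (sum(calls$detected & calls$filter_status == "PASS") < 3) {
      abort(sprintf("need >= 3 variants detected in the %s sample", label))
    }
    y <- calls$vaf[regional]
    if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warn(sprintf("VAF correlation with %s sample undefined (zero variance)", label))
      return(tibble(comparison = label, r = NA_real_, n_variants = length(x)))
    }
    tibble(comparison = label, r = cor(x, y), n_variants = length(x))
  }

  out <- one(pooled_calls, "pooled")
  if (!is.null(mixed_calls)) out <- bind_rows(out, one(mixed_calls, "mixed"))
  out
}

#' Quartile summary of observed regional VAFs per variant class
#'
#' Summarises the VAF distribution of common, shared and private variants as
#' observed in the regional samples: every (variant, region) pair where the
#' variant is a passing detection contributes one VAF observation to its
#' variant's class. In truncal-dominated architectures the common-variant
#' median sits near 0.40 while shared and private variants sit at low VAF.
#' (The per-variant *maximum* regional VAF, used by the moderate-VAF missed
#' statistic, is summarised instead when `statistic = "max"`; its median is
#' biased upward by the maximum over noisy regional measurements.)
#'
#' @param classification A `variant_classification`.
#' @param statistic `"regional"` (default): one observation per detected
#'   (variant, region) pair; `"max"`: one observation per variant, its
#'   maximum regional VAF.
#' @return Tibble with columns `class`, `n`, `q25`, `median`, `q75` (NA for
#'   empty classes).
#' @export
vaf_distribution_by_class <- function(classification,
                                      statistic = c("regional", "max")) {
  stopifnot(inherits(classification, "variant_classification"))
  statistic <- match.arg(statistic)
  tab <- tibble::as_tibble(classification)
  if (statistic == "max") {
    det <- dplyr::filter(tab, .data$class != "absent")
    obs <- tibble(class = det$class, vaf = det$max_regional_vaf)
  } else {
    det_m <- attr(classification, "detection")
    vaf_m <- attr(classification, "vaf_matrix")
    idx <- which(det_m, arr.ind = TRUE)
    obs <- tibble(class = tab$class[idx[, 1]], vaf = vaf_m[idx])
  }
  tibble(class = c("common", "shared", "private")) %>%
    left_join(
      obs %>%
        group_by(.data$class) %>%
        summarise(n = n(),
                  q25 = quantile(.data$vaf, 0.25, names = FALSE),
                  median = median(.data$vaf),
                  q75 = quantile(.data$vaf, 0.75, names = FALSE)),
      by = "class") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Principal components of variant-VAF profiles across samples
#'
#' Builds the samples x variants matrix of observed VAFs (0 where a variant
#' is not a passing call in that sample), column-centers it, and returns the
#' first two principal-component scores from an eigendecomposition of the
#' covariance matrix. Samples from the same tumor group together in this
#' 2-D space. Sign convention: for each component, the loading of largest
#' magnitude is made positive, so coordinates are deterministic.
#'
#' Call sets may cover different loci (e.g. several tumors); the matrix is
#' built over the union of loci with VAF 0 where a sample lacks the locus.
#'
#' @param callsets List of `call_set` objects (all samples to embed).
#' @return A `variant_pca`: tibble with columns `sample_id`, `PC1`, `PC2`;
#'   component standard deviations in attribute `"sdev"`.
#' @export
pca_variant_profiles <- function(callsets) {
  if (length(callsets) < 2) abort("need at least 2 call sets")
  sample_ids <- vapply(callsets, function(cs) cs$sample_id[1], character(1))
  all_ids <- unique(unlist(lapply(callsets, function(cs) cs$variant_id)))
  X <- matrix(0, length(callsets), length(all_ids),
              dimnames = list(sample_ids, all_ids))
  for (i in seq_along(callsets)) {
    cs <- callsets[[i]]
    ok <- cs$detected & cs$filter_status == "PASS"
    X[i, cs$variant_id[ok]] <- cs$vaf[ok]
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(S, symmetric = TRUE)
  V <- eig$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  out <- tibble(sample_id = sample_ids,
                PC1 = unname(scores[, 1]), PC2 = unname(scores[, 2]))
  class(out) <- c("variant_pca", class(out))
  attr(out, "sdev") <- sqrt(pmax(eig$values[1:2], 0))
  out
}
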