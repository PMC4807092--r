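#' Filter lowly expressed genes
#'
#' Keeps a gene iff its maximum read count across all samples is strictly
#' greater than `min_count` (default 20).
#'
#' @param counts Genes x samples matrix of nonnegative counts (or a data
#'   frame whose first column holds gene identifiers).
#' @param min_count Threshold on the per-gene maximum count (strict `>`).
#' @return The retained counts matrix (rownames = gene ids).
#' @examples
#' m <- rbind(a = c(0, 21), b = c(20, 20))
#' filter_low_expression(m)
#' @export
filter_low_expression <- function(counts, min_count = 20) {
  counts <- as_count_matrix(counts)
  counts[apply(counts, 1, max) > min_count, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample scaling factors for count
#' libraries: against a reference sample (the one whose upper-quartile count
#' is closest to the mean upper quartile), gene-wise log2 ratios (M) and
#' average log2 abundances (A) are computed over genes nonzero in both
#' samples, the extreme 30% of M and 5% of A are trimmed, and the factor is
#' 2 to the precision-weighted mean of the remaining M values, with weights
#' from binomial delta-method variances. Factors are rescaled so their
#' geometric mean is 1. Computed via [edgeR::calcNormFactors()], whose TMM
#' implementation is exactly this procedure.
#'
#' @param counts Genes x samples count matrix (>= 2 samples).
#' @param ... Passed on to [edgeR::calcNormFactors()] (e.g. `logratioTrim`,
#'   `sumTrim`).
#' @return Named numeric vector of scaling factors, one per sample.
#' @export
tmm_factors <- function(counts, ...) {
  counts <- as_count_matrix(counts)
  if (ncol(counts) < 2) abort("TMM needs at least 2 samples")
  if (any(counts < 0)) abort("counts must be nonnegative")
  f <- edgeR::calcNormFactors(counts, method = "TMM", ...)
  if (any(!is.finite(f))) {
    abort("TMM factors undefined: a sample shares no nonzero genes with the reference")
  }
  setNames(as.numeric(f), colnames(counts))
}

#' TMM-normalized expression values
#'
#' Divides each sample by its effective library size (library size times TMM
#' factor) and rescales by the mean effective library size, so normalized
#' values stay on a count-like scale.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Per-sample scaling factors; defaults to [tmm_factors()].
#' @return Matrix of normalized values, same dimensions as `counts`.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  counts <- as_count_matrix(counts)
  factors <- factors %||% tmm_factors(counts)
  eff <- colSums(counts) * factors
  sweep(counts, 2, eff, "/") * mean(eff)
}

#' Pairwise Pearson correlations of log2 expression
#'
#' Pearson correlation of `log2(normalized value + pseudocount)` for every
#' sample pair, over the retained genes.
#'
#' @param normalized Genes x samples matrix of normalized values.
#' @param pseudocount Added before the log2 transform; default 1.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(normalized, pseudocount = 1) {
  normalized <- as_count_matrix(normalized)
  cor(log2(normalized + pseudocount))
}

#' Fold-change fractions between sample pairs
#'
#' For every pair of regional samples (six pairs with four regions) and
#' every region-versus-pooled pair, the fraction of retained genes whose
#' expression differs by more than each fold threshold:
#' `|log2((a + 1) / (b + 1))| > log2(threshold)` on normalized values.
#'
#' @param normalized Genes x samples matrix of normalized values.
#' @param pooled_id Column name of the pooled sample; `NULL` if none (only
#'   region-vs-region pairs are reported).
#' @param thresholds Fold-change cutoffs, default `c(2, 3, 4)`.
#' @param pseudocount Added before the log2 ratio; default 1.
#' @return Tibble with columns `sample_a`, `sample_b`, `group`
#'   (`"region_vs_region"` or `"region_vs_pooled"`), `threshold`, `n_genes`,
#'   `fraction`.
#' @export
foldchange_fractions <- function(normalized, pooled_id = NULL,
                                 thresholds = c(2, 3, 4), pseudocount = 1) {
  normalized <- as_count_matrix(normalized)
  samples <- colnames(normalized)
  if (!is.null(pooled_id) && !pooled_id %in% samples) {
    abort(sprintf("pooled sample '%s' not found among columns", pooled_id))
  }
  regions <- setdiff(samples, pooled_id)
  pairs <- list()
  if (length(regions) >= 2) {
    cmb <- utils::combn(regions, 2)
    pairs <- purrr::map(seq_len(ncol(cmb)),
                        ~ list(a = cmb[1, .x], b = cmb[2, .x],
                               group = "region_vs_region"))
  }
  if (!is.null(pooled_id)) {
    pairs <- c(pairs, purrr::map(regions,
                                 ~ list(a = .x, b = pooled_id,
                                        group = "region_vs_pooled")))
  }
  L <- log2(normalized + pseudocount)
  purrr::map_dfr(pairs, function(p) {
    d <- abs(L[, p$a] - L[, p$b])
    tibble(sample_a = p$a, sample_b = p$b, group = p$group,
           threshold = thresholds,
           n_genes = nrow(normalized),
           fraction = vapply(thresholds, function(t) mean(d > log2(t)),
                             numeric(1)))
  })
}

#' Full transcriptome comparison of regional and pooled samples
#'
#' Runs the expression pipeline end to end: low-expression gene filter
#' (max count > 20), TMM normalization, pairwise log2 Pearson correlations,
#' and fold-change fractions at the 2/3/4-fold thresholds for all
#' region-vs-region and region-vs-pooled pairs.
#'
#' @param counts Genes x samples count matrix including the pooled sample.
#' @param pooled_id Column name of the pooled sample (`NULL` if none).
#' @param min_count Low-expression threshold, default 20.
#' @param thresholds Fold-change cutoffs, default `c(2, 3, 4)`.
#' @return An `expression_comparison`: list with `retained_genes`,
#'   `factors`, `correlations` (matrix), `foldchange` (tibble) and
#'   `n_genes_total`.
#' @examples
#' truth <- make_truth(sim_config(seed = 7, n_genes = 500))
#' regions <- simulate_tumor(truth)
#' counts <- expression_matrix(c(regions, list(pooled = pool_physical(regions))))
#' cmp <- compare_expression(counts, pooled_id = "pooled")
#' glance(cmp)
#' @export
compare_expression <- function(counts, pooled_id = NULL, min_count = 20,
                               thresholds = c(2, 3, 4)) {
  counts <- as_count_matrix(counts)
  kept <- filter_low_expression(counts, min_count)
  if (nrow(kept) < 2) abort("fewer than 2 genes pass the expression filter")
  factors <- tmm_factors(kept)
  norm <- normalize_counts(kept, factors)
  structure(
    list(retained_genes = rownames(kept),
         factors = factors,
         correlations = pairwise_correlation(norm),
         foldchange = foldchange_fractions(norm, pooled_id, thresholds),
         n_genes_total = nrow(counts),
         pooled_id = pooled_id),
    class = "expression_comparison"
  )
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf("<expression_comparison> %d/%d genes retained\n",
              length(x$retained_genes), x$n_genes_total))
  cat("  TMM factors:", paste(sprintf("%s=%.3f", names(x$factors), x$factors),
                              collapse = ", "), "\n")
  off <- x$correlations[upper.tri(x$correlations)]
  cat(sprintf("  pairwise log2 Pearson r: %.3f-%.3f (mean %.3f)\n",
              min(off), max(off), mean(off)))
  invisible(x)
}

#' Assemble a genes x samples count matrix from read sets
#'
#' @param read_sets List of `read_set` objects sharing the same gene list.
#' @return Integer matrix (genes x samples) with sample ids as column names.
#' @export
expression_matrix <- function(read_sets) {
  check_matching_read_sets(read_sets)
  m <- vapply(read_sets, function(r) r$expr_counts,
              numeric(length(read_sets[[1]]$expr_counts)))
  colnames(m) <- vapply(read_sets, function(r) r$sample_id, character(1))
  rownames(m) <- names(read_sets[[1]]$expr_counts)
  m
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    first <- counts[[1]]
    if (is.character(first) || is.factor(first)) {
      m <- as.matrix(counts[, -1, drop = FALSE])
      rownames(m) <- as.character(first)
      return(m)
    }
    return(as.matrix(counts))
  }
  if (!is.matrix(counts)) abort("`counts` must be a matrix or data frame")
  counts
}
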