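#' Physically pooled sample from regional read sets
#'
#' Models one sequencing library prepared from physically mixed tissue of
#' several tumor regions. Per variant locus, the pooled true signal fraction
#' is the weighted average of the regional observed alternate-read fractions,
#' and the pooled alternate-read count is drawn binomially at `pooled_depth`
#' from that fraction (the pool is re-sequenced, not a sum of regional
#' reads). Expression counts are a weighted mixture of the regional
#' expression *rates*, re-sampled (multinomial) to a library size equal to
#' the mean regional library size.
#'
#' With equal weights and equal regional depths the expected pooled VAF at a
#' locus equals the arithmetic mean of the regional VAFs — the dilution law:
#' a private variant at VAF v in one of four regions is expected at v/4 in
#' the pool.
#'
#' @param regions List of regional `read_set` objects sharing the same loci
#'   and gene list.
#' @param weights Per-region mixing fractions (nonnegative, summing to 1);
#'   default equal weights.
#' @param pooled_depth Sequencing depth of the pooled library at every locus;
#'   default the rounded mean regional depth.
#' @param sample_id Name of the pooled sample.
#' @param seed RNG seed; defaults to the current RNG state.
#' @return A `read_set` with `kind = "pooled"`.
#' @examples
#' truth <- make_truth(sim_config(seed = 7, n_genes = 100))
#' regions <- simulate_tumor(truth)
#' pooled <- pool_physical(regions)
#' @export
pool_physical <- function(regions, weights = NULL, pooled_depth = NULL,
                          sample_id = "pooled", seed = NULL) {
  check_matching_read_sets(regions)
  k <- length(regions)
  weights <- weights %||% rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be nonnegative, one per region, and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)

  depths <- vapply(regions, function(r) r$variants$depth, numeric(nrow(regions[[1]]$variants)))
  alts <- vapply(regions, function(r) r$variants$alt_count, numeric(nrow(regions[[1]]$variants)))
  frac <- alts / pmax(depths, 1)  # observed alt fraction, 0 where depth 0
  frac[depths == 0] <- 0
  q <- drop(frac %*% weights)

  pooled_depth <- pooled_depth %||% round(mean(depths))
  n <- length(q)
  alt_pool <- rbinom(n, pooled_depth, q)

  expr <- vapply(regions, function(r) r$expr_counts, numeric(length(regions[[1]]$expr_counts)))
  lib <- colSums(expr)
  rate <- sweep(expr, 2, pmax(lib, 1), "/") %*% weights
  target <- round(mean(lib))
  pooled_expr <- drop(rmultinom(1, target, drop(rate)))
  names(pooled_expr) <- names(regions[[1]]$expr_counts)

  new_read_set(
    sample_id = sample_id, kind = "pooled",
    variants = mutate(select(regions[[1]]$variants, "variant_id", "chrom",
                             "pos", "ref", "alt"),
                      depth = as.integer(pooled_depth),
                      alt_count = .env$alt_pool),
    expr_counts = pooled_expr
  )
}

#' In-silico mixed sample by read subsampling
#'
#' Computational counterpart of pooling: from each regional sample a fixed
#' fraction of reads is chosen at random without replacement and the chosen
#' reads are combined. Per variant locus and region, `round(fraction * depth)`
#' reads are drawn hypergeometrically from that region's alternate/reference
#' reads; the mixed record is the sum over regions. Expression counts are
#' subsampled the same way: each gene's retained count is a hypergeometric
#' draw of `round(fraction * library size)` reads from the library (marginals
#' of choosing a fixed fraction of all reads; draws are independent across
#' genes).
#'
#' @param regions List of regional `read_set` objects sharing loci and genes.
#' @param fraction Subsampling fraction per region, in (0, 1]; the default
#'   0.25 combines a quarter of each of four regional samples.
#' @param sample_id Name of the mixed sample.
#' @param seed RNG seed; defaults to the current RNG state.
#' @return A `read_set` with `kind = "mixed"`.
#' @examples
#' truth <- make_truth(sim_config(seed = 7, n_genes = 100))
#' mixed <- mix_in_silico(simulate_tumor(truth))
#' @export
mix_in_silico <- function(regions, fraction = 0.25, sample_id = "mixed",
                          seed = NULL) {
  check_matching_read_sets(regions)
  if (!(is.numeric(fraction) && length(fraction) == 1 &&
        fraction > 0 && fraction <= 1)) {
    abort("`fraction` must be a single value in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(regions[[1]]$variants)
  depth_mix <- integer(n)
  alt_mix <- integer(n)
  for (r in regions) {
    d <- r$variants$depth
    a <- r$variants$alt_count
    k <- round(fraction * d)
    sel <- rhyper(n, m = a, n = d - a, k = k)
    depth_mix <- depth_mix + as.integer(k)
    alt_mix <- alt_mix + as.integer(sel)
  }

  g <- length(regions[[1]]$expr_counts)
  expr_mix <- integer(g)
  for (r in regions) {
    cnt <- r$expr_counts
    lib <- sum(cnt)
    kk <- round(fraction * lib)
    sel <- rhyper(g, m = cnt, n = lib - cnt, k = kk)
    expr_mix <- expr_mix + as.integer(sel)
  }
  names(expr_mix) <- names(regions[[1]]$expr_counts)

  new_read_set(
    sample_id = sample_id, kind = "mixed",
    variants = mutate(select(regions[[1]]$variants, "variant_id", "chrom",
                             "pos", "ref", "alt"),
                      depth = depth_mix, alt_count = alt_mix),
    expr_counts = expr_mix
  )
}
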