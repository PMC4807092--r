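#' Simulate observed sequencing evidence for one tumor region
#'
#' Stand-in for library preparation, sequencing and alignment of a regional
#' biopsy: per variant locus a sequencing depth is drawn (negative binomial
#' around `depth_mean`; Poisson when `depth_dispersion` is 0) and the
#' alternate-read count is binomial with success probability
#' `p = v * (1 - e) + (1 - v) * e / 3`, where `v` is the region's true VAF
#' and `e` the per-base error rate. Absent variants (`v = 0`) therefore still
#' yield occasional error reads at rate `e / 3`. Gene-expression counts are
#' drawn from a negative binomial with mean `gene_means * region_effects`.
#'
#' @param truth A `truth_set` from [make_truth()].
#' @param region Region index in `1:n_regions`.
#' @param seed RNG seed for this sample; defaults to a fixed offset of the
#'   configuration seed so each region has its own reproducible stream.
#' @return An object of class `read_set`: a list with `sample_id`, `kind`
#'   (`"region"`), `variants` (tibble: `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_count`) and `expr_counts` (named integer vector,
#'   one entry per gene).
#' @examples
#' truth <- make_truth(sim_config(seed = 7, n_genes = 100))
#' rs <- simulate_region_counts(truth, 1)
#' head(rs$variants)
#' @export
simulate_region_counts <- function(truth, region, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  cfg <- truth$config
  if (!(is.numeric(region) && length(region) == 1 && region >= 1 &&
        region <= cfg$n_regions)) {
    abort(sprintf("`region` must be a single index in 1..%d", cfg$n_regions))
  }
  region <- as.integer(region)
  set.seed(seed %||% derive_seed(cfg$seed, "region", region))

  n <- nrow(truth$variants)
  depth <- draw_depth(n, cfg$depth_mean, cfg$depth_dispersion)
  v <- truth$vaf[, region]
  p <- v * (1 - cfg$error_rate) + (1 - v) * cfg$error_rate / 3
  alt_reads <- rbinom(n, depth, p)

  mu <- truth$gene_means * truth$region_effects[, region]
  expr <- draw_counts(mu, cfg$expr_dispersion)
  names(expr) <- names(truth$gene_means)

  new_read_set(
    sample_id = paste0("region_", region),
    kind = "region",
    variants = mutate(select(truth$variants, "variant_id", "chrom", "pos",
                             "ref", "alt"),
                      depth = .env$depth, alt_count = .env$alt_reads),
    expr_counts = expr
  )
}

#' Simulate all regional read sets of a tumor
#'
#' Convenience wrapper running [simulate_region_counts()] for every region.
#'
#' @param truth A `truth_set`.
#' @return Named list of `read_set` objects, one per region.
#' @export
simulate_tumor <- function(truth) {
  stopifnot(inherits(truth, "truth_set"))
  regions <- purrr::map(seq_len(truth$config$n_regions),
                        ~ simulate_region_counts(truth, .x))
  setNames(regions, purrr::map_chr(regions, "sample_id"))
}

draw_depth <- function(n, mean, dispersion) {
  if (dispersion > 0) rnbinom(n, mu = mean, size = 1 / dispersion)
  else rpois(n, mean)
}

draw_counts <- function(mu, dispersion) {
  if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  else rpois(length(mu), mu)
}

new_read_set <- function(sample_id, kind, variants, expr_counts) {
  stopifnot(all(variants$alt_count <= variants$depth),
            all(variants$alt_count >= 0))
  structure(list(sample_id = sample_id, kind = kind,
                 variants = as_tibble(variants), expr_counts = expr_counts),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s (%s): %d variant loci, %d genes\n",
              x$sample_id, x$kind, nrow(x$variants), length(x$expr_counts)))
  cat(sprintf("  mean depth %.1fx, total expression reads %s\n",
              mean(x$variants$depth),
              format(sum(x$expr_counts), big.mark = ",")))
  invisible(x)
}

# shared input check for pooling operations: same loci and gene universe
check_matching_read_sets <- function(regions) {
  if (length(regions) < 1) abort("need at least 1 regional read set")
  ref <- regions[[1]]
  for (i in seq_along(regions)[-1]) {
    ids <- regions[[i]]$variants$variant_id
    if (length(ids) != nrow(ref$variants) ||
        length(regions[[i]]$expr_counts) != length(ref$expr_counts)) {
      abort(sprintf(
        "read sets disagree in size: sample '%s' has %d loci / %d genes, expected %d / %d",
        regions[[i]]$sample_id, length(ids), length(regions[[i]]$expr_counts),
        nrow(ref$variants), length(ref$expr_counts)))
    }
    if (!identical(ids, ref$variants$variant_id)) {
      bad <- which(ids != ref$variants$variant_id | is.na(ids))[1] %||% 1L
      abort(sprintf(
        "read sets disagree on variant loci: sample '%s' locus %d is '%s', expected '%s'",
        regions[[i]]$sample_id, bad, ids[bad] %||% "<missing>",
        ref$variants$variant_id[bad]))
    }
    if (!identical(names(regions[[i]]$expr_counts), names(ref$expr_counts))) {
      mism <- which(names(regions[[i]]$expr_counts) != names(ref$expr_counts))[1]
      abort(sprintf(
        "read sets disagree on gene lists: sample '%s' gene %d is '%s', expected '%s'",
        regions[[i]]$sample_id, mism %||% 1L,
        names(regions[[i]]$expr_counts)[mism %||% 1L],
        names(ref$expr_counts)[mism %||% 1L]))
    }
  }
  invisible(TRUE)
}
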