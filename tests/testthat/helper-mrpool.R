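# Builders for hand-crafted fixtures; all synthetic, generated in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

tiny_config <- function(...) {
  defaults <- list(n_truncal = 12L, n_shared = 6L, n_private = 8L,
                   n_germline_het = 10L, n_germline_hom = 5L,
                   n_genes = 200L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# read set with fixed depths/alt counts at dummy loci
manual_read_set <- function(depth, alt, sample_id = "s1", expr = NULL,
                            n_genes = 5L) {
  n <- length(depth)
  expr <- expr %||% stats::setNames(rep(100L, n_genes),
                                    sprintf("gene%05d", seq_len(n_genes)))
  alt_reads <- as.integer(alt)
  mrpool:::new_read_set(
    sample_id = sample_id, kind = "region",
    variants = tibble::tibble(
      variant_id = sprintf("var%05d", seq_len(n)),
      chrom = "chr1", pos = seq_len(n), ref = "A", alt = "C",
      depth = as.integer(depth), alt_count = !!alt_reads),
    expr_counts = expr
  )
}

# call set with prescribed detection and VAF (depth/alt made consistent)
manual_call_set <- function(detected, vaf, sample_id = "s1", depth = 1000L,
                            ids = NULL, filter_status = NULL) {
  n <- length(detected)
  ids <- ids %||% sprintf("var%05d", seq_len(n))
  mrpool:::new_call_set(tibble::tibble(
    variant_id = ids, chrom = "chr1", pos = seq_len(n), ref = "A", alt = "C",
    sample_id = sample_id,
    depth = as.integer(rep(depth, length.out = n)),
    alt_count = as.integer(round(vaf * rep(depth, length.out = n))),
    vaf = vaf,
    detected = detected,
    filter_status = filter_status %||%
      ifelse(detected, "PASS", "NOT_DETECTED")
  ))
}

# list of n_regions random call sets over shared loci
random_call_sets <- function(n_var, n_regions, seed, p_detect = 0.5) {
  set.seed(seed)
  lapply(seq_len(n_regions), function(r) {
    det <- stats::runif(n_var) < p_detect
    manual_call_set(det, ifelse(det, round(stats::runif(n_var, 0.05, 0.6), 3), 0),
                    sample_id = paste0("region_", r))
  })
}

# random annotation flags for filter tests
random_flags <- function(ids, seed) {
  set.seed(seed)
  n <- length(ids)
  tibble::tibble(
    variant_id = ids,
    in_dbsnp = stats::runif(n) < 0.5,
    pop_af_gt_1pct = stats::runif(n) < 0.5,
    in_cosmic_or_tcga = stats::runif(n) < 0.3,
    in_panel337 = stats::runif(n) < 0.3
  )
}
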