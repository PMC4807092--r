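#' Run a full multi-region vs pooled experiment
#'
#' End-to-end pipeline: simulate the ground truth and regional read sets,
#' build the physically pooled and in-silico mixed samples, call variants in
#' every sample with the binomial stand-in caller, apply the
#' homozygous/germline (and optionally gene-panel) filters, classify
#' variants as common/shared/private, compute the pooled/mixed detection and
#' VAF-correlation statistics, and run the transcriptome comparison on the
#' regional plus pooled expression counts.
#'
#' All randomness flows from `config$seed` via fixed per-sample offsets, so
#' a re-run with the same configuration is bit-identical. When `outdir` is
#' given, the truth VCF, one call VCF per sample, the per-variant
#' classification TSV, the expression count TSV and a `summary.json` with
#' every headline statistic are written there; if any stage fails, partial
#' outputs are removed and the error names the stage.
#'
#' @param config A [sim_config()] (or a path to a JSON configuration file).
#' @param outdir Optional output directory for the report bundle.
#' @param panel Apply the 337-gene panel filter? Default `FALSE`.
#' @param mix_fraction Read fraction per region for the in-silico mixed
#'   sample, default 0.25.
#' @param min_alt,alpha Stand-in caller parameters.
#' @return An `mrpool_experiment`: list with `config`, `truth`, `read_sets`,
#'   `callsets`, `classification`, `concordance`, `detection_stats`,
#'   `correlation`, `vaf_by_class`, `pca`, `expression`, and `summary`
#'   (plain named list of headline numbers).
#' @examples
#' \donttest{
#' exp <- run_experiment(sim_config(seed = 1, n_genes = 1000))
#' exp$summary$fraction_common
#' }
#' @export
run_experiment <- function(config = sim_config(), outdir = NULL,
                           panel = FALSE, mix_fraction = 0.25,
                           min_alt = 4L, alpha = 1e-6) {
  if (is.character(config)) config <- read_config_json(config)
  config <- validate_sim_config(config)

  created <- FALSE
  if (!is.null(outdir)) {
    created <- !dir.exists(outdir)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir)) {
        if (created) unlink(outdir, recursive = TRUE)
        else unlink(list.files(outdir, full.names = TRUE))
      }
      abort(sprintf("experiment failed at stage '%s': %s", name,
                    conditionMessage(e)))
    })
  }

  truth <- stage("simulate", make_truth(config))
  regions <- stage("simulate", simulate_tumor(truth))
  pooled <- stage("pool", pool_physical(
    regions, pooled_depth = round(config$depth_mean),
    seed = derive_seed(config$seed, "pool")))
  mixed <- stage("mix", mix_in_silico(
    regions, fraction = mix_fraction,
    seed = derive_seed(config$seed, "mix")))

  call_one <- function(rs) {
    detect_variants(rs, min_alt = min_alt, alpha = alpha,
                    error_rate = config$error_rate) %>%
      apply_variant_filters(truth$variants, panel = panel)
  }
  callsets <- stage("call", purrr::map(regions, call_one))
  pooled_calls <- stage("call", call_one(pooled))
  mixed_calls <- stage("call", call_one(mixed))

  classification <- stage("classify", classify_variants(callsets))
  concordance <- stage("classify", concordance_fractions(classification))
  det_stats <- stage("classify", pooled_detection_stats(
    classification, pooled_calls, mixed_calls))
  correlation <- stage("classify", vaf_correlation(
    classification, pooled_calls, mixed_calls))
  vaf_by_class <- stage("classify", vaf_distribution_by_class(classification))
  pca <- stage("classify", pca_variant_profiles(
    c(callsets, list(pooled = pooled_calls, mixed = mixed_calls))))

  counts <- stage("expression", expression_matrix(c(regions, list(pooled = pooled))))
  expression <- stage("expression", compare_expression(counts, pooled_id = "pooled"))

  summary <- experiment_summary(config, concordance, det_stats, correlation,
                                expression)

  result <- structure(
    list(config = config, truth = truth,
         read_sets = c(regions, list(pooled = pooled, mixed = mixed)),
         callsets = c(callsets, list(pooled = pooled_calls, mixed = mixed_calls)),
         classification = classification, concordance = concordance,
         detection_stats = det_stats, correlation = correlation,
         vaf_by_class = vaf_by_class, pca = pca, expression = expression,
         summary = summary),
    class = "mrpool_experiment"
  )

  if (!is.null(outdir)) stage("write", write_experiment(result, outdir))
  result
}

experiment_summary <- function(config, concordance, det_stats, correlation,
                               expression) {
  frac <- function(cl) concordance$fraction[concordance$class == cl]
  rate <- function(cl, col) det_stats$by_class[[col]][det_stats$by_class$class == cl]
  off <- expression$correlations[upper.tri(expression$correlations)]
  pool_cols <- grepl("pooled", colnames(expression$correlations))
  region_cor <- expression$correlations[!pool_cols, !pool_cols]
  list(
    seed = config$seed,
    n_variants_detected = sum(concordance$n),
    fraction_common = frac("common"),
    fraction_shared = frac("shared"),
    fraction_private = frac("private"),
    pooled_detection_common = rate("common", "pooled_rate"),
    pooled_detection_shared = rate("shared", "pooled_rate"),
    pooled_detection_private = rate("private", "pooled_rate"),
    mixed_detection_common = rate("common", "mixed_rate"),
    missed_moderate_vaf_fraction = det_stats$missed_moderate_fraction,
    single_biopsy_rate = det_stats$single_biopsy_rate,
    vaf_correlation_pooled = correlation$r[correlation$comparison == "pooled"],
    vaf_correlation_mixed = correlation$r[correlation$comparison == "mixed"],
    n_genes_retained = length(expression$retained_genes),
    mean_expression_cor_regions = mean(region_cor[upper.tri(region_cor)]),
    mean_expression_cor_all = mean(off),
    max_foldchange_fraction_2x = max(
      expression$foldchange$fraction[expression$foldchange$threshold == 2])
  )
}

write_experiment <- function(result, outdir) {
  write_truth_vcf(result$truth, file.path(outdir, "truth.vcf"))
  for (cs in result$callsets) {
    write_call_vcf(cs, file.path(outdir, paste0("calls_", cs$sample_id[1], ".vcf")))
  }
  readr::write_tsv(tibble::as_tibble(result$classification),
                   file.path(outdir, "classification.tsv"))
  readr::write_tsv(result$expression$foldchange,
                   file.path(outdir, "foldchange_fractions.tsv"))
  readr::write_tsv(tibble::as_tibble(result$pca),
                   file.path(outdir, "pca_coordinates.tsv"))
  write_counts_tsv(expression_matrix(result$read_sets),
                   file.path(outdir, "expression_counts.tsv"))
  write_config_json(result$config, file.path(outdir, "config.json"))
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.mrpool_experiment <- function(x, ...) {
  s <- x$summary
  cat("<mrpool_experiment>\n")
  cat(sprintf("  %d variants detected in >= 1 region: %.1f%% common, %.1f%% shared, %.1f%% private\n",
              s$n_variants_detected, 100 * s$fraction_common,
              100 * s$fraction_shared, 100 * s$fraction_private))
  cat(sprintf("  pooled detection: common %.1f%%, shared %.1f%%, private %.1f%%\n",
              100 * s$pooled_detection_common, 100 * s$pooled_detection_shared,
              100 * s$pooled_detection_private))
  cat(sprintf("  VAF correlation (pooled vs mean regional): r = %.3f\n",
              s$vaf_correlation_pooled))
  cat(sprintf("  expression: %d genes retained, mean regional r = %.3f\n",
              s$n_genes_retained, s$mean_expression_cor_regions))
  invisible(x)
}

#' Detection-power sweep over allele frequency and depth
#'
#' Monte-Carlo power of detecting a private variant (present in one of
#' `n_regions` regions) in (a) its home region, (b) one randomly chosen
#' regional biopsy, and (c) the equal-weight pooled sample sequenced at the
#' same depth, for every combination of true VAF and sequencing depth.
#' The pooled sample is simulated through the pooling mechanics: regional
#' alternate fractions are drawn (home region at the variant's VAF, other
#' regions at error level), averaged, and re-sequenced at the same depth.
#'
#' Common random numbers are used across the grid (the same uniforms drive
#' every (VAF, depth) cell through inverse-CDF sampling), so power is exactly
#' monotone in VAF and depth rather than monotone only up to Monte-Carlo
#' noise.
#'
#' @param vaf_grid True regional VAFs to scan.
#' @param depth_grid Sequencing depths to scan.
#' @param n_replicates Monte-Carlo replicates per cell.
#' @param seed RNG seed.
#' @param n_regions Number of regions, default 4.
#' @param error_rate Sequencing error rate, default 1e-3.
#' @param min_alt,alpha Stand-in caller parameters.
#' @return Tibble with columns `vaf`, `depth`, `power_home`,
#'   `power_single_biopsy`, `power_pooled`.
#' @examples
#' sweep_detection(c(0.05, 0.4), 137, n_replicates = 200, seed = 1)
#' @export
sweep_detection <- function(vaf_grid, depth_grid, n_replicates = 1000,
                            seed = 1L, n_regions = 4L, error_rate = 1e-3,
                            min_alt = 4L, alpha = 1e-6) {
  stopifnot(all(vaf_grid >= 0 & vaf_grid <= 1), all(depth_grid >= 1),
            n_replicates >= 1)
  set.seed(derive_seed(seed, "sweep"))
  n <- n_replicates
  u_home <- runif(n)
  u_other <- matrix(runif(n * (n_regions - 1)), n, n_regions - 1)
  u_pick <- runif(n)
  u_pool <- runif(n)
  pick_home <- ceiling(u_pick * n_regions) == 1L

  p_of <- function(v) v * (1 - error_rate) + (1 - v) * error_rate / 3

  grid <- tidyr::expand_grid(vaf = sort(vaf_grid), depth = depth_grid)
  purrr::pmap_dfr(grid, function(vaf, depth) {
    alt_home <- qbinom(u_home, depth, p_of(vaf))
    det_home <- detect_decision(alt_home, depth, min_alt, alpha, error_rate)
    alt_other <- qbinom(u_other, depth, p_of(0))
    q <- (alt_home + rowSums(matrix(alt_other, n))) / (n_regions * depth)
    alt_pool <- qbinom(u_pool, depth, q)
    det_pool <- detect_decision(alt_pool, depth, min_alt, alpha, error_rate)
    tibble(vaf = vaf, depth = depth,
           power_home = mean(det_home),
           power_single_biopsy = mean(pick_home & det_home),
           power_pooled = mean(det_pool))
  })
}
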