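#' Simulation configuration for a multi-regional tumor experiment
#'
#' Collects every tunable of the synthetic-data generator: the clonal
#' architecture (how many truncal, shared and private somatic variants, plus
#' germline heterozygous/homozygous SNPs), the allele-frequency model, the
#' sequencing-depth model, and the gene-expression model. One object of this
#' class, together with its `seed`, fully determines a simulated tumor:
#' identical configurations give bit-identical outputs.
#'
#' @details
#' Defaults describe a four-region exome/transcriptome experiment: mean
#' target coverage 137x with mild overdispersion (standard deviation about
#' 17x), truncal variant allele frequencies centered at 0.40, subclonal
#' (shared/private) frequencies uniform on `vaf_subclonal_range`, and 18,161
#' coding genes of which a small minority carry a region-specific expression
#' fold change. Class counts default to an architecture dominated by truncal
#' variants, the regime observed in multi-region exome studies of solid
#' tumors.
#'
#' @param n_regions Number of regional biopsies (>= 2).
#' @param n_truncal,n_shared,n_private Somatic variant counts per class:
#'   truncal variants exist in every region, shared variants in a strict
#'   subset of at least two regions, private variants in exactly one region.
#' @param n_germline_het,n_germline_hom Germline SNP counts (true VAF 0.5 and
#'   1.0 in every region).
#' @param vaf_truncal_mean Center of the truncal VAF distribution (fraction).
#' @param vaf_truncal_sd Spread of truncal VAFs (normal, truncated to
#'   (0.02, 0.98)).
#' @param vaf_subclonal_range Length-2 numeric, uniform VAF range for shared
#'   and private variants in the regions where they are present.
#' @param depth_mean Mean sequencing depth per locus.
#' @param depth_dispersion Negative-binomial dispersion of per-locus depth
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson depth.
#' @param error_rate Per-base sequencing error fraction; an absent allele is
#'   still read with probability `error_rate / 3`.
#' @param n_genes Number of coding genes in the expression model.
#' @param frac_de_genes Fraction of genes with a region-specific fold change.
#' @param de_fold_range Length-2 numeric, bounds of the fold change assigned
#'   to differentially expressed genes (lower bound > 1); the direction
#'   (up/down) is random.
#' @param expr_dispersion Negative-binomial dispersion of expression counts;
#'   0 gives Poisson counts.
#' @param frac_cosmic Fraction of somatic variants flagged as present in
#'   COSMIC/TCGA.
#' @param frac_panel Fraction of somatic variants falling in the 337-gene
#'   cancer panel.
#' @param seed Integer RNG seed; all per-sample random streams are derived
#'   from it by fixed offsets, so adding samples never perturbs earlier ones.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$depth_mean
#' @export
sim_config <- function(n_regions = 4L,
                       n_truncal = 70L,
                       n_shared = 20L,
                       n_private = 20L,
                       n_germline_het = 150L,
                       n_germline_hom = 50L,
                       vaf_truncal_mean = 0.40,
                       vaf_truncal_sd = 0.05,
                       vaf_subclonal_range = c(0.02, 0.30),
                       depth_mean = 137,
                       depth_dispersion = 0.009,
                       error_rate = 1e-3,
                       n_genes = 18161L,
                       frac_de_genes = 0.05,
                       de_fold_range = c(2, 6),
                       expr_dispersion = 0.01,
                       frac_cosmic = 0.10,
                       frac_panel = 0.15,
                       seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    n_truncal = as.integer(n_truncal),
    n_shared = as.integer(n_shared),
    n_private = as.integer(n_private),
    n_germline_het = as.integer(n_germline_het),
    n_germline_hom = as.integer(n_germline_hom),
    vaf_truncal_mean = vaf_truncal_mean,
    vaf_truncal_sd = vaf_truncal_sd,
    vaf_subclonal_range = vaf_subclonal_range,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    error_rate = error_rate,
    n_genes = as.integer(n_genes),
    frac_de_genes = frac_de_genes,
    de_fold_range = de_fold_range,
    expr_dispersion = expr_dispersion,
    frac_cosmic = frac_cosmic,
    frac_panel = frac_panel,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every field of a [sim_config()]; errors name the offending field.
#'
#' @param cfg A `sim_config` object (or a bare list with the same fields,
#'   e.g. read back from JSON).
#' @return The validated `sim_config`, invisibly classed.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(sprintf("invalid config field `%s`: %s", field, msg))
  }
  scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  chk(scalar_num(cfg$n_regions) && cfg$n_regions >= 2, "n_regions", "must be >= 2")
  for (f in c("n_truncal", "n_shared", "n_private", "n_germline_het",
              "n_germline_hom", "n_genes")) {
    chk(scalar_num(cfg[[f]]) && cfg[[f]] >= 0, f, "must be a count >= 0")
  }
  for (f in c("vaf_truncal_mean", "error_rate", "frac_de_genes",
              "frac_cosmic", "frac_panel")) {
    chk(scalar_num(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f,
        "must be a fraction in [0, 1]")
  }
  chk(scalar_num(cfg$vaf_truncal_sd) && cfg$vaf_truncal_sd >= 0,
      "vaf_truncal_sd", "must be >= 0")
  chk(is.numeric(cfg$vaf_subclonal_range) && length(cfg$vaf_subclonal_range) == 2 &&
        all(cfg$vaf_subclonal_range >= 0 & cfg$vaf_subclonal_range <= 1) &&
        cfg$vaf_subclonal_range[1] <= cfg$vaf_subclonal_range[2],
      "vaf_subclonal_range", "must be an increasing pair of fractions in [0, 1]")
  chk(scalar_num(cfg$depth_mean) && cfg$depth_mean > 0, "depth_mean", "must be > 0")
  chk(scalar_num(cfg$depth_dispersion) && cfg$depth_dispersion >= 0,
      "depth_dispersion", "must be >= 0")
  chk(is.numeric(cfg$de_fold_range) && length(cfg$de_fold_range) == 2 &&
        cfg$de_fold_range[1] > 1 && cfg$de_fold_range[1] <= cfg$de_fold_range[2],
      "de_fold_range", "lower bound must be > 1 and <= upper bound")
  chk(scalar_num(cfg$expr_dispersion) && cfg$expr_dispersion >= 0,
      "expr_dispersion", "must be >= 0")
  chk(scalar_num(cfg$seed), "seed", "must be a single integer")

  if (!inherits(cfg, "sim_config")) class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  regions: %d | somatic: %d truncal / %d shared / %d private | germline: %d het / %d hom\n",
              x$n_regions, x$n_truncal, x$n_shared, x$n_private,
              x$n_germline_het, x$n_germline_hom))
  cat(sprintf("  depth: mean %.0fx (dispersion %.3g), error rate %.1g\n",
              x$depth_mean, x$depth_dispersion, x$error_rate))
  cat(sprintf("  VAF: truncal %.2f +/- %.2f, subclonal U(%.2f, %.2f)\n",
              x$vaf_truncal_mean, x$vaf_truncal_sd,
              x$vaf_subclonal_range[1], x$vaf_subclonal_range[2]))
  cat(sprintf("  expression: %d genes, %.1f%% DE (fold %.1f-%.1f), dispersion %.3g\n",
              x$n_genes, 100 * x$frac_de_genes, x$de_fold_range[1],
              x$de_fold_range[2], x$expr_dispersion))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Derived per-sample RNG seeds: fixed offsets from the global seed so adding
# samples never perturbs earlier streams. Kept well below .Machine$integer.max.
derive_seed <- function(seed, stream, index = 0L) {
  offsets <- c(truth = 0L, region = 10000L, pool = 20000L, mix = 30000L,
               sweep = 40000L)
  base <- offsets[[stream]] + as.integer(index)
  as.integer((as.numeric(seed) + base) %% .Machine$integer.max)
}
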