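#' Generate the ground-truth clonal architecture of a simulated tumor
#'
#' Draws the full truth set for one tumor: somatic variants partitioned into
#' truncal (present in every region), shared (a strict subset of >= 2
#' regions) and private (exactly one region) classes, germline heterozygous
#' and homozygous SNPs, per-region true variant allele frequencies,
#' annotation flags used by the downstream filters, and the gene-expression
#' model (baseline per-gene means plus region-specific fold effects for a
#' minority of genes).
#'
#' Each truncal variant gets one clonal prevalence, drawn from a truncated
#' normal centered at `vaf_truncal_mean` and shared by every region (regional
#' scatter arises from sequencing noise); shared/private VAFs are drawn
#' uniformly on `vaf_subclonal_range`, independently for each region where
#' the variant is present. Germline variants have exact VAF 0.5 (het) or 1.0 (hom) in every
#' region and carry dbSNP/population-frequency flags so that the germline
#' filter removes most of them; a configurable fraction of somatic variants
#' is flagged as COSMIC/TCGA-listed and as falling in the 337-gene cancer
#' panel.
#'
#' @param config A [sim_config()].
#' @return An object of class `truth_set`: a list with elements
#'   * `config`: the configuration used;
#'   * `variants`: a tibble with one row per variant (`variant_id`, `chrom`,
#'     `pos`, `ref`, `alt`, `origin`, and logical flags `in_dbsnp`,
#'     `pop_af_gt_1pct`, `in_cosmic_or_tcga`, `in_panel337`);
#'   * `vaf`: numeric matrix (variants x regions) of true VAFs, 0 where a
#'     variant is absent;
#'   * `gene_means`: named numeric vector of baseline expression means;
#'   * `region_effects`: numeric matrix (genes x regions) of fold
#'     multipliers, 1 for unaffected genes.
#' @examples
#' truth <- make_truth(sim_config(seed = 7))
#' table(truth$variants$origin)
#' @export
make_truth <- function(config) {
  config <- validate_sim_config(config)
  set.seed(derive_seed(config$seed, "truth"))
  nr <- config$n_regions

  counts <- c(somatic_truncal = config$n_truncal,
              somatic_shared = config$n_shared,
              somatic_private = config$n_private,
              germline_het = config$n_germline_het,
              germline_hom = config$n_germline_hom)
  n_var <- sum(counts)
  origin <- rep(names(counts), counts)

  bases <- c("A", "C", "G", "T")
  pos <- sample.int(2e8, n_var)
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  variants <- tibble(
    variant_id = sprintf("var%05d", seq_len(n_var)),
    chrom = paste0("chr", sample.int(22, n_var, replace = TRUE)),
    pos = pos,
    ref = ref,
    alt = unname(alt),
    origin = origin
  )

  # presence sets per class
  presence <- matrix(FALSE, n_var, nr,
                     dimnames = list(variants$variant_id,
                                     paste0("region_", seq_len(nr))))
  presence[origin %in% c("somatic_truncal", "germline_het", "germline_hom"), ] <- TRUE
  if (config$n_shared > 0 && nr < 3) {
    # a shared variant occupies a strict subset of >= 2 regions
    abort("invalid config field `n_shared`: shared variants need n_regions >= 3")
  }
  shared_sizes <- 2:(nr - 1L)
  for (i in which(origin == "somatic_shared")) {
    k <- shared_sizes[sample.int(length(shared_sizes), 1)]
    presence[i, sample.int(nr, k)] <- TRUE
  }
  for (i in which(origin == "somatic_private")) {
    presence[i, sample.int(nr, 1)] <- TRUE
  }

  # true per-region VAFs
  vaf <- matrix(0, n_var, nr, dimnames = dimnames(presence))
  trunc_idx <- origin == "somatic_truncal"
  if (any(trunc_idx)) {
    # one clonal prevalence per truncal variant, shared by all regions;
    # regional scatter enters through sequencing noise
    base <- rnorm(sum(trunc_idx), config$vaf_truncal_mean, config$vaf_truncal_sd)
    vaf[trunc_idx, ] <- pmin(pmax(base, 0.02), 0.98)
  }
  sub_idx <- origin %in% c("somatic_shared", "somatic_private")
  if (any(sub_idx)) {
    m <- presence & sub_idx
    vaf[m] <- runif(sum(m), config$vaf_subclonal_range[1], config$vaf_subclonal_range[2])
  }
  vaf[origin == "germline_het", ] <- 0.5
  vaf[origin == "germline_hom", ] <- 1.0
  vaf[!presence] <- 0

  # annotation flags
  somatic <- grepl("^somatic", origin)
  germline <- !somatic
  variants$in_dbsnp <- germline
  variants$pop_af_gt_1pct <- germline & (runif(n_var) < 0.95)
  variants$in_cosmic_or_tcga <- (somatic & runif(n_var) < config$frac_cosmic) |
    (germline & runif(n_var) < 0.02)
  variants$in_panel337 <- somatic & (runif(n_var) < config$frac_panel)

  # expression model
  gene_means <- rlnorm(config$n_genes, meanlog = 5.5, sdlog = 1.2)
  names(gene_means) <- sprintf("gene%05d", seq_len(config$n_genes))
  region_effects <- matrix(1, config$n_genes, nr,
                           dimnames = list(names(gene_means), colnames(presence)))
  n_de <- round(config$frac_de_genes * config$n_genes)
  if (n_de > 0) {
    de_genes <- sample.int(config$n_genes, n_de)
    de_region <- sample.int(nr, n_de, replace = TRUE)
    lfold <- runif(n_de, log2(config$de_fold_range[1]), log2(config$de_fold_range[2]))
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    region_effects[cbind(de_genes, de_region)] <- 2^(sign * lfold)
  }

  structure(
    list(config = config, variants = variants, vaf = vaf,
         gene_means = gene_means, region_effects = region_effects),
    class = "truth_set"
  )
}

#' Region-presence matrix of a truth set
#'
#' @param truth A `truth_set` from [make_truth()].
#' @return Logical matrix (variants x regions): `TRUE` where the variant
#'   truly exists (equivalently, where its true VAF is > 0).
#' @export
truth_presence <- function(truth) {
  stopifnot(inherits(truth, "truth_set"))
  truth$vaf > 0
}

#' Tidy per-variant view of a truth set
#'
#' @param x A `truth_set`.
#' @param ... Unused.
#' @return A tibble, one row per (variant, region) with the true VAF and
#'   presence indicator.
#' @export
tidy.truth_set <- function(x, ...) {
  long <- as_tibble(x$vaf, rownames = "variant_id") %>%
    tidyr::pivot_longer(-"variant_id", names_to = "region", values_to = "true_vaf")
  left_join(long, x$variants, by = "variant_id") %>%
    mutate(present = .data$true_vaf > 0) %>%
    select("variant_id", "chrom", "pos", "ref", "alt", "origin",
           "region", "true_vaf", "present", dplyr::everything())
}

#' @export
print.truth_set <- function(x, ...) {
  tab <- table(x$variants$origin)
  cat("<truth_set>\n")
  cat(sprintf("  %d variants over %d regions: %s\n",
              nrow(x$variants), x$config$n_regions,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d genes (%d with a region-specific fold effect)\n",
              length(x$gene_means),
              sum(rowSums(x$region_effects != 1) > 0)))
  invisible(x)
}
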