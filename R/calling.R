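#' Detect variants from read counts with a binomial-tail stand-in caller
#'
#' Transparent, desk-scale replacement for a somatic variant caller: a locus
#' is called detected iff its alternate-read count reaches `min_alt` *and*
#' the one-sided binomial tail probability of observing at least that many
#' alternate reads from sequencing error alone (rate `error_rate` over
#' `depth` trials) is below `alpha`. Every locus receives a call record;
#' undetected loci carry `filter_status = "NOT_DETECTED"`.
#'
#' The defaults (`min_alt = 4`, `alpha = 1e-6`) give near-certain detection
#' of variants at VAF >= 5% at ~137x coverage while keeping error-driven
#' false calls rare.
#'
#' @param read_set A `read_set` (regional, pooled or mixed).
#' @param min_alt Minimum alternate-read count.
#' @param alpha Significance level for the binomial error tail.
#' @param error_rate Assumed per-base error rate of the null model.
#' @return A `call_set`: a tibble with one row per locus and columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `sample_id`, `depth`,
#'   `alt_count`, `vaf` (`alt_count / depth`, 0 at depth 0), `detected`,
#'   `filter_status`; caller parameters are kept in the `"params"` attribute.
#' @examples
#' truth <- make_truth(sim_config(seed = 7, n_genes = 50))
#' calls <- detect_variants(simulate_region_counts(truth, 1))
#' dplyr::count(calls, filter_status)
#' @export
detect_variants <- function(read_set, min_alt = 4L, alpha = 1e-6,
                            error_rate = 1e-3) {
  stopifnot(inherits(read_set, "read_set"))
  if (!(min_alt >= 1 && alpha > 0 && alpha < 1 && error_rate > 0 && error_rate < 1)) {
    abort("caller parameters out of range: need min_alt >= 1, alpha and error_rate in (0, 1)")
  }
  v <- read_set$variants
  if (nrow(v) == 0) {
    warn(sprintf("read set '%s' has no variant loci; empty call set", read_set$sample_id))
  }
  detected <- detect_decision(v$alt_count, v$depth, min_alt, alpha, error_rate)
  calls <- tibble(
    variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
    ref = v$ref, alt = v$alt,
    sample_id = read_set$sample_id,
    depth = as.integer(v$depth), alt_count = as.integer(v$alt_count),
    vaf = ifelse(v$depth > 0, v$alt_count / v$depth, 0),
    detected = detected,
    filter_status = ifelse(detected, "PASS", "NOT_DETECTED")
  )
  new_call_set(calls, params = list(min_alt = as.integer(min_alt),
                                    alpha = alpha, error_rate = error_rate))
}

# detection rule shared by detect_variants() and sweep_detection()
detect_decision <- function(alt, depth, min_alt, alpha, error_rate) {
  tail_p <- pbinom(alt - 1, depth, error_rate, lower.tail = FALSE)
  alt >= min_alt & tail_p < alpha
}

new_call_set <- function(calls, params = NULL) {
  out <- as_tibble(calls)
  class(out) <- c("call_set", setdiff(class(out), "call_set"))
  attr(out, "params") <- params
  out
}

# keep call_set class through dplyr verbs used internally
restore_call_set <- function(out, template) {
  new_call_set(out, params = attr(template, "params"))
}

#' Filter out homozygous germline calls by VAF
#'
#' Calls with observed VAF strictly above `max_vaf` (default 90%) are treated
#' as homozygous germline SNPs and excluded from somatic analysis
#' (`filter_status = "HOM_FILTER"`). Only currently passing calls are
#' touched, so filters can be applied in any order.
#'
#' @param calls A `call_set`.
#' @param max_vaf VAF threshold; the boundary itself passes (strict `>`).
#' @return The filtered `call_set`.
#' @export
filter_homozygous <- function(calls, max_vaf = 0.90) {
  stopifnot(inherits(calls, "call_set"))
  hit <- calls$filter_status == "PASS" & calls$vaf > max_vaf
  calls$filter_status[hit] <- "HOM_FILTER"
  restore_call_set(calls, calls)
}

#' Filter out germline variants by annotation criteria
#'
#' Removes calls satisfying all three germline criteria simultaneously:
#' reported in dbSNP, population allele frequency above 1%, and *not*
#' reported in COSMIC or TCGA (cancer-database membership rescues a call).
#' Removed calls get `filter_status = "GERMLINE_FILTER"`.
#'
#' @param calls A `call_set`.
#' @param flags A data frame with columns `variant_id`, `in_dbsnp`,
#'   `pop_af_gt_1pct`, `in_cosmic_or_tcga` (and optionally `in_panel337`),
#'   e.g. `truth$variants`.
#' @return The filtered `call_set`.
#' @export
filter_germline <- function(calls, flags) {
  stopifnot(inherits(calls, "call_set"))
  flags <- check_flags(calls, flags,
                       c("in_dbsnp", "pop_af_gt_1pct", "in_cosmic_or_tcga"))
  idx <- match(calls$variant_id, flags$variant_id)
  germ <- flags$in_dbsnp[idx] & flags$pop_af_gt_1pct[idx] &
    !flags$in_cosmic_or_tcga[idx]
  hit <- calls$filter_status == "PASS" & germ
  calls$filter_status[hit] <- "GERMLINE_FILTER"
  restore_call_set(calls, calls)
}

#' Restrict calls to a cancer gene panel
#'
#' When enabled, only calls at loci flagged as belonging to the 337-gene
#' cancer panel are retained; others get `filter_status = "PANEL_FILTER"`.
#' Disabled (the default in simulations) it returns the call set unchanged,
#' keeping class totals interpretable.
#'
#' @param calls A `call_set`.
#' @param flags Data frame with columns `variant_id` and `in_panel337`.
#' @param enabled Apply the filter? Default `TRUE`.
#' @return The (possibly) filtered `call_set`.
#' @export
filter_panel <- function(calls, flags, enabled = TRUE) {
  stopifnot(inherits(calls, "call_set"))
  if (!enabled) return(calls)
  flags <- check_flags(calls, flags, "in_panel337")
  idx <- match(calls$variant_id, flags$variant_id)
  hit <- calls$filter_status == "PASS" & !flags$in_panel337[idx]
  calls$filter_status[hit] <- "PANEL_FILTER"
  restore_call_set(calls, calls)
}

check_flags <- function(calls, flags, needed) {
  flags <- as_tibble(flags)
  miss_col <- setdiff(c("variant_id", needed), names(flags))
  if (length(miss_col)) {
    abort(sprintf("`flags` lacks column(s): %s", paste(miss_col, collapse = ", ")))
  }
  active <- calls$variant_id[calls$filter_status == "PASS"]
  missing_var <- setdiff(active, flags$variant_id)
  if (length(missing_var)) {
    abort(sprintf("no annotation flags for called variant '%s'", missing_var[1]))
  }
  flags
}

#' Apply the full post-call filter pipeline
#'
#' Homozygous-VAF filter, then the three-criteria germline filter, then
#' (optionally) the 337-gene panel filter. The filters are independent
#' predicates, so the resulting PASS set does not depend on their order.
#'
#' @param calls A `call_set` from [detect_variants()].
#' @param flags Annotation flags per variant (e.g. `truth$variants`).
#' @param panel Apply the gene-panel filter? Default `FALSE`.
#' @param max_vaf Homozygous-filter threshold, default 0.90.
#' @return The filtered `call_set`.
#' @export
apply_variant_filters <- function(calls, flags, panel = FALSE, max_vaf = 0.90) {
  calls %>%
    filter_homozygous(max_vaf = max_vaf) %>%
    filter_germline(flags) %>%
    filter_panel(flags, enabled = panel)
}

#' Passing somatic calls of a call set
#'
#' @param calls A `call_set`.
#' @return The subset of calls with `filter_status == "PASS"`.
#' @export
passing_calls <- function(calls) {
  stopifnot(inherits(calls, "call_set"))
  restore_call_set(calls[calls$filter_status == "PASS", ], calls)
}
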