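#' Write a truth set as a VCF file
#'
#' Serializes the simulated ground truth: one record per variant with INFO
#' fields `ORIGIN` (variant class), `PRESENCE` (comma-separated 1-based
#' region indices), `RVAF` (per-region true VAFs, one value per region) and
#' the annotation flags `DBSNP`, `POPAF1PCT`, `COSMIC`, `PANEL337` (0/1).
#' Records are sorted by chromosome and position; column order is stable.
#'
#' @param truth A `truth_set`.
#' @param path Output file path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  v <- truth$variants
  vaf <- truth$vaf
  nr <- ncol(vaf)
  ord <- order(chrom_rank(v$chrom), v$pos)

  info <- vapply(seq_len(nrow(v)), function(i) {
    pres <- which(vaf[i, ] > 0)
    sprintf("ORIGIN=%s;PRESENCE=%s;RVAF=%s;DBSNP=%d;POPAF1PCT=%d;COSMIC=%d;PANEL337=%d",
            v$origin[i], paste(pres, collapse = ","),
            paste(format_float(vaf[i, ]), collapse = ","),
            v$in_dbsnp[i], v$pop_af_gt_1pct[i],
            v$in_cosmic_or_tcga[i], v$in_panel337[i])
  }, character(1))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mrpool_truth",
    sprintf("##mrpool_n_regions=%d", nr),
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Variant origin class\">",
    "##INFO=<ID=PRESENCE,Number=.,Type=Integer,Description=\"1-based indices of regions carrying the variant\">",
    sprintf("##INFO=<ID=RVAF,Number=%d,Type=Float,Description=\"True VAF per region\">", nr),
    "##INFO=<ID=DBSNP,Number=1,Type=Integer,Description=\"Reported in dbSNP (0/1)\">",
    "##INFO=<ID=POPAF1PCT,Number=1,Type=Integer,Description=\"Population AF > 1% (0/1)\">",
    "##INFO=<ID=COSMIC,Number=1,Type=Integer,Description=\"Reported in COSMIC or TCGA (0/1)\">",
    "##INFO=<ID=PANEL337,Number=1,Type=Integer,Description=\"In 337-gene cancer panel (0/1)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  v$chrom, v$pos, v$variant_id, v$ref, v$alt, info)
  writeLines(c(header, body[ord]), path)
  invisible(path)
}

#' Read a truth VCF written by [write_truth_vcf()]
#'
#' @param path Path to the VCF.
#' @return List with `variants` (tibble: id, coordinates, alleles, origin,
#'   flags) and `vaf` (variants x regions matrix of true VAFs), in file
#'   order.
#' @export
read_truth_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  origin <- vcfR::extract.info(vcf, "ORIGIN")
  rvaf <- vcfR::extract.info(vcf, "RVAF")
  vaf <- do.call(rbind, lapply(strsplit(rvaf, ","), as.numeric))
  rownames(vaf) <- fix$ID
  colnames(vaf) <- paste0("region_", seq_len(ncol(vaf)))
  variants <- tibble(
    variant_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    origin = origin,
    in_dbsnp = vcfR::extract.info(vcf, "DBSNP") == "1",
    pop_af_gt_1pct = vcfR::extract.info(vcf, "POPAF1PCT") == "1",
    in_cosmic_or_tcga = vcfR::extract.info(vcf, "COSMIC") == "1",
    in_panel337 = vcfR::extract.info(vcf, "PANEL337") == "1"
  )
  list(variants = variants, vaf = vaf)
}

#' Write a call set as a VCF file
#'
#' One record per locus; the FILTER column carries the filter status
#' (`PASS`, `HOM_FILTER`, `GERMLINE_FILTER`, `PANEL_FILTER`,
#' `NOT_DETECTED`) and the single sample column carries FORMAT fields
#' `DP` (depth), `AD` (ref,alt read counts) and `VAF`. Reading the file back
#' with [read_call_vcf()] reproduces the call set exactly.
#'
#' @param calls A `call_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_call_vcf <- function(calls, path) {
  stopifnot(inherits(calls, "call_set"))
  ord <- order(chrom_rank(calls$chrom), calls$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mrpool_calls",
    "##FILTER=<ID=NOT_DETECTED,Description=\"Below detection threshold\">",
    "##FILTER=<ID=HOM_FILTER,Description=\"VAF > 90%, homozygous germline\">",
    "##FILTER=<ID=GERMLINE_FILTER,Description=\"dbSNP + population AF > 1%, not in COSMIC/TCGA\">",
    "##FILTER=<ID=PANEL_FILTER,Description=\"Outside the 337-gene cancer panel\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Reference and alternate read counts\">",
    "##FORMAT=<ID=VAF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
            calls$sample_id[1])
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t.\tDP:AD:VAF\t%d:%d,%d:%s",
                  calls$chrom, calls$pos, calls$variant_id, calls$ref,
                  calls$alt, calls$filter_status, calls$depth,
                  calls$depth - calls$alt_count, calls$alt_count,
                  format_float(calls$vaf))
  writeLines(c(header, body[ord]), path)
  invisible(path)
}

#' Read a call-set VCF written by [write_call_vcf()]
#'
#' @param path Path to the VCF.
#' @return A `call_set` tibble in file order; `vaf` is recomputed as
#'   `alt_count / depth` and `detected` as `FILTER != "NOT_DETECTED"`.
#' @export
read_call_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  sample_id <- colnames(vcf@gt)[2]
  dp <- as.integer(vcfR::extract.gt(vcf, "DP"))
  ad <- vcfR::extract.gt(vcf, "AD")
  alt_count <- as.integer(vapply(strsplit(as.character(ad), ","),
                                 `[`, character(1), 2))
  new_call_set(tibble(
    variant_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    sample_id = sample_id,
    depth = dp,
    alt_count = alt_count,
    vaf = ifelse(dp > 0, alt_count / dp, 0),
    detected = fix$FILTER != "NOT_DETECTED",
    filter_status = fix$FILTER
  ))
}

#' Write / read a genes x samples count matrix as TSV
#'
#' The first column (`gene`) carries gene identifiers; remaining columns are
#' samples in stable order.
#'
#' @param counts Genes x samples matrix.
#' @param path File path.
#' @return `write_counts_tsv()` returns `path` invisibly;
#'   `read_counts_tsv()` returns the matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  counts <- as_count_matrix(counts)
  df <- tibble::as_tibble(counts, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_count_matrix(as.data.frame(df))
}

#' Write / read a simulation configuration as JSON
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `write_config_json()` returns `path` invisibly;
#'   `read_config_json()` returns a validated `sim_config`.
#' @export
write_config_json <- function(config, path) {
  config <- validate_sim_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, cfg)
}

# natural chromosome ordering: chr1..chr22, chrX, chrY, others last
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  num[sub("^chr", "", chrom) == "X"] <- 23L
  num[sub("^chr", "", chrom) == "Y"] <- 24L
  ifelse(is.na(num), 99L, num)
}

# shortest decimal representation that round-trips exactly
format_float <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                               trim = TRUE, drop0trailing = TRUE),
         character(1))
}
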