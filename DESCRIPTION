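Package: mrpool
Title: Simulation and Analysis of Multi-Region Versus Pooled Tumor Biopsy Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-regional tumor clonal architectures (truncal,
    shared and private somatic variants plus germline polymorphisms), per-region
    exome read counts and gene-expression counts, and compares what a physically
    pooled biopsy or an in-silico read mixture detects relative to the regional
    samples. Implements a transparent binomial-tail stand-in variant caller,
    homozygous/germline/gene-panel post-call filters, common/shared/private
    concordance classification, pooled-versus-mean-regional variant allele
    frequency correlation, variant-profile principal components, and a
    transcriptome comparison based on TMM normalization, pairwise log2 Pearson
    correlations and fold-change fractions. Includes detection-power sweeps over
    allele frequency and sequencing depth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
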