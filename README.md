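# mrpool

Simulation and analysis of **multi-region versus pooled tumor biopsy
sequencing**.

A single biopsy under-represents intratumoral heterogeneity; sequencing four
regional biopsies separately captures it but costs four libraries. A popular
compromise is to pool tissue from several regions into one library — but a
variant private to one of four regions is then diluted fourfold: a private
variant at allele fraction *v* in its home region appears at roughly *v*/4
in the pool, and can fall below the caller's detection limit. `mrpool` is
for cancer-genomics methodologists and biobank designers who want to
quantify that trade-off: what an equal-weight pool detects, what it dilutes,
and what it misses, at both the variant and the gene-expression level.

## What it models

* **Clonal architecture.** Somatic variants are partitioned into *truncal*
  variants (present in all regions, clonal prevalence drawn around VAF
  0.40), *shared* variants (a strict subset of ≥ 2 regions) and *private*
  variants (one region), plus germline heterozygous/homozygous SNPs
  (VAF 0.5 / 1.0). Regional read counts at ~137x exome-like depth follow
  `alt ~ Binomial(depth, v(1−e) + (1−v)e/3)` with per-base error rate `e`,
  so absent alleles still produce rare error reads.
* **Two pooling routes.** `pool_physical()` re-sequences a weighted tissue
  mixture at a fixed pooled depth (expected pooled VAF = weighted mean of
  the regional VAFs — the dilution law); `mix_in_silico()` draws a fixed
  fraction (default 25%) of reads from each regional sample without
  replacement and combines them.
* **Calling and filtering.** A transparent stand-in caller declares a locus
  detected iff `alt ≥ min_alt` and the one-sided binomial error tail
  `P(X ≥ alt | depth, e) < alpha` (defaults 4 and 1e-6). Post-call filters:
  VAF > 90% (homozygous germline), the conjunctive three-criteria germline
  filter (dbSNP ∧ population AF > 1% ∧ not in COSMIC/TCGA), and an optional
  337-gene panel restriction.
* **Classification and statistics.** Variants detected in all *n* regions
  are *common*, in exactly one *private*, otherwise *shared*; the package
  computes per-class concordance fractions, pooled/mixed detection rates,
  the fraction of moderate-VAF (> 20%) variants missed by the pool, the
  Pearson correlation between pooled VAF and mean regional VAF, and
  variant-profile principal components.
* **Transcriptome comparison.** Genes with max count > 20 are retained, TMM
  normalization factors computed, pairwise Pearson correlations taken on
  log2(normalized + 1), and the fraction of genes beyond 2/3/4-fold
  reported for all six region pairs and four region-vs-pool pairs.

## Worked example

```r
library(mrpool)
exp <- run_experiment(sim_config(seed = 1))
exp
#> <mrpool_experiment>
#>   131 variants detected in >= 1 region: 69.5% common, 15.3% shared, 15.3% private
#>   pooled detection: common 100.0%, shared 90.0%, private 50.0%
#>   VAF correlation (pooled vs mean regional): r = 0.981
#>   expression: 17954 genes retained, mean regional r = 0.972
```

Of the 131 variants found in at least one regional sample, 69.5% are common
to all four regions; the pool recovers every common variant but only half
of the private ones, and its VAF tracks the mean regional VAF with
r = 0.981. Per-class VAF distributions show why:

```r
vaf_distribution_by_class(exp$classification)
#> # A tibble: 3 × 5
#>   class       n    q25 median   q75
#> 1 common    364 0.366   0.416 0.471
#> 2 shared     50 0.0877  0.144 0.216
#> 3 private    20 0.0870  0.139 0.242
```

Common variants sit at a median VAF of ~0.42 while shared/private variants
sit low — exactly the variants that dilution pushes under the detection
limit. The power sweep quantifies the dilution:

```r
sweep_detection(vaf_grid = c(0.02, 0.05, 0.1, 0.2, 0.4),
                depth_grid = 137, n_replicates = 5000, seed = 1)
#> # A tibble: 5 × 5
#>     vaf depth power_home power_single_biopsy power_pooled
#> 1  0.02   137      0.158               0.038       0.0052
#> 2  0.05   137      0.820               0.201       0.0524
#> 3  0.1    137      0.999               0.246       0.281
#> 4  0.2    137      1                   0.246       0.804
#> 5  0.4    137      1                   0.246       0.997
```

A private variant at VAF 0.10 is found essentially always in its home
region, about a quarter of the time by a random single biopsy (the 1-in-4
expectation), and 28% of the time in the pool — pooled power at VAF *v*
equals home-region power at *v*/4. Each result type has `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` figures; `run_experiment(config,
outdir = "...")` writes truth and per-sample call VCFs, classification and
expression TSVs, and a `summary.json`. A thin CLI wrapper lives at
`inst/cli/mrpool.R` (`run` and `sweep` subcommands).

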