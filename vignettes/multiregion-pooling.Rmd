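---
title: "Models and methods behind mrpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpool)
```

`mrpool` simulates a multi-region tumor sequencing experiment — four
regional biopsies plus a pooled library made from the mixed tissue — and
measures what pooling detects, dilutes, and misses relative to the regional
samples. This vignette documents the generative model, the choices behind
every default, and what the package's passing tests do and do not establish
about real data.

## The generative model

### Clonal architecture

A simulated tumor is a set of variant loci, each assigned an origin class:

* **truncal** somatic variants exist in every region. Each gets a single
  clonal prevalence drawn from a normal centered at `vaf_truncal_mean`
  (default 0.40, truncated to (0.02, 0.98)) and *shared by all regions*: a
  clonal variant has one cellular prevalence, and regional scatter in its
  observed VAF should come from sequencing noise, not from independent
  per-region redraws. This keeps the observed VAF distribution of common
  variants centered at 0.40, the regime reported for concordant variants in
  multi-region exome studies.
* **shared** somatic variants occupy a strict subset of at least two
  regions (subset size uniform on 2..n−1); **private** variants occupy
  exactly one region, uniformly chosen. Both draw their VAF independently
  per present region, uniform on `vaf_subclonal_range` (default
  (0.02, 0.30)): subclones are region-specific events with no reason to
  share a prevalence, and the low range reproduces the qualitative
  observation that non-concordant variants sit at low allele frequency.
* **germline** heterozygous/homozygous SNPs have exact VAF 0.5 / 1.0
  everywhere. They are flagged as dbSNP members, carry population allele
  frequency > 1% with probability 0.95, and are COSMIC/TCGA-listed with
  probability 0.02, so the germline filter removes most but not all of them
  — mirroring the small germline leakage any annotation-based filter has.

Default class counts (70 truncal, 20 shared, 20 private somatic; 150 het +
50 hom germline) are a deliberate choice, not a fit: published multi-region
exome comparisons report on the order of 100–150 detected somatic SNVs per
tumor with common-variant fractions between roughly 55% and 80%, and the
defaults land the simulated detected totals and fractions inside those
ranges. No per-class truth counts are reported for real tumors, so these
are calibrated to the qualitative pattern only.

### Read counts

Sequencing is replaced by a two-stage count model. Depth at each locus is
negative binomial with mean `depth_mean` (default 137, matching exome-like
target coverage) and dispersion `depth_dispersion` (default 0.009, giving a
standard deviation near 17x). The alternate-read count is binomial with
success probability

$$p = v\,(1 - e) + (1 - v)\,\frac{e}{3},$$

where $v$ is the region's true VAF and $e$ the per-base error rate (default
1e-3). The error term is substitution-symmetric (a read error lands on each
of the three wrong bases equally often), which is the simplest model that
makes false-positive behavior testable: a locus absent from a region still
produces alternate reads at rate $e/3$.

### Expression counts

Per-gene baseline means are log-normal (meanlog 5.5, sdlog 1.2 over a
default universe of 18,161 coding genes), giving a median of a few hundred
reads per gene and realistic library sizes of ~9M counted reads. Counts are
negative binomial with dispersion `expr_dispersion` (default 0.01, i.e. a
biological coefficient of variation of 10% — the low end of what bulk
RNA-seq shows for closely related samples, appropriate for regions of one
tumor). A fraction `frac_de_genes` (default 5%) of genes carries a fold
change (uniform on log2 scale between 2- and 6-fold, random direction) in
one random region. These values are chosen so the *null* configuration
(no regional effects) reproduces the high-correlation regime reported for
the most homogeneous tumors (pairwise $R^2 \approx 0.97$, under 1% of genes
beyond 2-fold), and the default reproduces visible but minority regional
effects. Real tumors with strong expression heterogeneity correspond to
larger `frac_de_genes` or `expr_dispersion`.

## Pooling routes

`pool_physical()` models one library prepared from physically mixed tissue:
the pooled signal fraction at a locus is the weighted mean of the regional
*observed* alternate fractions, and the pooled alternate count is a fresh
binomial draw at `pooled_depth`. The pooled depth is held constant (default
the mean regional depth): whether real pooled libraries are sequenced
deeper is unknown, so depth is a free parameter rather than a modeled
quantity, and a constant keeps the dilution arithmetic exact — the expected
pooled VAF equals the weighted mean regional VAF, so with equal weights a
private variant is diluted by the number of regions.

`mix_in_silico()` models the computational alternative of drawing 25% of
reads from each sample: per locus and region, `round(fraction × depth)`
reads are chosen hypergeometrically (without replacement, matching
"choosing reads") from the region's alternate/reference reads, and the
choices are summed. Expression counts are subsampled with per-gene
hypergeometric marginals of "choose `round(fraction × library)` reads from
the library"; the marginal of each gene is exact and the identity holds at
fraction 1, but the joint sum-to-total constraint across genes is not
enforced — a negligible approximation at library sizes in the millions.

Both routes estimate the same per-locus quantity; the package treats their
agreement as a testable invariant.

## The stand-in caller

Real pipelines (alignment, duplicate marking, MuTect/LoFreq) are out of
scope; detection is replaced by an explicit binomial-tail rule: a locus is
detected iff `alt ≥ min_alt` *and* `P(X ≥ alt | depth, error_rate) < alpha`.
Defaults `min_alt = 4`, `alpha = 1e-6` give near-certain detection of
VAF ≥ 5% variants at 137x (at that depth the binomial rule requires 5
alternate reads) while keeping error-driven calls rare; both are
configurable, and every detection decision is checkable against exhaustive
enumeration of the binomial tail — a property the test suite exercises for
all depths up to 200.

Post-call filters are independent predicates, applied only to
currently-passing calls, so their order cannot change the PASS set:

* VAF > 90% (strict) marks homozygous germline SNPs;
* the germline filter removes calls satisfying **all three** criteria —
  dbSNP membership, population AF > 1%, and absence from COSMIC/TCGA. The
  conjunctive reading follows the phrase "satisfying the following three
  criteria"; a disjunctive reading (dbSNP membership alone sufficing) would
  be defensible but is not implemented;
* the optional 337-gene panel filter is off by default in simulations so
  that class totals stay interpretable.

## Classification and pooled-detection statistics

With $n$ regions, a variant detected (passing) in all $n$ is *common*, in
exactly one *private*, in 2..n−1 *shared*, in none *absent*. The literal
reading "shared = detected in > 2 samples" conflicts at $n = 4$ with
"common = all four" (2-region variants would be unclassifiable), so the
partition reading is adopted.

* **Mean regional VAF** averages over all $n$ regions with zeros for
  regions where the variant is not a passing call — this is the quantity
  the dilution law predicts for the pool, and the default for the
  pooled-vs-regional Pearson correlation. Averaging over detected regions
  only is available via `zero_undetected = FALSE`.
* **Missed moderate-VAF fraction** is computed over *all* regionally
  detected variants with max regional VAF > 20% (a `shared_only` mode
  restricts it to shared variants; the unrestricted form is the default
  because a pool that misses a moderate-VAF variant is a failure regardless
  of the variant's class).
* **Per-class VAF distributions** summarise one observation per detected
  (variant, region) pair, matching what a per-sample VAF plot shows. A
  per-variant max-based summary exists (`statistic = "max"`) but its median
  is biased upward by roughly one standard error of the binomial noise
  (~0.04 at 137x) because it is a maximum over four noisy measurements.
* **Variant-profile PCA** column-centers the samples × variants VAF matrix
  and eigendecomposes its covariance; signs are fixed by making the
  largest-magnitude loading of each component positive, so coordinates are
  deterministic. Call sets over different loci (several tumors) are aligned
  on the union of loci with zeros.

The correlation is reported as `NA` with a warning when either VAF vector
is constant (zero variance), rather than erroring: degenerate simulations
are legitimate inputs.

## Expression comparison

Genes are retained iff their maximum count across samples is strictly
greater than 20. TMM normalization uses the standard published procedure
and defaults — reference sample with upper quartile closest to the mean
upper quartile, 30% trim on M-values, 5% on A-values, precision weighting,
factors rescaled to geometric mean 1 — via `edgeR::calcNormFactors()`,
which implements exactly that procedure; re-deriving it here would add
nothing but risk. Note that TMM factors are *residual to library size*:
uniformly doubling a sample's counts doubles its library size and leaves
its factor at 1, so "recovering" a constant scaling means the effective
size (library size × factor) recovers it, and normalized values are
invariant — the form in which the package's tests assert it.

Correlations and fold changes are computed on normalized values with a
pseudocount of 1 before log2 (zero handling is otherwise undefined);
fold-change fractions count genes with |log2 ratio| above log2 of each
threshold (2, 3, 4) for the six region pairs and four region-vs-pool pairs.

## Determinism and numerical choices

* One global seed; every sample's stream is derived by a fixed offset
  (truth 0, region `10000 + r`, pool 20000, mix 30000, sweep 40000), so
  adding samples never perturbs earlier ones, and identical configurations
  are bit-identical.
* `sweep_detection()` uses common random numbers: one set of uniforms
  drives every (VAF, depth) grid cell through inverse-CDF (`qbinom`)
  sampling. Detection power is then *exactly* monotone in VAF and depth,
  not merely monotone up to Monte-Carlo noise — the variance-reduction
  device that makes the monotonicity property assertable.
* VCF output writes VAFs with 17 significant digits so numeric round-trips
  are exact; call-set VAFs are in any case recomputed from DP/AD on read.
* Quartiles use R's default (type 7) interpolation; boundary conventions
  are strict where the source phrasing is strict (VAF > 90%, max count
  > 20, fold change > threshold).

## Problem sizes used by the tests

The test suite simulates at the scale the statistics need, not larger:
1000–1500 loci for unbiasedness and dilution checks (3-standard-error
assertions), 1000 truncal variants for the pooled-sensitivity check,
exhaustive enumeration to depth 200 for the caller oracle, 3000–5000
Monte-Carlo replicates for power curves, and gene universes of 200–18,161
for the expression pipeline. The full suite runs in well under a minute.

## What passing tests do not show

The generator emulates the *statistical structure* the analysis assumes —
class architecture, binomial read sampling, negative-binomial expression —
not real data. There is no alignment artifact, mappability bias, GC bias,
copy-number-driven VAF distortion, tumor-purity variation across regions,
or indel calling; pooled tissue is assumed perfectly mixed (equal weights
by default) with no DNA-yield bias between regions. Agreement with the
published per-tumor numbers from real specimens (concordance percentages,
correlation coefficients of specific cancers) is therefore out of reach by
design; the package reproduces the analytic relationships — the 25%
single-biopsy expectation, the dilution law, the >97% pooled recovery of
truncal variants, the qualitative VAF orderings, and the high-correlation
expression regime — and exposes every assumption as a configurable
parameter.
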