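---
title: "Screening deleterious variants and estimating mutation burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening deleterious variants and estimating mutation burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenscan)
```

## The problem

Long-running crop breeding programs select intensively inside narrow gene
pools. In predominantly selfing species such as oat and wheat, selfing
purges strongly deleterious alleles quickly, but weakly and mildly
deleterious variants can drift to fixation behind the favoured haplotypes.
The *mutation burden* of a cultivar — how many predicted-deleterious
alleles it carries per deleterious locus — is therefore a genetic-risk
summary that complements ordinary diversity statistics, and its trend over
registration years tells you whether a century of breeding has been
accumulating or purging such variants.

`burdenscan` implements that analysis for a genotyped cohort: it starts
from a called multi-sample SNP VCF, per-variant functional annotations and
a per-site conservation track, and produces a deleterious-SNP (dSNP)
catalog, per-cultivar burden estimates, cohort summaries, diversity and
PCA descriptions of the gene pool, and trend tests against registration
year and yield.

## The screening rule

A site enters the dSNP catalog when two independent lines of evidence
agree:

* **SIFT** predicts the amino-acid substitution damaging: score at or
  below 0.05, and the call is not flagged low-confidence;
* **GERP++ RS** shows the site is evolutionarily constrained: rejected
  substitution score strictly above 0.

Catalog sites are banded by constraint into weakly (0 < RS < 1), mildly
(1 ≤ RS ≤ 3) and highly (RS > 3) deleterious classes.

Numerical conventions worth stating, since they affect counts at the
margins:

* The SIFT comparison is **inclusive** (`sift <= 0.05`) by default,
  following the SIFT tool's own definition of "0.05 or smaller";
  `filter_config(sift_inclusive = FALSE)` switches to a strict
  comparison.
* The severity band edges at 1 and 3 are closed into the middle band, so
  the three labels partition (0, ∞) without gaps.
* A site absent from the RS track has *unknown* constraint, not RS = 0:
  it can never be called deleterious. `rs_lookup()` returns `NA` for
  such sites by design.
* Annotation tables with several transcript rows per site are collapsed
  to the minimum SIFT score (carrying that transcript's confidence
  label). Canonical-transcript identifiers are typically not available
  downstream of the annotator, and the minimum is the conservative
  stand-in; `read_annotations(collapse = "first")` is the alternative.

Quality filtering precedes screening and mirrors the standard vcftools
recipe for RNA-seq SNP matrices in selfing cereals: per-genotype read
depth below `min_dp = 10` masks the genotype missing, sites with QUAL
below `min_qual = 20` are dropped, and with `max_missing = 0` any site
left with a missing genotype is dropped (`--max-missing 1` semantics).
Masking happens before the missingness test, so a single low-depth
genotype removes the site under the zero-tolerance default. The filter is
idempotent.

## Burden definitions

With `L` catalog loci, `n_hom` the count of loci homozygous for the
deleterious allele, and `n_het` the count heterozygous:

$$\mathrm{hom} = \frac{n_{hom}}{2L},\qquad
  \mathrm{het} = \frac{n_{het}}{2L},\qquad
  \mathrm{total} = \frac{2\,n_{hom} + n_{het}}{2L}
                 = 2\,\mathrm{hom} + \mathrm{het}.$$

Two interpretation points are deliberate:

* The *deleterious allele* is the alternate allele relative to the
  reference genome. The cohorts this targets are not polarized against an
  outgroup, and SIFT scores the substitution induced by the alternate
  allele; this is an assumption, stated rather than hidden.
* The homozygous numerator counts *loci* in the homozygous state, not
  alleles. Only under that reading does the printed identity
  `total = 2 hom + het` hold; the alternative (counting both alleles,
  `2 n_hom`) double-counts once the factor 2 in the identity is applied.
  The code computes `total` as `2*hom + het` so the identity holds to
  machine precision.

The total burden is the per-locus deleterious-allele dosage: 0 for a
cultivar carrying no deleterious alleles, 1 for one homozygous-deleterious
at every catalog locus, and `hom` is bounded by 0.5.

A catalog site is **fixed** when its deleterious-allele frequency across
all assayed cultivars is exactly 1 — no tolerance, because the quantity is
a ratio of integer counts.

## Diversity, PCA, and trends

Per-site nucleotide diversity uses the unbiased pairwise estimator with
vcftools `--site-pi` semantics: for N called chromosomes and alternate
count c, π = 2c(N−c)/(N(N−1)). `diversity_by_period()` averages site-π
within each chromosome for a breeding period's members, then reports mean
± SD across chromosomes, plus an OLS trend of the period means on the
period index 1..K. Two grouping modes are provided because usage in the
field is ambiguous: `per_period` (default; each period's registrants
only) and `cumulative` (all cultivars registered up to and including the
period). Periods with fewer than two members have undefined diversity and
are excluded from the trend rather than imputed.

`genotype_pca()` uses the standard allele-frequency normalization:
dosages centered by 2p̂ and scaled by √(p̂(1−p̂)), monomorphic sites
dropped, eigendecomposition of the sample covariance scaled by the site
count. For reproducible orientation each eigenvector's largest-magnitude
entry is made positive — coordinates are otherwise sign-arbitrary.
Missing genotypes are mean-imputed with a message (the default filters
leave none).

Trend tests are ordinary least squares (`stats::lm`) of a per-sample
statistic on registration year (calendar integers, uncentred — slopes are
per year) or adjusted yield, with a two-sided t-test of zero slope.
`trend_suite()` runs the six {total, het, hom} × {year, yield}
regressions and reports nominal p-values without multiple-testing
correction, which is the reporting convention this mirrors; treat the six
p-values accordingly. A response with zero variance (e.g. het burden in a
fully selfing cohort) is returned as a flagged degenerate fit — slope 0,
R² 0, p 1 — rather than an error, because a flat response is a meaningful
"no trend" outcome.

### Yield harmonization

Yields come from heterogeneous report sources. A cultivar present only in
source B is rescaled onto source A through *bridge* cultivars present in
both: each bridge contributes the candidate
`(target_B / bridge_B) × bridge_A`. With several bridges the default
aggregates by the arithmetic mean of the candidates
(`mean_of_candidates`); the `ratio_of_means` alternative scales by the
ratio of bridge means. The two agree exactly when all bridge ratios are
equal, and the choice is exposed because the multi-bridge arithmetic is
under-determined by common usage. Unit conversion uses the standard
bushel weights of 32 lb (oats) and 60 lb (wheat).

## The synthetic cohort generator

Nothing downstream can be validated without inputs whose truth is known,
so `simulate_cohort()` is a first-class, tested module, not a throwaway
fixture. It emulates the statistical structure of a century-scale
selfing-crop cohort:

* **MAF spectrum.** Per-site minor allele frequencies are drawn from a
  Beta(`maf_shape`, 1) law folded to [0, 0.5]. For `maf_shape` < 1 the
  folded density is strictly decreasing on (0, 0.5), giving the L-shape
  expected of largely rare variation; the default 0.3 puts roughly half
  the sites below MAF 0.05. Near 0.5 the density is nearly flat, so
  empirical histograms obey monotonicity only up to sampling noise in the
  tail bins — the tests check it with binomial slack.
* **Homozygosity.** Genotypes are drawn under a single inbreeding-like
  parameter F: P(hom-alt) = Fq + (1−F)q², P(het) = (1−F)·2q(1−q). The
  default F = 0.98 makes heterozygotes rare, as in a selfing crop;
  F = 1 eliminates them.
* **Year coupling.** At deleterious sites, a cultivar's alternate-allele
  probability is q + s·(year − start_year), so the *expected* total
  burden rises linearly in registration year with slope exactly s,
  whatever F, because the expected dosage is 2p regardless of how it is
  apportioned between het and hom states. Base frequencies at deleterious
  sites are clamped so probabilities stay in [0, 1]; a slope whose drift
  alone exceeds 1 over the year range is rejected as infeasible. The
  default s = 3×10⁻⁴ per year accumulates ≈ 0.036 of expected burden over
  the default 1900–2019 range, comparable to the spread between low- and
  high-burden cultivars in cereal cohorts; at 140 samples the OLS slope
  standard error is ≈ 6×10⁻⁵, so the planted trend is comfortably
  detectable — this was verified by a 50-seed pilot before the defaults
  were frozen.
* **Annotations by construction.** Deleterious sites are emitted with
  SIFT < 0.05, high confidence, and RS > 0 drawn from a weak/mild/high
  mixture (default weights 0.41/0.40/0.19). Every non-deleterious site
  fails the screen in exactly one of four ways — tolerated SIFT score,
  non-positive RS, low-confidence SIFT call, or absence from the RS
  track — so the screen's truth set is known exactly and every rejection
  path is exercised.
* **Artifacts.** `invariant_het_fraction` makes a chosen fraction of
  sites all-heterozygous, reproducing the near-0.5-MAF invariant
  heterozygote artifact seen in hexaploid wheat RNA-seq SNP calls;
  `missing_rate` masks genotypes at random.
* **Metadata.** Registration years are uniform over `year_range`,
  breeding periods are ten equal-width year bins, and yields rise at
  0.35 bu/ac per year around a 60 bu/ac base with SD 8 — a deliberate
  positive year–yield coupling so that burden–yield regressions have
  realistic confounding, as they do in real cohorts.

What the generator does **not** emulate: linkage disequilibrium (sites
are independent), pedigree structure and shared descent within breeding
periods, allele-frequency change by drift or selection (the year coupling
is imposed directly), sequencing error, and reference bias. Tests passing
on these cohorts therefore validate the *arithmetic and inference
machinery*, not the biological claims one would make from a real cohort;
in particular the PCA on synthetic data has no population structure to
find, and its variance proportions are near-uniform.

## Validation strategy and problem sizes

Every operation is tested against an independent oracle rather than
against itself: site-π against exhaustive enumeration of chromosome pairs
for N ≤ 8; PCA coordinates (up to sign) and eigenvalues against a direct
SVD of the same normalized matrix; OLS output against the closed-form
covariance solution and a hand-built t-test; the burden identity
`total = 2 hom + het` bitwise on random cohorts; the screen against the
generator's exact truth list; round-trips through files against the
in-memory objects (the VCF written by the package is read back through
the independent vcfR parser). The slope test's type-I error is checked
empirically over 1000 null replicates against its 2-SD binomial band
around 0.05.

Cohort-level checks run at the package's reference scale of 140 samples ×
21 chromosomes × 500 sites each (10,500 sites, ≈ 200 deleterious), which
a laptop completes in seconds; unit tests use smaller cohorts (30 × 240).
Published per-class count tables for the 141-oat and 142-wheat Canadian
cohorts ship in `reported_class_counts()` / `reported_cohort_stats()` so
the aggregate arithmetic (loss-of-function totals, proportions,
per-chromosome means, severity and MAF percentages) can be recomputed and
checked exactly.

## Known limitations

* The artifact consumes annotations and conservation scores; it does not
  run VEP/SIFT or GERP++, and inherits whatever biases those upstream
  tools have.
* Deleteriousness here is *predicted* damage to gene function, not
  demonstrated fitness cost.
* Burdens are unweighted counts: a highly deleterious allele counts the
  same as a weakly deleterious one. Severity is reported alongside, not
  folded into the statistic.
* Yield harmonization assumes bridge cultivars perform proportionally
  across report environments; with few bridges the adjustment is fragile,
  which is why the aggregation rule is exposed and logged.
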