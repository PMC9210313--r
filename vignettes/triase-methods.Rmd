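---
title: "Models and methods: expression inheritance, regulatory divergence, dosage and heterosis in triploid hybrids"
author: "triase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triase)
```

# The biological setting

triase analyses bulk RNA-Seq from interspecific families produced by crossing
a diploid (2x) parent with a tetraploid (4x) parent. The progeny are triploid
(3x): each individual carries one haploid complement from the diploid parent
and a diploid complement from the tetraploid parent. Three questions drive
the analysis:

1. **Inheritance of expression.** For each gene, is the hybrid's expression
   additive (midparent), dominant (indistinguishable from one parent),
   transgressive (outside the parental range), or conserved?
2. **Mechanism of divergence.** Where parental expression diverges, is the
   cause *cis* (allele-intrinsic, persisting when both alleles share the
   hybrid's cellular environment) or *trans* (background-dependent,
   vanishing in the hybrid), or a combination?
3. **Dosage and phenotype.** Which chromosomes deviate from the expected
   1:2 parental-allele dosage (aneuploidy), which genes escape dosage
   expectations altogether (dysregulation), and how well does expression
   predict midparent heterosis of growth traits?

Because the corresponding field datasets are large and external, the package
ships a synthetic-data generator that emulates the count structures these
analyses consume, with known ground truth, so every stage is testable end to
end on a laptop.

# Differential expression: the NB exact test

All pairwise comparisons (P1 vs P2, and each parent vs each hybrid
individual) use a two-sample negative-binomial exact test on raw counts with
a single common dispersion per comparison, mirroring the classical
replicate-based exact-test workflow:

* **CPM filter.** Only genes with CPM >= 1 (configurable) in every replicate
  of at least one of the two groups enter the test. The all-replicates,
  either-group rule keeps genes expressed in only one genotype, which is
  essential for silencing/activation calls downstream.
* **Library equalization.** The exact test conditions on the sum of group
  totals, which requires equal library sizes; libraries are rescaled to
  their geometric mean and rounded. This is a mean-preserving approximation
  of quantile-based pseudo-data; at the library-size ratios of designed
  experiments (within ~2x) the rounding bias is negligible relative to
  counting noise.
* **Dispersion.** A common dispersion `phi` (variance `mu + phi mu^2`)
  maximizes the sum over genes of the likelihood conditional on each group
  total, which is free of the per-gene means. The search is a 1-D
  log-scale optimization on [1e-6, 4]; data with no overdispersion are
  reported at the lower bound. The estimator agrees with edgeR's
  common-dispersion estimate on simulated data (see the test suite).
* **Exact p-value.** Conditional on `s = A + B`, the group-A total follows a
  negative hypergeometric distribution free of the mean; the two-sided p is
  the total probability of all partitions of `s` no more probable than the
  observed one. At `phi = 0` this reduces exactly to the conditional
  binomial (Poisson-limit) test, which the test suite verifies against a
  brute-force enumeration oracle.
* **Calling.** Benjamini-Hochberg q-values; a gene is significant when
  `q < 0.005` and `|log2FC| > 1.2` (both configurable; the fold-change
  threshold is interpreted on the log2 scale). The log2FC uses a prior
  count of 0.5 per group so it is always finite.

# Inheritance classification

The three test outcomes per gene map onto six exhaustive classes:

| pattern (PP, P1-H, P2-H) | label |
|---|---|
| hybrid significantly above both parents | overdominant |
| hybrid significantly below both parents | underdominant |
| PP sig, hybrid ~ P1, hybrid != P2 | P1_dominant |
| PP sig, hybrid ~ P2, hybrid != P1 | P2_dominant |
| PP sig, hybrid significantly between, or indistinguishable from both | additive |
| everything else | conserved |

Partial patterns (for example a single parent-hybrid difference without
parental divergence) default to conserved: with no evidence of parental
divergence and no transgression there is no inheritance mode to assign, and
an explicit "ambiguous" bin would fragment the six-category summary. This
convention is ours; the classes themselves are the standard
expression-level-dominance vocabulary.

Presence/absence calls use all-replicates quantifiers: a gene is *silenced*
when CPM exceeds 1 in every replicate of at least one parent and is exactly
0 in every hybrid replicate, *activated* in the mirrored case. Requiring
every replicate makes the calls robust to single-library dropouts at the
cost of sensitivity for marginally expressed genes.

# Regulatory divergence from allele-specific counts

At parent-diagnostic biallelic sites with at least 20 reads summed between
the parents, three exact tests are computed on depth-normalized counts:

* **P** — binomial test of allelic balance between the parent libraries;
* **H** — binomial test of allelic balance within the hybrid;
* **F** — Fisher exact test of the 2x2 table parents-vs-hybrid.

The significance pattern (after per-test BH adjustment at FDR 0.005) maps to
`cis` (P, H), `trans` (P, F), `compensatory` (H, F), `cis_plus_trans` /
`cis_times_trans` (all three; same or opposite signs of the cis and trans
magnitudes, zero magnitudes breaking toward `cis_plus_trans`), `conserved`
(none) and `ambiguous` (exactly one).

Two triploid-specific choices matter and are both configurable:

* **The hybrid null is dosage-aware by default.** A triploid that inherited
  `k` tetraploid-parent copies of a chromosome has expected diploid-allele
  fraction `1/(1+k)`, not the genome-wide library proportion. Testing
  against a fixed genome-wide proportion mistakes chromosome dosage for
  regulatory divergence; the test suite demonstrates the inflation on a
  simulated replete chromosome and its elimination under the `1/(1+k)`
  null. A `null = "fixed"` mode reproduces the literal fixed-proportion
  test.
* **The Fisher table is dosage-adjusted by default** (`H4X` divided by `k`,
  rounded). Without the adjustment, every gene on a balanced triploid
  chromosome has a 1:1 parental table against a 1:2 hybrid table, and F
  would flag dosage rather than regulation genome-wide. The unadjusted
  table is available for comparison.

Normalization treats `P2X` and `P4X` as separate libraries but scales `H2X`
and `H4X` by a common factor, because they are counts from one hybrid
library: scaling them separately would erase the within-library allelic
ratio that the H and F tests measure. Using the allele-table column sums as
library-size proxies assumes approximate genome-wide allelic balance, which
holds when conserved genes dominate the table.

The cis magnitude is the dosage-corrected hybrid allelic log-ratio,
`cis = log2(H2X/H4X) - log2(1/k)`, and `trans` is the parental log-ratio
minus `cis`, so cis + trans equals the parental divergence by construction.

# Chromosome dosage and aneuploidy

For each chromosome x individual, with per-gene pseudo-count 0.5 and
zero-coverage genes excluded:

* `D` = median over genes of `log2(P2X/P4X) - log2(H2X/H4X)`;
* diploid % = median of `100 * H2X/(H2X + H4X)`.

Under copy numbers (`c4` in the tetraploid parent, `k` inherited), the
noise-free expectations are `D = log2(k) - log2(c4/4)` and
diploid % `= 100/(1+k)`; the balanced state (`c4 = 4`, `k = 2`) puts the
per-gene hybrid/parent ratio cloud at `(log2(1/3), log2(2/3)) =
(-1.585, -0.585)`. Inversion is two rounding steps — `k` from the diploid
percentage, then `c4` from `D` given `k` — clamped to the valid ranges; the
12 valid pairs are recovered exactly from simulations at 500 genes and
depth 200. One inherited diploid-parent copy is assumed throughout:
diploid-parent aneuploidy is not identifiable from these ratios alone.

Chromosome-scale shifts are screened by a per-chromosome two-sided Wilcoxon
rank-sum test of its per-gene log-ratios against all other chromosomes
(default call threshold 1e-16, p floored at 1e-300). Per-gene dosage
outliers operationalize the "expected dosage ellipse": location is the
coordinate-wise median; covariance is the classical covariance of points
inside the central 95% chi-square region of an initial fit, rescaled by the
truncation consistency factor `0.95 / F_chi2(4)(q_chi2(2)(0.95))` so the
estimator is unbiased under normality; points with squared Mahalanobis
distance beyond the chi-square(2) quantile at `1 - 1e-5` are flagged.
Cumulative dysregulation per individual is the count of flagged genes
(default) or the summed excess Mahalanobis distance (a severity-weighted
alternative); the exact definition in the literature is not standardized,
so both are reported with the mode recorded.

# Heterosis prediction

Midparent heterosis is `100 (F1 - MP)/MP`, `MP = (P1 + P2)/2`, per trait and
individual. Predictors are per-gene standardized `log2(CPM + 1)` values.
Four gene sets are compared: a seeded random sample, the most highly
expressed genes, genes DE in at least one parent pair, and genes DE in all
parent pairs (with one family the last two coincide). Prediction uses ridge
regression with objective

`(1/(2n)) ||y - b0 - X b||^2 + lambda ||b||^2`

(intercept unpenalized, closed-form solve, kernel dual when p > n), under
10 replications of nested cross-validation: outer 10-fold splits define
held-out individuals; inner 10-fold cross-validation on each training set
picks `lambda` by minimum MSE over 100 log-spaced values spanning 4 decades
down from `lambda_max = max|X'y|/n` (the glmnet-style convention, fixed
here explicitly so penalties are comparable across n). The whole path is
evaluated through one SVD per training set. Accuracy is the R-squared of
regressing observed on mean predicted values, the convention of the study
design this mirrors; the plain `1 - SSE/SST` is reported alongside because
the regression R-squared is blind to scale and offset miscalibration. Fold
assignments are fully seeded; random/top sets are drawn once, not per
replication.

# The synthetic-data generator

`simulate_family()` draws, per gene: a log-normal baseline (sdlog 1, mean
scaled to `mean_depth` reads); NB counts with dispersion 0.05 for 3
replicates per genotype (2 parents + progeny). Exactly
`round(frac_de * n_genes)` genes carry a parental log2 difference of
magnitude 3 (default), and inheritance labels allocate those genes by
largest remainder across the non-conserved classes; hybrid means follow the
class archetypes (midpoint, parent level, or 2 log2 units beyond the more
extreme parent). Regulatory labels decompose each divergent gene's
parental difference into cis and trans parts (divergence-free genes are
conserved or compensatory), the cis part shifting the hybrid diploid-allele
log-odds away from the `1/(1+k)` dosage baseline. Allele counts are
multinomial thinnings of the gene-level counts (30% allele-informative
reads), so gene- and allele-level tables are mutually consistent.
Aneuploidy events rescale the tetraploid parent by `c4/4` and the hybrid by
`(1+k)/3` on the affected chromosome for all progeny.

Two progeny-level effects make sibs differ biologically, not just by
measurement error:

* an **individual deviation** per gene (log-normal, sdlog 0.25), shared by
  an individual's replicates;
* a **parental-balance factor** `b_i ~ N(0, 0.3)` shifting every parent-DE
  gene by `b_i d_g / 2` log2 units toward one parent, modelling the shared
  segregation of divergent regulatory backgrounds. This factor is what
  makes parent-DE genes co-vary across sibs, and hence what gives the DE
  gene set its predictive advantage for heterosis — the qualitative
  finding the prediction module is designed to reproduce.

Phenotypes are `baseline + Z beta + noise`: a causal gene set (drawn from
the parent-DE genes by default, 50 genes, effects N(0, 1)) acts through
standardized expression, with Gaussian noise (sd 0.5) and baseline 100
trait units — a positive baseline keeps midparent-percent heterosis well
defined, as for real biomass and growth traits.

**What the generator does not emulate:** read-level artifacts (mapping
bias, reference bias at diagnostic sites), correlated co-expression modules
beyond the single balance factor, dosage compensation, partial aneuploidy,
and segregation of individual chromosomes (the balance factor is
genome-wide, and aneuploidy events are family-wide rather than private to
single sibs). Passing recovery tests therefore demonstrates correctness of
the statistical machinery under its own assumptions, not robustness to
alignment artifacts in real data.

# Numerical and testing choices

* Exact tests are validated against independent brute-force enumeration
  oracles (conditional binomial for the NB test at `phi = 0`, full binomial
  and hypergeometric enumeration, exhaustive rank-sum permutation); the NB
  test is additionally cross-checked against edgeR's exact test at matched
  dispersion.
* Type-I-error simulations for the allele-specific tests are run at NB
  dispersion 0: the binomial and Fisher tests assume multinomial read
  sampling, and that is the null they are calibrated for. With biological
  overdispersion between parent libraries these tests are anticonservative
  — a property of the binomial-ASE design itself, which users should keep
  in mind when interpreting P-test calls on real replicated data.
* Classifier-recovery simulations disable the individual deviation and
  balance factor: both genuinely move an individual's expression away from
  its gene's class archetype, so with them active the planted label is no
  longer that individual's truth.
* Recovery and calibration suites run at 500-2000 genes, depths 200-1000
  and up to 30 progeny; these sizes put simulation medians well inside the
  +-0.05-log2 bands used by the dosage checks while keeping the whole
  suite under a minute of compute for the deterministic parts and a few
  minutes overall.
* Degenerate inputs are defined, not special-cased downstream: all-zero
  tests return p = 1, zero-coverage genes drop out of medians, zero
  midparent values yield NA heterosis with a warning, rank-deficient
  ridge at `lambda = 0` is an error directing users to a positive penalty.

# Known limitations

* The common-dispersion model ignores gene-wise dispersion variation;
  genuinely tagwise-overdispersed genes will be slightly anticonservative.
* Binomial ASE tests do not model replicate-level biological variance (see
  above).
* The deficient/normal/replete call treats the diploid contribution as
  fixed; diploid-parent aneuploidy masquerades as a shifted `D`.
* With a single simulated family, the "DE in any pair" and "DE in all
  pairs" gene sets coincide; multi-family designs are supported by passing
  several DE tables to `build_gene_sets()`.
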