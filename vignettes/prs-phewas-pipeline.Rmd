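---
title: "From genotype QC to PRS-PheWAS: models, parameters and design choices"
author: "prsphewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genotype QC to PRS-PheWAS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsphewas)
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic cohort, the statistical
procedures of each pipeline stage, the parameters that matter and their
defaults, the numerical decisions taken where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate about
real data.

## The pipeline at a glance

The package implements a complete case-control genetic-association
workflow of the kind run on biobank genotype arrays:

1. **Cohort assembly** — age- and sex-matched control selection.
2. **Quality control** — a sample-level cascade (sex concordance, call
   rate, inbreeding outliers, relatedness) followed by a variant-level
   cascade (autosomes, call rate, monomorphics, differential
   missingness, exact Hardy–Weinberg in controls, strand flipping).
3. **GWAS** — per-variant covariate-adjusted logistic regression with
   principal-component covariates, genomic-control diagnostics, and
   greedy LD clumping.
4. **Rare-variant collapsing** — qualifying-variant selection
   (consequence, reference-population MAF, low-complexity regions) and a
   per-gene carrier-burden test.
5. **Polygenic risk scores** — harmonization of external summary
   statistics, clumping + thresholding (C+T) model selection over a grid
   of LD and p-value thresholds, optional SNP-set restriction, and the
   average-over-observed score formulas.
6. **Evaluation** — repeated stratified cross-validated AUC and quintile
   odds ratios.
7. **PheWAS** — phenome construction from EHR diagnosis codes (ICD-10 or
   phecode-aggregated), and logistic scans of a variant dosage or a PRS
   against every phenotype.

Every stage is exercised end-to-end on a synthetic cohort, so no
controlled-access data is needed anywhere in the tests.

## The synthetic cohort

### Genotypes: calibrated Gaussian-copula LD blocks

Genotypes are organized in LD blocks, each on its own synthetic
chromosome with variants 5 kb apart, so clumping and pruning windows
never span blocks. Within a block, a latent AR(1) Gaussian chain is
transformed variant-wise through the Binomial(2, p) quantile function.
The quantile transform attenuates correlation, so the latent adjacent
correlation is *calibrated*: the dosage correlation implied by a latent
correlation is computed by bivariate-normal quadrature and inverted by
root finding, per minor-allele frequency. With
`within_block_r = 0.8` the realized mean adjacent dosage r² is about
0.64, as an uncalibrated construction would not achieve. Frequencies
are drawn per block (variants in one block share a MAF) because a
target correlation between variants of very different frequencies can
be unattainable — the comonotone bound on the dosage correlation drops
below the target.

What the generator does **not** emulate: real haplotype reference
panels, recombination hotspots, allele-frequency spectra with rare
variants, ancestry admixture, or imputation uncertainty. Passing tests
therefore demonstrate the *statistical* correctness of each procedure
under a clean, known-truth generative model — not robustness to the
messiness of real array data.

### Phenotype: liability threshold

Disease liability is the sum of a genetic term (standardized dosages of
`n_causal` planted variants, spread across blocks round-robin, scaled
to variance `heritability_liability`), small age and sex terms
(`covar_frac`, default 0.02, split equally), and Gaussian noise filling
the rest, so total liability variance is 1. A sample is a case iff its
liability exceeds the standard-normal `1 - prevalence` quantile. Ages
are Normal(57, 8) truncated to [40, 70] — a typical adult-biobank age
structure — and sexes are Bernoulli(0.5).

Defaults encode the conditions the downstream analyses assume: 8000
samples, 80 blocks × 25 variants, heritability 0.5, prevalence 0.1.

### Training summary statistics, EHR phenome, QC defects

External training-GWAS summary statistics are emulated by adding
Gaussian noise with `se = 1/(sd(G) * sqrt(n_train))` to each variant's
true *marginal* effect (the regression of genetic liability on dosage,
so LD proxies of causal variants carry effects too). Fractions of
records can be emitted allele-swapped or strand-flipped to exercise
harmonization; the noise-free limit `n_train = Inf` is supported for
ranking tests.

The EHR generator plants: an index code carried by every case; one
comorbid code whose own liability reuses a
`comorbidity_shared_fraction` subset of the causal effects (this *is*
cross-trait genetic sharing, with known ground truth); null codes
assigned independently of genotype at prevalences 2–10%; and an anchor
code (`Z00.00`, the healthy-encounter code that defines control
eligibility) assigned at `anchor_code_rate` independently of case
status.

`sim_qc_defects()` corrupts a clean cohort with every failure class the
QC cascade filters — sex mismatches, low call rate, near-total
homozygosity (inbreeding), duplicate samples with extra missingness,
monomorphic variants, Wahlund-style mixture variants (a half/half blend
of subpopulation frequencies 0.02 and 0.6, a strong heterozygote
deficit), and case-only missingness — and returns a ledger naming
exactly what was corrupted, so tests can assert that *exactly* the
planted items are removed.

## Quality control: estimators and thresholds

| Parameter | Default | Meaning |
|---|---|---|
| sample call rate | ≥ 0.94 | fraction of non-missing genotypes per sample |
| inbreeding bound | mean ± 6 SD | method-of-moments F outliers |
| PI_HAT | ≤ 0.25 | excludes first/second-degree relatives and duplicates |
| variant call rate | ≥ 0.95 | per-variant |
| missing-rate difference | ≤ 0.05 | case vs control |
| HWE in controls | p ≥ 1e-6 | exact test |

Sample steps run first (in the order listed), then variant steps; the
inbreeding mean/SD are computed on the samples that survived the
call-rate step, so already-failed samples cannot distort the outlier
bounds. Filters only change membership — retained dosage values are
never altered — and re-running QC on QC'd output removes nothing.

**Exact HWE.** The test conditions on the sample size and allele count;
each attainable heterozygote count has an exactly computable
probability, and the p-value sums the probabilities of configurations
no more probable than the observed one. We use the standard cumulative
p rather than the mid-p — the conventional, slightly conservative
choice for QC filtering. The implementation is checked against full
enumeration for every genotype table with n ≤ 100.

**Relatedness.** PI_HAT = P(IBD=2) + P(IBD=1)/2 by the method of
moments on observed IBS sharing versus Hardy–Weinberg expectations,
computed on markers LD-pruned at r² = 0.2 (moment relatedness
estimators assume quasi-independent markers). Because the allele
frequencies are estimated from the analyzed cohort itself, the
small-sample corrections (falling-factorial ratios of allele counts)
are applied; without them the estimator is visibly inflated at a few
hundred samples. Two practical notes: the per-pair IBD-state estimates
are truncated at zero before normalization, which leaves a small
positive bias in the null PI_HAT, and the null noise scales as
1/√(markers). At 2400 pruned markers the largest null PI_HAT across
half a million pairs stays near 0.2 — below the 0.25 threshold — which
is why the QC tests use cohorts of at least that marker count.
Relatedness on a few hundred markers is not meaningful.

## GWAS

Per variant, `status ~ age + sex + 10 PCs + dosage` is fitted by IRLS
and the Wald statistics of the additive dosage term reported; variants
with cohort MAF < 0.01 are excluded, and samples missing a variant's
dosage are dropped for that variant only (complete-case; PCs are the
one place where mean-imputation is used instead). PCs are left
singular vectors of the standardized dosage matrix, sign-fixed by the
largest-magnitude loading, so scores are exactly orthonormal.

Separated or non-converged fits are *flagged* with `p = NA`, never
given a fabricated value. The separation bound is placed on the per-SD
scale of the predictor (`|beta|·sd(x) > 15` or `se·sd(x) > 15`):
a fixed raw-coefficient bound would misfire for predictors on very
small scales, such as a PRS normalized by 2·M, whose legitimate
log-odds coefficients run in the hundreds.

Clumping is the standard greedy procedure: the smallest-p unassigned
variant with p ≤ p1 (default 1e-5) indexes a clump and absorbs
unassigned same-chromosome variants within 150 kb with p ≤ p2 (default
1e-3) and r² ≥ 0.5 with the index. The r² threshold is exposed because
it is toolchain-convention rather than principle; p ties break by
(chromosome, position) for determinism, and undefined r² (monomorphic
overlap) counts as 0, i.e. the pair is never clumped together.

Genomic inflation is `lambda = median(chi2_obs)/0.4549`, where the
observed chi-squares are the inverse-chi-square transforms of the Wald
p-values.

## Rare-variant collapsing

A variant qualifies iff its most severe consequence term (multi-term
annotations are resolved by a configurable severity ranking) is in the
13-term high-impact vocabulary, its reference-population MAF is below
0.01, it is outside low-complexity regions, and it has a gene symbol.
The gene-level test is deliberately the transparent one: carrier status
(≥ 1 qualifying ALT allele anywhere in the gene) in a
covariate-adjusted logistic model, with a two-sided Fisher exact
fallback when the logistic fit separates — e.g. genes whose carriers
are all cases. Kernel-based variance-component tests (SKAT-family) are
published methodology with their own reference implementations; the
module defines the qualifying-variant logic and leaves a seam where
such a test can be plugged in, rather than re-deriving its internals.

## Polygenic scores

Harmonization matches summary-statistic records to cohort variants by
(chromosome, position) and reconciles alleles in four cases: direct,
swapped (beta negated), strand-flipped, and strand-flipped + swapped.
Palindromic A/T and C/G pairs are excluded by default — a strand flip
is undetectable from the alleles, and the training statistics carry no
allele frequency column to arbitrate — and every exclusion reason is
counted in a ledger.

C+T selection clumps with index and member thresholds of 1 (every
variant is index-eligible; a member threshold below 1 would silently
drop variants from consideration), window 250 kb, at the grid r²
threshold; index variants are then filtered at the p-value cutoff. The
grids mirror standard practice: r² ∈ {0.05, 0.1, 0.2, 0.4, 0.6, 0.8}
and p ∈ {5e-8 … 0.5, 1}.

Scores use the average-over-observed normalization:

$$PRS_j = \frac{\sum_i S_i G_{ij}}{P\,M_j},\qquad
  PRS_j^{unw} = \frac{\sum_i G_{ij}}{P\,M_j}$$

with ploidy P = 2 and M_j the number of non-missing model variants in
sample j; sums run over observed variants only, and a sample observing
none is flagged missing rather than scored 0. Model variants absent
from the genotype data are dropped (with a warning) and do not enter N
or M_j. These conventions give the identities the tests pin down to
1e-12: equal weights c reproduce c × the unweighted score; an
everywhere-missing variant changes nothing; allele-swapped inputs score
identically after harmonization.

## Evaluation

Cross-validation is stratified by status (the procedure should not
hinge on fold luck for imbalanced outcomes; for balanced cohorts it is
inconsequential) and reports the mean and SD over all folds × repeats
for both the covariates-only and the PRS + covariates model. Both
in-sample and cross-validated AUCs are available because published
model-comparison tables are often ambiguous about which is shown; the
CV mean is the primary number here. AUC itself is the Mann–Whitney
probability with half-credit ties, cross-checked in the tests against
exhaustive pair counting and against an established ROC implementation.

Quintiles are cut at the 20/40/60/80 rank percentiles with ties
assigned to the lower quintile (deterministic; group sizes stay within
1 of n/5 for continuous scores), and a covariate-adjusted logistic
model on quintile indicators yields the Q2–Q5 odds ratios against the
lowest quintile.

## PheWAS

For each code with ≥ 50 distinct case samples: cases are samples with
≥ 1 assignment; eligible controls *lack* the code and *carry* the
anchor code; the control set is a seeded uniform sample of five times
the case count (capped by eligibility) to avoid effect-size bias from
extreme imbalance. The anchor code itself is not scanned — its
control set is empty by construction. Phecode aggregation translates
each ICD-10 assignment through the map with a truncation fallback
(successively shortened prefixes) before dropping unmapped codes with a
logged count; phecode case sets are unions over mapped ICD-10 codes.
Phecode exclusion ranges are not applied by default — the scan
implements plain grouping — and the Bonferroni divisor is always
derived from the phenome actually scanned, with an override argument
for reproducing externally fixed divisors.

## Numerical choices and test problem sizes

* **Lambda on a 2000-variant null.** The median-based inflation factor
  estimated from 2000 variants has Monte-Carlo standard deviation of
  about 0.05 — as wide as the conventional ±0.05 comfort band. The
  calibration check therefore averages lambda over five independent
  null-phenotype replicates drawn on the same genotype matrix
  (sd ≈ 0.02). A single-draw check at this problem size would fail a
  third of the time under a perfectly calibrated test.
* **Type-I error checks** pool Wald p-values across the same replicates
  and compare the rejection rate at α = 0.05 against the 99% binomial
  band; the calibration cohort uses independent variants
  (`within_block_r = 0`), since LD between test statistics widens the
  band a binomial computation assumes away.
* **Problem sizes.** The test suite runs the calibration cohort at
  8000 × 2000, parameter recovery at 8000 samples × 1000 variants over
  5 seeds (heritability 0.5, prevalence 0.1, training n = 50,000), and
  the QC cascade at 1000 × 2400. Cross-validation in the recovery tests
  uses 2 repeats of 5 folds; the repeat count is a precision knob, not
  a model parameter.
* **Differential-missingness planting** uses a 25% case-only missing
  rate at 10% prevalence so the variant stays clear of the 95%
  call-rate filter (overall missingness 2.5%) while the case-control
  difference is far above the 5% threshold — the two filters' margins
  otherwise collide.
* **Degenerate inputs**: monomorphic HWE tables give p = 1 (a single
  attainable configuration); undefined inbreeding denominators and
  underpowered relatedness pairs are flagged, not filtered; empty C+T
  or restriction results are valid empty models, with a message.

## Known limitations

Single-ancestry cohorts only (no PCA-based ancestry assignment; the
covariate PCs handle within-cohort stratification). No X-chromosome
QC, no imputation, no kernel-based rare-variant tests, no shrinkage
(LDpred-style) scores, no phecode exclusion ranges by default, and no
longitudinal EHR logic. The simulator's LD is block-diagonal by
construction, which is exactly what makes clumping-window behavior
testable, and exactly what real chromosomes are not.
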