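---
title: "Methods: triangulating adjusted regression and two-sample MR for metabolomic outcomes"
author: "mrtriangulate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triangulating adjusted regression and two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriangulate)
```

## The problem

Sleep traits — insomnia symptoms, habitual sleep duration, chronotype —
are associated with cardiometabolic disease, and circulating metabolites
measured by NMR (lipoprotein subclasses, fatty acids, amino acids,
glycolysis metabolites, an inflammatory glycoprotein marker) are
candidate intermediates. Two study designs speak to whether those
associations are causal, and they fail in different ways:

* **Adjusted multivariable regression (AMV).** Cross-sectional OLS of a
  standardized log-metabolite on the sleep exposure, adjusted for age,
  sex, and BMI, fitted per cohort and pooled by inverse-variance
  meta-analysis. Vulnerable to residual confounding and reverse
  causation.
* **Two-sample Mendelian randomization (MR).** Genetic variants
  associated with the exposure serve as instruments; SNP–exposure
  associations come from one GWAS sample and SNP–metabolite associations
  from non-overlapping samples. Vulnerable to horizontal pleiotropy and
  weak instruments, but not to classical confounding of the
  exposure–outcome relation.

Triangulation asks both designs the same question and treats agreement —
same direction, adequate evidence in each — as stronger support for a
causal effect than either design alone.

## Genetic arm

**Instrument selection.** From the exposure GWAS we keep variants with
p < 5e−8 (strict inequality), drop palindromic (A/T, C/G) variants
outright, and greedily clump the remainder against a supplied LD matrix:
repeatedly keep the smallest-p remaining SNP and discard everything with
r² > 0.001 to a kept SNP. Ties in p break by the lexicographically
smaller SNP id so the output is deterministic. Clumping is all-pairs
(no physical-distance window): the threshold alone defines independence,
and the window option that physical clumpers add is unnecessary at the
scales the package targets. For chronotype-style exposures the records
can be re-expressed on the trait-increasing allele. Instrument strength
is reported as the per-SNP F statistic (β/σ)² and their sum; the sum is
the convention consistent with the magnitudes reported for biobank-scale
sleep instruments (total F in the hundreds to thousands across tens to
hundreds of variants).

**Harmonization.** Outcome records are aligned to each instrument's
effect allele: identical coding is kept, swapped coding negates the
outcome beta and complements its allele frequency, and strand-complement
codings reduce to those two cases — unambiguously, because palindromic
variants were already excluded, which is also why no frequency-based
strand inference is implemented. Anything else is dropped with an
explicit reason (`allele_mismatch`, `missing_in_outcome`). Harmonization
is exactly invariant to re-expressing the outcome file on opposite
alleles, and the test suite asserts this through to the estimates.

**Estimators.** With harmonized effects (β̂~Xj~, β̂~Yj~, σ~Yj~):

* *IVW, multiplicative random effects* (primary): slope of the weighted
  regression of β̂~Yj~ on β̂~Xj~ through the origin, weights 1/σ~Yj~²;
  Cochran's Q over per-SNP Wald ratios measures between-SNP
  heterogeneity, and the fixed-effect SE is multiplied by
  max(1, √(Q/(J−1))) — inflation only, never deflation. Normal
  inference.
* *MR-Egger*: free intercept, after orienting all β̂~Xj~ ≥ 0; the
  intercept estimates directional pleiotropy. SEs carry the analogous
  max(1, √(Q/(J−2))) factor; slope and intercept use t references with
  J−2 degrees of freedom. Where the convention is not pinned down in the
  literature the package documents its choice and the tests freeze it:
  normal reference for IVW and weighted median, t for Egger.
* *Weighted median*: per-SNP ratios sorted, standardized cumulative
  weight midpoints p~j~ = (S~j~ − w~j~/2)/S~J~ with first-order weights
  w~j~ = β̂~Xj~²/σ~Yj~², linear interpolation at p = 0.5. The SE is the
  standard deviation of the estimate over a seeded parametric bootstrap
  (default 1,000 draws of both betas from normal laws at their reported
  SEs); the bootstrap is the estimator's standard companion where no
  closed form is in general use.
* *Wald ratio* for the single-instrument case, with the first-order SE
  σ~Yj~/|β̂~Xj~|.

Method gating follows the minimum instrument counts (1 Wald, 2
IVW/weighted-median, 3 Egger). Egger and the weighted median are
sensitivity analyses: they are reported everywhere but never gate the
triangulation verdicts, which use IVW only.

**Pooling.** MR is run once per outcome GWAS dataset and pooled across
datasets by fixed-effect inverse-variance meta-analysis; per-dataset Q
statistics are reported rather than pooled, since heterogeneity is a
property of each dataset's instrument set. The observational arm pools
cohorts by fixed effects (headline) and DerSimonian–Laird random effects
(reported alongside; the moment estimator is the long-standing default
of the classic meta-analysis packages, so REML is deliberately not
implemented).

## Observational arm

Each cohort table holds one participant per row. Metabolites are assumed
log-transformed and standardized within cohort, so coefficients are in
SD units; the exposure is never standardized — binary exposures are
coded 0/1 (index category 1) and duration is in hours, so effects are
per category switch or per hour. The model is OLS with age, sex (0/1),
and BMI; listwise deletion handles missingness, no interactions or
survey weights are modelled, and an unadjusted variant (empty covariate
set) exists for comparison. Degenerate inputs fail loudly: a constant
exposure is a "no contrast" error, and n must exceed the parameter
count.

## Triangulation

The selection threshold divides 0.05 by the effective number of
independent tests. For this panel class 17 principal components explain
95% of the variance, giving 0.05/17 = 0.0029; the constant 17 is the
default (taken as an input of the design, not re-estimated from data),
while `effective_tests_from_panel()` recomputes it for synthetic panels
from the correlation-matrix eigenvalues. The same threshold is applied
separately to each arm. An association selected by either arm is
**consistent** if the other arm has the same sign and p < 0.05; if both
arms pass the threshold the rule is symmetric, and opposite signs — a
case the selection rule itself does not resolve — are classified
`not_consistent`. A zero point estimate never counts as sign agreement.
Concordance across the panel is the OLS of MR estimates (vertical axis)
on AMV estimates with intercept, reported as slope, intercept, and R²;
plots show per-point 95% CI bars, the identity line, and the fitted
line.

## The synthetic-data generator

The generator produces everything the pipeline consumes from one seed
and one truth record, so every estimator can be scored against known
parameters.

* **Genotypes.** Allele counts from two haplotypes via a Gaussian
  copula; LD is block-exchangeable (independent blocks of configurable
  size, one within-block r²), which is sufficient to exercise clumping
  without a coalescent model. The emitted LD matrix is the population
  block matrix.
* **Exposure.** A liability-threshold model: liability = genetic score +
  confounder U + age/sex/BMI paths + N(0,1); binary exposures cut the
  liability at the configured prevalence (default 0.3, the order of
  biobank insomnia-symptom prevalence), continuous duration rescales it
  to mean 7.2 h, SD 1.1 h. GWAS betas are computed on the observed 0/1
  scale by linear regression, mirroring biobank GWAS of binary sleep
  codings.
* **Metabolites.** 113 outcomes on the log scale, each loading on one of
  17 latent factors scaled so the systematic part carries 95% of
  baseline variance. The confounder and covariate paths are routed
  through the factor scores, keeping the systematic covariance at rank
  17 — so the effective-tests property of the observed panel matches the
  convention the threshold is built on. The causal path adds
  θ·exposure, pleiotropy adds direct SNP effects (balanced: mean zero;
  directional: positive mean) on a configurable fraction of SNPs, and
  columns are standardized within sample. Because standardization
  changes the outcome unit, the truth record reports θ rescaled to final
  SD units (computed from the model-implied variance), and that is the
  estimand every recovery test scores against. Gaussian noise on the log
  scale is assumed throughout.
* **Two samples, many datasets.** Exposure GWAS (sample A) and each
  outcome dataset (independent samples B1..Bk, default 4 pooled
  downstream) are drawn with no overlap. All randomness flows from one
  seed through named sub-streams per component, so adding cohorts never
  perturbs the GWAS draws — a property the tests assert.
* **Fast path.** `gwas_mode = "analytic"` draws β̂ from its asymptotic
  normal law around the model-implied marginal slope (including LD
  leakage and the liability-to-observed attenuation) instead of
  regressing individual-level data. Simulation-heavy properties (bias,
  coverage, type-I error, pleiotropy detection, at 200–500 replicates)
  use this path; individual-level regression mode backs the end-to-end
  runs so SEs, Q behaviour, and weak-instrument effects also emerge from
  data.

What the generator does *not* emulate: realistic human LD maps,
imputation uncertainty, sample overlap, non-Gaussian metabolite error,
non-European frequency spectra, or family structure. Passing tests
therefore demonstrate correctness of the statistical machinery under a
faithful structural model, not robustness to every artefact of real
cohort data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 200 replicates for
bias/coverage (50 instruments of total F ≈ 4,000, four pooled outcome
datasets, analytic mode at n = 50,000 per sample), 500 replicates for
type-I error, 200 for the pleiotropy diagnostics (20 instruments with
effects 0.06–0.2, 40% given directional pleiotropy of mean 0.04), a
5,000-participant panel for the effective-tests check, and a full
regression-mode run at 60 SNPs × 113 metabolites × 4 outcome datasets ×
10 cohorts of 2,000 — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping Monte-Carlo error well inside the
asserted bounds.

Numerical conventions: p-values are clamped into (0, 1] (a GWAS z of 40
underflows otherwise, violating the record contract); 95% CIs use
±1.959964·SE or the Egger t quantile; DL τ² truncates at zero; weighted
TSVs are written with `%.17g` so write→read round trips are bit-exact;
greedy-clumping and weighted-median ties resolve deterministically
(lexicographic SNP id; ordered interpolation). Validation errors always
carry the offending row, column, or SNP id.

## Known limitations

* Heritability-scale realism of instrument effects is approximate; the
  generator targets instrument-strength regimes (total F from hundreds
  to thousands) rather than polygenic architectures.
* The weighted-median SE is bootstrap-only; very small instrument sets
  give noisy SEs.
* MR-Egger requires spread in the instrument-effect magnitudes; the
  estimator refuses identical β̂~X~ rather than returning an unstable
  slope.
* The consistency rule treats the two arms symmetrically when both pass
  the threshold; conflicting signs in that cell are rare but are
  classified `not_consistent` by design.
* Resumable runs reuse completed stage outputs verbatim; they do not
  detect a changed configuration behind an existing output directory.
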