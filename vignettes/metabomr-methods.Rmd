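---
title: "Methods: two-stage metabolite GWAS and one-sample MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage metabolite GWAS and one-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomr)
```

`metabomr` implements the causal-inference workflow used to ask whether a
serum metabolite *causes* variation in cardio-metabolic risk factors:
a two-stage genome-wide association study (GWAS) of the metabolite, reduction
of its signals to independent, replicated variants, and one-sample Mendelian
randomization (MR) with a weighted genetic risk score (wGRS) instrument.
This vignette explains each model, its assumptions, the tunable parameters,
and the design choices that were genuinely open.

## Phenotype preparation

Metabolite intensities are skewed and unit-arbitrary, so before association
testing the metabolite is (i) residualized on age, sex, and the leading
genetic principal components and (ii) mapped through the rank-based inverse
normal transformation (INT)

$$y^*_i = \Phi^{-1}\!\left(\frac{r_i - 1/2}{n}\right),$$

with ties sharing the average rank. The resulting trait is standard-normal
by construction, making per-allele effects directly interpretable in SD
units and robust to outliers. The $(r-1/2)/n$ offset is the default because
it reproduces the GenABEL-style transformation common in metabolite GWAS;
the Blom offset $(r - 3/8)/(n + 1/4)$ is available via
`inverse_normal_transform(..., offset = "blom")` — the two differ only in
the extreme tails. INT is invariant to monotone rescaling of the input and
idempotent, both checked as properties in the test suite.

The pipeline order is fixed: residualize, then INT, then regress the
prepared trait on dosage *alone*. A joint-covariate regression is available
through the building blocks (`first_stage()` accepts covariates), but the
two-step flow is the default because it reproduces the standard
residualize-then-scan GWAS procedure; at these covariate strengths the two
differ negligibly. Derived traits follow their clinical definitions:
`compute_bmi()` (kg/m²) and `compute_homa_ir()` = insulin (µU/L) × glucose
(mmol/L) / 22.5. Glucose enters HOMA-IR in mmol/L — the standard formula —
and TG/UA/FPG/insulin/HOMA-IR can be log-transformed per trait via
`prepare_trait(transform = "ln" | "log")` when analyzed on measured scales.

## Association scan and its diagnostics

Each variant is tested by OLS of $y^*$ on the effect-allele dosage under the
additive model; with covariates already removed, $\hat\beta =
\mathrm{cov}(g, y^*)/\mathrm{var}(g)$, the SE comes from the residual
variance, and two-sided P values use the $t_{n-2}$ reference — at $n \approx
1000$ this matters in the far tail relative to a normal approximation.
Missing dosages are handled per variant by complete cases (minimum 10);
monomorphic variants are skipped and logged. P values are floored at
$10^{-300}$ to avoid underflow.

Variant QC retains variants with MAF ≥ 0.05, Hardy-Weinberg exact
P ≥ 10⁻⁴, and call rate ≥ 0.95. The HWE test is the exact conditional test:
given the allele counts, the probability of each feasible heterozygote count
is computed by a ratio recurrence held in log space (stable to thousands of
samples), and the P value sums the probabilities no larger than the observed
configuration's. The test suite verifies it against an independent
log-factorial enumeration oracle over every genotype table with up to 200
alleles.

Scan calibration is summarized by the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_1)/0.4549$; a homogeneous cohort should
give $\lambda \approx 1$, and `null_gwas_calibration()` reproduces that at
the study scale (1,000 subjects, 100,000 independent variants) together with
the empirical type-I error. QQ and Manhattan coordinates are emitted as
plain tables (`qq_data()`, `manhattan_data()`) so plotting is decoupled from
analysis.

## Clumping, replication, meta-analysis

Suggestive signals ($P < 5\times10^{-5}$) are reduced by PLINK-style greedy
clumping: the best unassigned P becomes an index and absorbs same-chromosome
variants within ±1 Mb whose in-sample $r^2$ with it is at least 0.5. Two
conventions needed fixing: "1 Mb" is read as ±1,000,000 bp around the index,
inclusive, and the $r^2$ boundary absorbs (a variant at exactly $r^2 = 0.5$
joins the clump). LD is computed in-sample from the analysis cohort itself,
matching a design where discovery and validation come from one genotyping
effort; external LD reference panels are out of scope.

An index replicates when its validation P is strictly below 0.05 *and* the
effect direction agrees after allele harmonization (label swap or strand
complement; unresolvable alleles are reported, not silently dropped).
Replicated variants are combined across stages by fixed-effect
inverse-variance meta-analysis with a normal (z) P value, the METAL
convention. No heterogeneity statistics are computed — with two stages of
one design, fixed effects is the appropriate and intended model.

## The instrument and the causal estimator

The instrument is the weighted allele count
$\mathrm{wGRS}_i = \sum_j \beta_j N_{ij}$ with weights taken from the
discovery-stage effects of the replicated variants, oriented so every
$\beta_j > 0$ on its metabolite-raising allele (which makes "number of
risk alleles" well defined). Missing dosages are mean-imputed per variant.
All downstream estimates are invariant to positive affine rescaling of the
score — a property the tests assert — so any global normalization of the
weights (e.g. dividing by $\sum_j \beta_j$) changes nothing causal;
`build_wgrs()` therefore implements the plain weighted sum.

Three age/sex-adjusted regressions follow: score on exposure
($\beta_{ZX}$, with instrument strength $F = t^2$), score on each outcome
($\beta_{ZY}$), and the observational exposure–outcome slope
($\beta_{XY}$). The causal estimate is the Wald ratio
$\hat\theta = \beta_{ZY}/\beta_{ZX}$ with the second-order delta SE

$$\mathrm{se}(\hat\theta) = \sqrt{\frac{se_{ZY}^2}{\beta_{ZX}^2} +
\frac{\beta_{ZY}^2\, se_{ZX}^2}{\beta_{ZX}^4}},$$

normal 95% CI and P. The first-order SE ($se_{ZY}/|\beta_{ZX}|$) is
available via `wald_estimator(method = "delta1")`. A caveat worth stating
plainly: both variants treat $\hat\beta_{ZX}$ and $\hat\beta_{ZY}$ as
independent, which is exact for two-sample MR but conservative in a
one-sample design, where the two share sampling noise
($\hat\beta_{ZY} \approx \theta\,\hat\beta_{ZX} + \text{noise}$). The
omitted covariance term inflates the variance by roughly
$1 + 2\theta^2\sigma_X^2/\sigma_\eta^2$, so when the exposure explains a
sizeable share of outcome variance the intervals over-cover (simulations in
the test suite at $\theta = 0.5$ show ≈ 99% coverage of nominal 95%
intervals). Estimates are unbiased regardless, and rejection rates under the
null are at or below nominal, i.e. the conservatism never manufactures
significance. The point estimate itself equals single-instrument two-stage
least squares exactly, which the suite checks against an explicit
Frisch-Waugh-Lovell oracle.

`pleiotropy_check()` regresses the score on each measured candidate
confounder (age, sex) singly; a valid instrument shows no association.
A weak-instrument warning fires when $|\beta_{ZX}/se_{ZX}| < 1$; the
conventional adequacy rule $F > 10$ is what the synthetic study-scale cohort
is checked against.

## The synthetic cohort generator

`sim_config()` defines the study conditions the package is verified under;
its defaults are fixed, not tuning knobs:

- **n**: 1,062 discovery / 227 validation subjects.
- **Instruments**: four unlinked variants on chromosomes 2, 3, 12, 13 with
  effect-allele frequencies 0.11, 0.22, 0.25, 0.75 and per-allele effects
  −0.38, 0.21, −0.21, −0.22 SD of the prepared metabolite. (One "MAF" of
  0.75 is really an effect-allele frequency; the field is named `eaf`
  accordingly and validated in (0, 1).)
- **Covariates**: age ~ N(57.4, 10²) years, sex ~ Bernoulli(0.5); their
  effects on the metabolite default to 0.1 SD each — the variance explained
  by covariates in the real metabolite is not identified, so these are
  documented free parameters.
- **Noise**: unit residual SD for the metabolite and each outcome; each of
  the 13 outcomes receives θ (default 0.3 SD/SD) times the metabolite.
- **Confounding**: an optional latent U ~ N(0, 1) loads equally on the
  metabolite and every outcome (`confounder_effect`), reproducing the
  omitted-variable bias that MR is designed to bypass; genotypes are
  independent of U by construction.

Genotypes are drawn from Hardy-Weinberg proportions. Null variants come in
LD blocks built from an exchangeable latent Gaussian thresholded at the HWE
quantile per haplotype; because thresholding attenuates correlation, the
latent correlation is *calibrated* (bivariate-normal orthant probability +
root finding) so the realized dosage correlation matches `ld_block_r`. This
gives clump tests a tunable, honest r². Outcomes are generated on
standardized scales by default; `outcome_scale = "mapped"` applies an affine
map to realistic measurement units (means anchored to typical mid-life
cohort values, field-plausible SDs) for cosmetic realism — MR estimates are
scale-equivariant, so all tests run on the standardized scale.

What the generator does *not* emulate: LC-MS acquisition artifacts,
imputation dosage uncertainty, population stratification (PC covariates are
pure noise), relatedness, and non-linear or interaction effects. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated linear structural model, not robustness to those real-data
complications.

## Numerical choices and degenerate inputs

- Exact HWE recurrence in log space; enumeration capped only by feasible
  heterozygote counts.
- P floors at 1e-300; perfect fits report the floor rather than 0.
- Rank ties: average rank, shared quantile — deterministic and
  permutation-invariant.
- Rank-deficient covariate designs raise an error naming the collinear
  column; constant traits, constant scores, and zero-variance variants are
  rejected or skipped with logs rather than propagating NaN.
- Coordinates are 1-based (VCF convention); the clump window is inclusive.
- One global seed fans out to sub-streams (validation cohort at
  seed + 1000, phenotypes at seed + 1), so stages are independently
  reproducible and same-seed pipeline reruns are byte-identical.

## Problem sizes used in verification

Calibration and recovery checks run at the sizes the science dictates:
null-scan calibration at 1,000 subjects × 100,000 variants; parameter
recovery and CI coverage at n = 5,000 over 500 replicates; confounded-null
robustness at n = 2,000 over 500 replicates; LD calibration at n = 10,000.
Unit tests use smaller fixtures chosen to keep each property sharp.

## Known limitations

- One-sample MR with a single score instrument only: no MR-Egger, weighted
  median/mode, Steiger filtering, or two-sample designs.
- Delta-method CIs are conservative in-sample (see above); a
  covariance-corrected one-sample variance is a natural extension.
- No mixed-model association or relatedness correction; autosomes only.
- In-sample LD only; no external reference panels.
- The pipeline's validation stage re-tests only the clumped indices, by
  design — genome-wide validation scans are not performed.
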