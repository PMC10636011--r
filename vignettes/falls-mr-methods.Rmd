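---
title: "Models and methods behind fallmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fallmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallmr)
```

`fallmr` packages the full analysis chain for an electronic-health-record
(EHR) study of balance-related falls: phenotype derivation from coded event
logs, variant-level association, heritability and genetic correlation, and
a multi-method Mendelian randomisation (MR) suite. This vignette explains
the models, the defaults and why they are set where they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer would want written down.

## The phenotyping model

Hospital (HES, ICD-10) and primary-care (GP, Read v2/v3) event rows are
classified against a user-supplied code list with three categories:
`balance_fall` (the include set), `other_fall` (fall codes judged
unrelated to balance, e.g. falls into water) and `non_fall`. The
assignment rule is:

* **case** — at least one `balance_fall` code in the selected sources;
* **control** — at least one record of any kind and *no* fall code of
  either category: any fall code disqualifies a control;
* **excluded** — no records in the selected sources, *or* fall codes only
  of the `other_fall` category.

The last clause is a deliberate design decision. Removing non-balance fall
codes from the case definition while also disqualifying controls on any
fall code leaves persons with only `other_fall` codes with no consistent
assignment except exclusion, so that is what the package does, with the
reason recorded per person.

Fall counts are deduplicated by calendar date: the count is the number of
distinct dates carrying at least one `balance_fall` code, so two different
codes recorded on the same day contribute one fall. Codes not present in
the code list still count as clinical records (they keep a person in the
control denominator) — a person's eligibility should not depend on how
exhaustive the non-fall side of the list is. Rows whose vocabulary
contradicts their source (ICD-10 in GP, Read in HES) are dropped with a
warning rather than silently coerced.

## Variant QC and the Firth scan

QC excludes a variant iff INFO < 0.3 or MAF < 0.1%, with MAF computed as
`min(eaf, 1 - eaf)`. Both comparisons are strict, so boundary variants are
retained; the exclusion log records which rule fired. The filter is
idempotent by construction.

With ~10% case prevalence, rare genotypes can separate the outcome and
ordinary logistic regression diverges. The scan therefore maximises the
Jeffreys-penalised log-likelihood
$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det I(\beta)$
by Newton iterations on Firth's modified score, tolerance $10^{-8}$ on the
free-coordinate score norm, at most 50 iterations, halving the step when
the penalised likelihood would decrease. P-values come from the penalised
likelihood ratio rather than the Wald statistic, which is better calibrated
in unbalanced designs — the reason Firth regression is used here at all.
One subtlety matters: the null model for the ratio is the *profile*
penalised fit, i.e. the variant coefficient constrained to zero while the
penalty keeps the full design's information matrix. Refitting a smaller
design instead changes the determinant's scale and ruins the test's null
distribution; the package's null-calibration test (150 null variants,
Kolmogorov–Smirnov against uniform) guards this.

## LD score regression

LD scores are computed from the genotypes themselves (no external
reference panel exists for synthetic data): for variant $j$,
$\ell_j = \sum_k \tilde r^2_{jk}$ over a symmetric window in variant
order, with the finite-sample adjustment
$\tilde r^2 = r^2 - (1 - r^2)/(n - 2)$. The heritability regression
$E[\chi^2_j] = 1 + N h^2 \ell_j / M$ is fitted by weighted least squares
with the standard heteroskedasticity weights $1/(1 + N h^2 \ell_j/M)^2$,
updated once from an unweighted first pass (two-step). Cross-trait
products $z_{A,j} z_{B,j}$ regressed on $\sqrt{N_A N_B}\,\ell_j/M$ give
the genetic covariance; the free intercept estimates the correlated
estimation error that shared participants induce, and
$r_g = \mathrm{gencov}/\sqrt{h^2_A h^2_B}$. All uncertainty is by
leave-one-block-out jackknife over 20 contiguous variant blocks
(configurable), with the three regressions recomputed jointly per deleted
block so the $r_g$ SE reflects their joint variability. When either fitted
heritability is non-positive the ratio is undefined and the result is
flagged rather than reported.

Heritability is reported on the observed scale; `h2_liability()` provides
the liability-scale transform for users who can supply a population
prevalence. The Bonferroni reporting rule is `alpha / n_tests` with strict
inequality; at the default 12 tests the threshold is 0.05/12, displayed
rounded as 0.0042 but applied exactly.

## The two-sample estimator suite

All estimators consume a harmonised instrument table. Harmonisation aligns
the outcome table to the exposure's effect allele, negating the outcome
beta for swapped alleles and complementing strands; palindromic variants
(A/T, C/G) with exposure EAF in 0.42–0.58 are dropped as ambiguous — the
window is conventional, and every action is logged per variant.

IVW is the closed-form weighted through-origin regression; the default SE
uses multiplicative random effects, inflating by
$\max(1, \sqrt{Q/(k-1)})$. The truncation at 1 makes the default
deliberately conservative under the null, which is why the package's
calibration tests check exact uniformity on the *fixed-effects* p-values
and only a type-I-rate band on the inflated ones. MR-Egger re-orients
instruments so all $\hat\beta_X \ge 0$ before fitting — the intercept is
orientation-dependent, and a fixed convention makes results reproducible.
Weighted-median estimates interpolate the cumulative inverse-variance
weight function at 50% (midpoint convention); the penalised variant
multiplies each weight by $\min(1, q_j/0.05)$ with $q_j$ the upper-tail
$\chi^2_1$ probability of the instrument's contribution to heterogeneity
about the unpenalised median. With no outliers every factor is 1 and PWM
equals WM exactly; as the penalisation constant goes to zero the penalty
disarms entirely. WM/PWM standard errors come from a seeded parametric
bootstrap (default 1,000 draws) perturbing both effect columns — simpler
to verify by simulation than the analytic approximation, at the cost of a
seed argument. Degenerate instrument counts degrade gracefully: $k = 1$
gives the Wald ratio with an explicit note, $k = 2$ IVW only.

Estimates for binary exposures whose summary statistics are log odds
ratios are rescaled by $\ln 2 = 0.693$ (`scale_per_doubling()`), giving
the effect per doubling of genetic liability odds; the function refuses to
run twice or on continuous-exposure estimates.

## One-sample MR

The default instrument is a weighted allele score (missing dosages
mean-imputed to $2 \cdot \mathrm{EAF}$, preserving the score's
expectation); a multi-variant first stage is available by passing any
numeric instrument column. The two-stage fit regresses the exposure on the
instrument plus covariates (age and sex by default), then the outcome on
the fitted values under a linear, logistic or Poisson family. Second-stage
SEs are HC0 sandwich estimates treating the first stage as fixed — the
common practice for two-stage fits with non-linear second stages — with
the caveat that generated-regressor uncertainty is not propagated; with
strong instruments (the F > 30 regime the package tests in) the omission
is negligible. Stratified analyses refit the first stage within each
stratum, because a stratum-specific instrument-exposure relation is
exactly the premise of the never/ever negative-control design; a z-test
contrasts the strata. Sex-specific instrument selection tests the gene-sex
interaction $z = (\beta_m - \beta_f)/\sqrt{se_m^2 + se_f^2}$ at
$\alpha = 10^{-5}$ (the interaction criterion is a package choice; only
the strength threshold is prescribed by convention) and keeps a variant
only if $(\beta/se)^2 > 15$ in its assigned sex, strictly.

## The overlap-corrected IVW

When instruments are selected in the exposure GWAS and the two GWAS share
participants, three biases act at once: winner's curse inflates the
selected $\hat\beta_X$, weak instruments attenuate the ratio, and
correlated errors pull the estimate toward the confounded observational
association. Conditional on the observed exposure estimates, with a
normal polygenic prior $\beta_X \sim N(0, \sigma^2_j)$,

$$E[\hat\beta_{IVW} \mid \hat\beta_X] = \lambda\,\alpha + B, \qquad
\lambda = \frac{\sum w_j s_j \hat\beta_{X_j}^2}{\sum w_j \hat\beta_{X_j}^2},\quad
B = c \cdot \frac{\sum w_j \frac{se_{Y_j}}{se_{X_j}}(1 - s_j)\hat\beta_{X_j}^2}{\sum w_j \hat\beta_{X_j}^2},$$

where $s_j = \sigma^2_j/(\sigma^2_j + se^2_{X_j})$ is the shrinkage factor
and $c$ the error correlation. The corrected estimate inverts this:
$\hat\alpha = (\hat\beta_{IVW} - B)/\lambda$. Because threshold selection
is a function of $\hat\beta_X$ alone, the conditional shrinkage mean is
unchanged by selection — which is what licenses the same formula for
winner's-curse-selected instruments. Two estimation choices matter:

* $c$ comes from the cross-trait LD score regression intercept on the
  *full* (pre-selection) tables, and its jackknife variance is propagated
  into the corrected and difference SEs by the delta method — the
  intercept is the dominant noise source, and ignoring it makes the
  difference test reject wildly in the no-bias regime;
* $\sigma^2_j = \hat\sigma^2 \ell_j$ with the base variance estimated by
  moments, $\hat\sigma^2 = (\overline{\hat\beta_X^2} - \overline{se_X^2})/\bar\ell$,
  on the full table. This targets the same quantity as the LDSC slope
  ($h^2/M$) but cannot land near zero by regression noise and explode the
  attenuation inverse; when even the moment estimate is non-positive there
  is no polygenic signal to shrink toward and the corrected result is
  withheld with a flag. The LDSC $h^2$ is still estimated and echoed in
  `correction_inputs`.

The observed-minus-corrected difference is tested with a
leave-one-instrument-out jackknife SE (the two estimates are strongly
dependent, so naive variance addition would be wrong) combined with the
intercept term above. When the difference is significant, the corrected
estimate is the one to report. Forcing the correction factors to identity
(`force_identity = TRUE`) reproduces plain IVW exactly, a tested
invariant. Numeric identity with external implementations of this kind of
correction is explicitly not a goal; the correctness contract is
simulation recovery, which the test suite enforces under confounded
full-overlap nulls and winner's-curse selection.

## The synthetic-data generator

The generator is the package's study design, not a test fixture; its
defaults are fixed and the test suite runs against them.

* **Genotypes.** Hard-call dosages from two latent thresholded haplotype
  draws per person, Hardy–Weinberg at a per-variant MAF drawn uniformly in
  `maf_range` (default 0.05–0.5). LD is block structured with a per-block
  latent correlation drawn uniformly in $[0, 2r]$ (default $r = 0.3$,
  capped at 0.95). The heterogeneity is deliberate: constant within-block
  correlation gives the panel nearly constant LD scores, under which the
  LD score regression slope is barely identified; real genomes have widely
  varying LD. INFO scores are drawn in `info_range` (default 0.9–1, so the
  default panel passes QC; lower the floor to exercise filtering).
* **Traits.** The infinitesimal polygenic model: per-variant effects
  $N(0, h^2/M)$ on standardised dosages (default $h^2 = 0.2$), a shared
  standard-normal confounder with configurable loadings on exposure and
  outcome, and a logistic fall model whose intercept is tuned by
  root-finding to hit the target case prevalence (default 10%, matching
  the EHR-derived phenotype the package is designed around; the tuner
  reports the achievable range when asked for an impossible target). The
  per-case fall count is $1 + \mathrm{Poisson}$ with the same linear
  predictor in the log rate — guaranteeing case $\Leftrightarrow$ count
  $\ge 1$ with simple moments — with the rate constant set so roughly a
  third of cases fall more than once, and a gamma-frailty over-dispersion
  knob (default variance 0.3) left configurable because the dispersion of
  real EHR fall counts is not well pinned down.
* **Event logs.** Each case's falls become distinct event dates carrying
  1–3 distinct fall codes across HES (1995–2021) and GP (1955–2017) date
  windows — so the same-date deduplication rule is genuinely exercised —
  controls get benign codes only, and a configurable fraction of persons
  emits no records at all. Dates are ordered but otherwise calendar-naive.
* **Summary-statistic pairs.** Marginal effects are the LD-smeared
  causal effects with standard errors $1/\sqrt{N}$; exposure and outcome
  errors are correlated as `overlap_fraction * pheno_correlation`
  (default phenotypic correlation 0.2), the summary-level signature of
  shared participants — overlap is modelled at the error level rather
  than by resampling individuals because that is the abstraction the
  correction itself operates in. Optional threshold selection implements
  winner's curse and records the retained truth.

What the generator does **not** emulate: realistic human LD maps,
imputation error structure, ancestry stratification and relatedness,
age-dependent event rates, and phenome-scale code usage. Passing tests
therefore demonstrate the estimators' internal correctness and their
behaviour under the biases the generator *does* encode (confounding,
pleiotropy, overlap, winner's curse, sex-specific effects) — not
robustness to population structure, which the whole-genome machinery of
large-scale GWAS tools exists to absorb and which this package
deliberately replaces with plain covariate adjustment at desk scale.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes chosen to
make Monte-Carlo checks sharp while keeping runs comfortable on one CPU:
cohorts of 20,000 for estimator recovery, an LD panel of 12,000 × 2,000
for heritability/correlation recovery, 200 replicates for the
overlap-correction null and 1,000 for calibration rates. Convergence
tolerances: $10^{-8}$ score norm (Firth), `uniroot` at $10^{-10}$
(prevalence intercept), $10^{-10}$–$10^{-12}$ equality tolerances against
closed-form oracles. Ties in the weighted median resolve by ordered
interpolation; monomorphic variants are flagged and excluded from
estimation rather than guessed at; empty strata and empty per-sex
instrument sets warn and degrade instead of erroring.

## Known limitations

* The Firth scan refits the penalised model per variant; it is a
  desk-scale scan, not a GWAS engine.
* Two-stage SEs ignore first-stage uncertainty (documented above);
  bootstrap SEs are the recourse when instruments are weak.
* The overlap correction assumes the polygenic normal prior of its
  derivation; under sparse genetic architectures the moment-based prior
  variance is misspecified, though the direction of the correction is
  preserved.
* rg estimates are not constrained to $[-1, 1]$; wild ratios under weak
  heritability are flagged rather than clamped.
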