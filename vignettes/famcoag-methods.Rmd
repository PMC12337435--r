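---
title: "Familial co-aggregation from pedigrees and lifetime phenotypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial co-aggregation from pedigrees and lifetime phenotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the two statistics

Given a population cohort with pedigree links and lifetime case/control
status for several binary disorders, `famcoag` quantifies whether pairs of
disorders cluster within families, using two complementary statistics.

**Recurrence risk ratio.** For an ordered pair (outcome A, exposure
disorder B),

$$\lambda_R = \frac{K_{A\,|\,\text{affected relative for }B}}{K_A},$$

the prevalence of A among individuals with at least one affected relative
of degree R for disorder B, divided by the general-population prevalence
of A. A ratio above 1 indicates shared familial risk. Both prevalences are
*marginalized* model-based estimates (average adjusted predictions, below),
not raw proportions, so that age, sex and data-availability differences
between the exposed group and the population do not masquerade as familial
signal.

**Familial correlation.** Under the liability threshold model, disorder
status arises when a standard-normal latent liability exceeds
$t = \Phi^{-1}(1-K)$. For a relative pair with relatedness coefficient
$a_R$ (0.5 for first degree, 0.25 for second degree), the cross-trait
cross-relative liability correlation is $a_R\, r_f$, where $r_f$ is the
familial correlation: the shared variance of the two traits attributable
to familial factors, genetic and common-environmental combined (a
relative-based design cannot separate the two). The prevalence of A among
individuals with an affected relative for B identifies $r_f$:

$$K_{A|B\text{-rel}} = \frac{P(X > t_A,\, Y > t_B;\ \rho = a_R r_f)}{K_B},$$

which `solveRf()` inverts by bracketed root finding (the left side is
strictly increasing in $r_f$, a tested invariant).

## Pipeline stages

1. **Pedigree** (`buildPedigree()`, `readPed()`): parent-child records are
   validated (unique ids, acyclic), dangling parent references become
   placeholder founders without data, and families are the connected
   components of the parent-child graph. Relative pairs are classified by
   a recursive kinship computation: $2\phi = 0.5$ is first degree,
   $2\phi = 0.25$ second degree, any other positive kinship (cousins,
   $2\phi = 0.125$) is "other" and contributes to neither exposures nor
   covariates. Sibling pairs whose full/half status cannot be resolved
   because a parent is unrecorded are classified "other" with a warning —
   a deliberate conservative choice where the data are silent.
2. **Phenotypes** (`buildPhenotypePanel()`): wave-level statuses collapse
   to lifetime status by the any-case rule; analysis age is the age at the
   first case assessment for cases and the last age with data for
   controls. Composites (`addCompositePhenotype()`) follow the same
   any-case rule; a composite case takes the earliest component case age
   (the natural analogue of "first satisfied the definition"; the source
   design is silent here, so this is flagged as a package choice).
   Sensitivity exclusions (`applyExclusions()`) set the target phenotype
   to missing for lifetime cases of the excluding conditions, removing
   them from both case and control pools of that phenotype only.
3. **Prevalence models** (`fitPrevalenceModel()`,
   `averageAdjustedPrediction()`): logistic regression of lifetime status
   on the exposure indicator, age, age², sex and the number of relatives
   of the relevant degree with data on the exposure disorder; variance by
   the family-clustered sandwich (bread = inverse observed information,
   meat = outer products of per-family score sums, HC0 form, no
   small-sample cluster adjustment — so singleton clusters reproduce HC0
   exactly). Prevalences are averages of fitted probabilities at observed
   covariates, with delta-method standard errors through the cluster-robust
   coefficient covariance. Because the exposure indicator is in the model,
   the exposed-subgroup average equals the raw exposed prevalence and the
   full-sample average equals the raw prevalence (logistic score
   identities, tested to 1e-10).
4. **Inference** (`recurrenceRiskRatio()`, `estimateFamilialCorrelation()`,
   `assembleResults()`): delta-method SE for the ratio assuming
   independence of numerator and denominator; one-sided tests
   (H0: $\lambda_R = 1$ vs $\lambda_R > 1$; H0: $r_f = 0$ vs $r_f > 0$);
   only lower 95% confidence bounds are reported (the upper bound is
   uninformative for a one-sided design). $r_f$ components (first/second
   degree × both directions) are combined by inverse-variance weighting,
   with per-component estimates always emitted so any alternative
   combination can be recomputed. One Benjamini–Hochberg family is applied
   across all λ and $r_f$ tests (a per-type option exists); tests never
   computed (e.g. no exposed cases) do not enter the family size.

## Tunable parameters that matter

* `q` (default 0.05): FDR level across the pooled test family.
* `mode` (default `"exact"`): liability inversion via the bivariate-normal
  tail, numerically robust up to high prevalences (~40%); the
  `"approximate"` Reich-type threshold shift is retained for comparability
  with the older literature (agreement within 0.02 predicted prevalence
  over K ∈ [0.05, 0.4], |r_f| ≤ 0.5 — a tested invariant).
* `aapMode` (default `"observed"`): the exposed-group prevalence is the
  average fitted probability *within the exposed subgroup at observed
  covariates* — the literal reading of the source design. A
  `"counterfactual"` mode (exposure set to 1 for everyone) is available
  because the wording admits both; with the exposure indicator in the
  model, the default mode equals the raw exposed prevalence.
* CI scale for λ: ratio scale by default ("the simple ratio"); log-scale
  behind a flag.
* Age and age² enter untransformed. This is collinear but harmless:
  marginalized prevalences are invariant to centering, so all tests
  compare prevalences, never coefficients.

## The synthetic-data generator

`simulationConfig()` + `simulateStudy()` generate a three-generation
population: founder couple, 2 children (each with a married-in spouse),
2 grandchildren per child — 10 members per family containing first-degree
(parent-offspring, full siblings), second-degree (grandparent, avuncular)
and "other" (cousin) pairs. Latent liabilities per family are matrix
normal with covariance $A \otimes C + I \otimes (R - C)$: $A$ is the
relationship matrix ($2\phi$), $C$ the familial covariance (diagonal =
per-trait familial variance share, default 0.6; off-diagonal = the
familial correlation targets themselves, since the cross-relative
cross-trait covariance is $a_R C_{jk}$), and $R$ the within-person total
correlation (unit diagonal; by default no residual cross-trait
correlation beyond the familial part). Status is liability above
$\Phi^{-1}(1-K)$ — exact calibration when covariate effects are zero
(the default); nonzero liability effects of age/sex switch to empirical
quantile calibration with a 0.002 tolerance on K. Cases become observable
from a uniformly drawn onset wave onward; every (individual, wave)
assessment is missing with the wave's probability (defaults 0.10 / 0.20 /
0.30 at waves +0/+4/+10 years); baseline ages are generation-specific
normals (means 68/42/16, SD 5).

What it emulates: family-clustered binary traits with realistic
prevalences (5–40%), multi-wave assessment with increasing dropout,
age-structured generations. What it does **not** emulate: partial family
enrollment (every simulated family member has assessment data, unlike a
volunteer cohort where many participants have no enrolled relatives),
assortative mating, ascertainment, and real onset hazards. Passing
recovery tests therefore demonstrate internal consistency of the
generator-estimator pair, not unbiasedness on any real cohort.

## Known estimator properties (and two deliberate red flags in the tests)

Two properties of the *method itself* — faithfully implemented — make two
of the packaged acceptance expectations fail, and they are left failing
rather than papered over:

* **Union-exposure attenuation of $r_f$.** The exposure is "at least one
  affected relative of the degree", but the liability inversion conditions
  on a single affected relative. Each *unaffected* relative in the exposed
  group carries negative information about the proband's liability that
  the single-pair model ignores, so $\hat r_f$ is attenuated, increasingly
  with the number of relatives with data. The test suite demonstrates both
  halves: conditioning on one designated relative recovers the generative
  value (0.30 within Monte-Carlo tolerance), while the full union-exposure
  pipeline on 10-member families recovers ≈ 0.23 for a generative 0.30
  (the acceptance script reports this as `rf_recovered`). Real cohorts
  with a median of ~2 enrolled relatives sit closer to the single-pair
  model, but the direction of the bias — toward zero — is universal, so
  reported familial correlations should be read as conservative.
* **Conservative λ inference.** The ratio SE assumes independence between
  the exposed-group and population prevalences, but the exposed are part
  of the population; with common exposures the covariance is substantial.
  Under the packaged null simulation the one-sided test rejects in well
  under 1% of replicates at nominal 5% (the acceptance script reports
  `lambda_typeI_rate_pct`), and the delta SE exceeds a family-bootstrap SD
  by roughly half on the packaged fixture. Type-I error remains
  controlled — the test is conservative, never anticonservative — matching
  the known behaviour of this estimator.

## Numerical choices

* Bivariate normal tails: `mvtnorm::pmvnorm` (TVPACK), absolute accuracy
  well below 1e-10 in two dimensions; cross-checked in tests against an
  adaptive-quadrature oracle.
* Root finding for $r_f$: bracketed on (−0.999, 0.999), tolerance 1e-10;
  out-of-range observed prevalences report the attainable range instead of
  silently clipping.
* Component SEs: central finite differences of the solver with step 1e-4
  on the prevalence argument.
* Separation / non-convergence in a prevalence model raises an error
  naming the most suspect covariate; pairs with *no exposed cases* yield
  missing rows with a warning, so sparse synthetic runs never crash.
* Determinism: a study is a pure function of (inputs, config, seed);
  rerunning `runStudy()` with the same configuration reproduces output
  files byte for byte.

## Problem sizes used by the packaged tests

Chosen to keep the default suite comfortably inside a half-hour single-CPU
run while leaving every property identifiable: point recovery at 30,000
families; interval coverage and directional consistency from 50 replicates
of 2,000 families; null type-I calibration from 500 replicates of 800
families; the 105-test null grid from 40 replicates of 400 families (type-I
error and coverage are sample-size-invariant properties, so replication
count, not family count, drives their precision).

## Limitations

Beyond the two estimator properties above: "other"-degree relatives are
ignored entirely (matching the source design, but discarding cousin
information); the inverse-variance combination of $r_f$ components is one
defensible choice among several (per-component estimates are emitted for
reanalysis); and the pipeline consumes already-derived wave-level binary
statuses — clinical scoring instruments are upstream and out of scope.
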