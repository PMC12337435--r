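# famcoag — familial co-aggregation of binary disorders

`famcoag` asks whether two disorders cluster within families, for
epidemiologists working with population cohorts that carry pedigree links
(registry-derived parent/child records) and multi-wave questionnaire or
measurement data — the setting of large three-generation cohorts where
functional disorders, internalizing disorders, cardiometabolic and
immune-related diseases are assessed repeatedly over years.

It implements the full analysis path from raw inputs to FDR-controlled
results:

* **Pedigree**: validation, placeholder founders, family components, and
  relative-pair classification by recursive kinship (first degree:
  2φ = 0.5; second degree: 2φ = 0.25; everything else ignored).
* **Lifetime phenotypes**: wave-level case/control/missing records
  collapse by the any-case rule; analysis age is the first case age for
  cases, the last age with data for controls; composite phenotypes and
  sensitivity-analysis exclusion lists.
* **Marginalized prevalences**: logistic models with exposure
  ("≥ 1 affected relative"), age, age², sex and number-of-relatives
  covariates; family-clustered sandwich variance; average adjusted
  predictions with delta-method SEs.
* **Recurrence risk ratio** λ_R = K_exposed / K_population with
  delta-method SE (numerator/denominator independence assumed), one-sided
  test of λ_R > 1, lower 95% bound only.
* **Familial correlation** r_f by inverting the liability threshold
  model: K_pred = P(X > t_A, Y > t_B; ρ = a_R·r_f) / K_B, solved per
  degree × direction component and combined by inverse-variance
  weighting; one-sided test of r_f > 0.
* **FDR control**: one Benjamini–Hochberg family across every λ and r_f
  test in the study grid.
* **Synthetic cohorts**: a liability-threshold simulator (three-generation
  families, matrix-normal familial covariance A ⊗ C, multi-wave records
  with missingness) with known generative r_f, so the whole pipeline is
  testable by parameter recovery.

## Worked example

Simulate a cohort of 300 ten-member families with two traits (lifetime
prevalences 0.10 and 0.15) and a generative familial correlation of 0.30,
then run the co-aggregation analysis:

```r
library(famcoag)

cfg <- simulationConfig(nFamilies = 300, seed = 42)
sim <- simulateStudy(cfg)
sim$ped
#> Pedigree with 3000 individuals (+0 placeholder founders) in 300 families
#>   sex: male=1500, female=1500, unknown=0
sim$panel
#> PhenotypePanel: 2987 individuals x 2 phenotypes
#>   lifetime prevalence (%): trait_a=8.4, trait_b=12.3

res <- runCoaggregationStudy(sim$ped, sim$panel,
                             focal = "trait_a", diseases = "trait_b")
res$lambda[, c("outcome", "relative_phenotype", "K_pop", "K_exposed",
               "lambda", "lower95", "p_adjusted", "significant")]
#>   outcome relative_phenotype  K_pop K_exposed lambda lower95 p_adjusted significant
#> 1 trait_a            trait_b 0.0844     0.127   1.51    1.21    0.00228        TRUE
#> 2 trait_b            trait_a 0.1225     0.184   1.50    1.23    0.00150        TRUE

res$rf[, c("phenotype_A", "phenotype_B", "rf", "se", "lower95", "p_adjusted")]
#>   phenotype_A phenotype_B    rf     se lower95 p_adjusted
#> 1     trait_a     trait_b 0.303 0.0486   0.224   6.22e-10
```

Reading the output: trait_a is about 1.5× as prevalent in people with an
affected first-degree relative for trait_b as in the population (and vice
versa), with one-sided 95% lower bounds above 1; inverting the liability
model across both relative degrees and directions gives a familial
correlation of 0.30 (SE 0.05), significant after BH correction across the
three tests. The observed panel prevalences (8.4%, 12.3%) sit slightly
below the generative targets because wave missingness can hide a case's
affected assessments — exactly the mechanism real multi-wave cohorts face.

File-based studies run from a YAML config naming a PED file, an
assessment TSV, wave order, focal/disease sets and optional
exclusions — `runStudy("config.yaml")` writes `lambda.tsv`, `rf.tsv`,
`tests.tsv` and a reproducibility manifest.

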