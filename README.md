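# famlipid

Family-based analysis of dyslipidemia and serum lipid traits in
longitudinal cohorts: how strongly do total cholesterol, triglycerides,
HDL-C, LDL-C and dyslipidemia itself run in families, and how much of
their variation does the pedigree explain?

The package is aimed at genetic-epidemiology analysts working with
family-structured cohort data (PED-style pedigrees plus per-phase lipid
measurements). It provides:

* **Pedigree machinery** — validated PED parsing, kinship coefficients φ
  by the recursive tabular method, the numerator relationship matrix
  A = 2φ, typed relative-pair enumeration (parent–offspring, siblings,
  grandparental, avuncular, half-siblings, cousins, spouses) and the
  consanguineous-marriage rate.
* **Phenotype processing** — Friedewald LDL-C (TC − HDL − TG/5, invalid at
  TG ≥ 400 mg/dL), TC medication adjustment (÷0.8 under lipid-lowering
  treatment), ATP III flags (TC ≥ 200, TG ≥ 200, LDL ≥ 160; HDL < 40
  men / < 50 women, mg/dL), first-measurement (FM) and
  average-measurement (AM) scenario tables, age/sex residualization and
  the rank-based inverse normal transform (Blom offset 3/8).
* **Cohort analysis** — configurable inclusion/exclusion screening,
  longitudinal dyslipidemia status (drug history or ≥ 1 ATP III flag in
  ≥ 2 phases), point and periodic prevalence.
* **Familial resemblance** — intraclass correlations by relative-pair
  type (double-entry estimator for exchangeable pairs, interclass for
  ordered pairs) with family-cluster bootstrap intervals, for continuous
  traits and binary status; covariate-adjusted logistic odds ratios for
  parental dyslipidemia history.
* **Heritability** — the polygenic mixed model
  `y = Xβ + g + e`, `g ~ N(0, A·σg²)`, fitted two ways: profile
  maximum likelihood (ML/REML) over h² = σg²/(σg² + σe²), and a Gibbs
  sampler with closed-form full conditionals; binary dyslipidemia through
  a probit liability model with latent-variable augmentation
  (h² = σg²/(σg² + 1) on the liability scale). Gelman–Rubin PSRF
  convergence diagnostics throughout.
* **A synthetic cohort generator** with known variance components
  (additive genetic, shared household, permanent environment, phase
  error), liability-threshold disease and a controllable consanguinity
  rate, so every stage is testable against planted truth.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` companions.

## Worked example

Simulate a 200-family cohort, estimate TC heritability from the
first-measurement scenario, and summarize dyslipidemia:

```r
library(famlipid)

cfg    <- simulation_config(n_families = 200, generations = 1, seed = 42)
cohort <- simulate_cohort(cfg)
kin    <- kinship_matrix(cohort$pedigree)

fm  <- first_measurement(cohort$phenotypes)   # earliest phase at age >= 18
fit <- fit_polygenic_ml(adjust_traits(fm), "tc", kin)
fit
#> <polygenic_fit> trait:tc method:ML
#>   h2 = 0.6024 (SE 0.0495)  sigma_g2 = 0.5856  sigma_e2 = 0.3865

st <- dyslipidemia_status(classify_lipid_flags(cohort$phenotypes))
periodic_prevalence(st, cohort$phenotypes)
#> # A tibble: 1 × 3
#>   prevalence n_positive     n
#>        <dbl>      <int> <int>
#> 1      0.941        934   993
```

The h² of 0.60 against a planted additive share of 0.43 is the package's
own caveat on display: the generator plants a shared-household effect
(10% of variance) that a pedigree-only model absorbs into σg², so
family-based heritability overstates the purely additive share. The 94%
periodic prevalence reflects the generator's wide trait dispersions
(matched to the emulated cohort's published SDs) pushing many simulated
people over an ATP III cut-point in two phases.

Sibling resemblance for the same cohort:

```r
pairs <- pedigree_pairs(cohort$pedigree)
sib   <- build_pair_values(pairs[pairs$category == "sibling", ],
                           dplyr::rename(adjust_traits(fm), value = tc))
pair_icc(sib[sib$exchangeable, ], n_boot = 500, seed = 1)
#> # A tibble: 1 × 5
#>     icc ci_low ci_high n_pairs significant
#>   <dbl>  <dbl>   <dbl>   <int> <lgl>
#> 1 0.444  0.329   0.541     325 TRUE
```

Same-sex sibling pairs correlate at ≈ 0.44 (family-cluster bootstrap CI),
consistent with half the additive variance plus the shared household
share, plus this realization's sampling noise.

A staged driver (`run_pipeline()`) chains simulation, kinship, pairs,
prevalence, ICCs, family-history ORs and both heritability engines behind
one seed and writes TSV/JSON artifacts plus a manifest;
`inst/cli/famlipid.R` is a thin command-line wrapper over it.

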