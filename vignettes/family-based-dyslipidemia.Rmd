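---
title: "Models and methods: family-based dyslipidemia analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: family-based dyslipidemia analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famlipid)
```

famlipid analyzes the familial transmission of dyslipidemia and serum
lipid traits (TC, TG, HDL-C, LDL-C) in longitudinal family cohorts. This
vignette describes the models, the defaults and why they were chosen, what
the synthetic cohort generator does and does not emulate, and the known
limitations.

## Phenotype processing

Lipid records are per person and phase (five phases, 3-year spacing in the
design the simulator emulates). Processing steps, in order:

* **Medication adjustment.** Measured TC under lipid-lowering treatment is
  divided by 0.8 (`adjust_tc_for_medication()`), restoring an estimate of
  the untreated level. Only TC is adjusted. When LDL-C is derived rather
  than assayed, the default is to derive it from the *adjusted* TC — the
  alternative order is available through the `formula` hook and by
  adjusting after derivation.
* **Derived LDL-C.** `friedewald_ldl()` computes `TC − HDL − TG/5`
  (mg/dL), invalid (`NA`) at TG ≥ 400 mg/dL. The classic formula is the
  default because it is fully reproducible; a replacement function can be
  supplied for any modified variant.
* **ATP III flags.** `classify_lipid_flags()`: high TC ≥ 200, high TG
  ≥ 200, high LDL-C ≥ 160; low HDL-C < 40 (men) / < 50 (women), all
  mg/dL, all configurable.
* **Scenario tables.** `first_measurement()` (FM) takes each person's
  earliest phase at age ≥ 18; `average_measurement()` (AM) averages each
  trait over all eligible non-missing phases, reporting per-trait counts
  (availability differs by trait). Averaging reduces phase-level
  measurement error by roughly the number of phases, which is why
  AM-based heritability estimates exceed FM-based ones whenever such
  error exists.
* **Adjustment and normalization.** `residualize()` regresses the trait
  (log scale for TG, HDL-C, LDL-C; raw scale for TC) on age and sex;
  `inverse_normal_transform()` maps the residuals to normal scores
  `qnorm((rank − 3/8)/(n + 1/4))` (Blom offset, midranks for ties). The
  offset is configurable; 3/8 is the common default of rank-based
  inverse-normal packages. The combination is invariant to affine
  rescalings of age.

## Dyslipidemia and prevalence

A person is dyslipidemic (`dyslipidemia_status()`) if they have a positive
lipid-lowering drug history at any phase, or meet at least one ATP III
threshold in at least two phases. The source wording grammatically also
lists "over age 40" as a qualifying condition; age alone cannot define
disease, so the implemented rule is drug-history OR two-phase threshold,
with a strict mode (`drug_rule = "over40"`) requiring drug use after 40.

`point_prevalence()` is the proportion already positive at the baseline
phase among persons observed there; `periodic_prevalence()` adds persons
first turning positive in later phases, over everyone ever observed. With
different denominators the periodic value can in principle drop below the
point value if many never-affected persons enrol late; with a common
baseline population it cannot, and the output records the denominator
convention.

Inclusion/exclusion (`apply_exclusions()`) reports one row per person with
all triggered reasons: under 18 throughout, extreme lipid values (robust
z > 5 on the log scale by default — "extreme" is otherwise undefined, and
a median/MAD rule is conservative and unit-free; absolute bounds are
configurable), a simplified familial-hypercholesterolemia screen
(TC > 290 or LDL-C > 190, optionally gated on a family-history flag; the
full clinical criteria need records this package does not model), drug
use before 40, and drug use or cardiovascular disease after 40.

## Pedigree structure

`kinship_matrix()` implements the recursive tabular method: processing
individuals parents-first, `phi[i,j] = (phi[i,f] + phi[i,m])/2` and
`phi[j,j] = (1 + phi[f,m])/2`, founders unrelated and non-inbred. Families
are independent blocks, so the matrix is stored sparse block-diagonal. The
additive (numerator) relationship matrix is `A = 2*phi`, with
`diag(A) = 1 + F`. The random-effect covariance in all heritability models
is `A` (not `phi`): with `phi` the genetic variance would be halved and
heritabilities implausibly small relative to the magnitudes family studies
report.

`pedigree_pairs()` classifies each within-family pair into at most one
blood category with first-degree precedence (a pair that is both sibling
and cousin in a consanguineous pedigree counts once, as siblings), and
enumerates spouse pairs separately (inferred from shared offspring, plus
an explicit list for childless couples). `consanguinity_rate()` is the
fraction of spouse pairs with kinship > 0.

## Familial correlations

Exchangeable pair types (same-sex sibling-like pairs, spouses) use the
double-entry product-moment correlation — each pair entered both ways —
which on balanced pairs equals the one-way random-effects ANOVA ICC
computed with method-of-moments (divide-by-n) mean squares; ordered types
(parent-offspring, grandparental, avuncular, mixed-sex siblings) use the
interclass correlation with the senior (or male) member in the first
slot. Binary statuses run through the same machinery (a phi-type
observed-scale correlation). Confidence intervals are percentile cluster
bootstraps resampling whole families (default 2000 resamples), because
pairs within a family share members and are dependent; Fisher-z intervals
would be anti-conservative. Every estimate is written with a
`significant` flag (CI excludes 0) rather than filtering the table.

## Heritability models

**Gaussian polygenic model** (`fit_polygenic_ml()`):
`y = X beta + g + e`, `g ~ N(0, A sigma_g^2)`, `e ~ N(0, I sigma_e^2)`.
A per-family eigendecomposition of `A` rotates the model so the random
effect has independent components; the likelihood then depends on
`h2 = sigma_g^2/(sigma_g^2 + sigma_e^2)` through a weighted least-squares
profile, maximized on [0, 1] (`optimize`, tolerance 1e-8), with total
variance and fixed effects profiled out analytically. ML is the default;
REML is available. The SE of h2 is the inverse square root of the
numerical curvature of the profile log-likelihood (central differences,
step 1e-4). Degenerate cases: a flat profile (e.g. all individuals
unrelated) is reported as h2 = 0 with a `boundary` flag, as are optima at
the endpoints. Fixed effects default to intercept-only because traits are
normally pre-residualized on age and sex; passing `covariates = c("age",
"sex")` instead avoids double adjustment when raw traits are supplied.

**Gaussian Gibbs sampler** (`gibbs_gaussian()`): the same model sampled by
closed-form full conditionals in the rotated basis — multivariate draws
reduce to vectorized univariate normals, and the two variances are scaled
inverse-chi-squares. Priors default to df 5 and scale `var(y)/2` for both
components (weakly informative, a common default of pedigree-BLUP Bayesian
software; configurable, and required explicitly for prior-only runs).
Chains start from overdispersed points (prior scale times `exp(U(−1,1))`).

**Probit liability model** (`gibbs_probit()`): binary status is an
indicator that a latent Gaussian liability `l = X beta + g + e`, `e ~
N(0,1)` (fixed for identifiability), exceeds 0, giving `P(status) =
Phi(eta)`. Latent liabilities are drawn from truncated normals consistent
with each status (inverse-CDF, vectorized), after which the Gaussian
updates apply with residual variance 1. Liability-scale heritability is
recorded per retained sample as `sigma_g^2/(sigma_g^2 + 1)`. The prior
scale for `sigma_g^2` defaults to half the variance of the observed 0/1
outcome, the binary-response analogue of the Gaussian default.

**Schedules and diagnostics.** `mcmc_config()` defaults to 50,000
iterations, 25,000 burn-in, thinning 25, two chains — a desk-scale
schedule that mixes well for these conditionally conjugate samplers; the
large published-style schedule (400,000/200,000/40, retaining 5,000
samples) is available through the same constructor. `gelman_rubin()`
implements the potential scale reduction factor
`sqrt(((n−1)/n W + B/n)/W)`; `summarize_posterior()` reports moments,
equal-tailed 95% intervals and the PSRF per parameter, with `h2`
summarized as the mean of per-sample variance ratios (never a ratio of
means).

Two numerically honest caveats. First, with `A = I` (no relatives) the
Gaussian likelihood depends only on `sigma_g^2 + sigma_e^2`: h2 is
unidentified and its posterior sits near the prior's balance point, not
near zero — the meaningful null check is planting `sigma_g^2 = 0` on a
*real* pedigree, where the posterior does concentrate near zero. Second,
posterior means of liability h2 at a few hundred families are attenuated
by a few hundredths (prior shrinkage plus the concavity of
`s/(s+1)`), and single-cohort estimates carry realization noise of about
±0.05; recovery claims in the test suite therefore average over replicate
cohorts.

## Family-history odds ratios

`parental_exposure()` categorizes offspring by affected parents among
parents of known status (`no_affected_parent`, `at_least_one` — which
pools `both` — and `both`); offspring with no parent of known status are
omitted. `fit_logistic_or()` fits a maximum-likelihood logistic model
(IRLS, coefficient tolerance 1e-8, max 100 iterations) of offspring status
on the exposure contrast plus age and sex, reporting `exp(beta)` with Wald
95% intervals; constant covariates (e.g. sex within a single-sex stratum)
are dropped automatically, and (quasi-)separation is an error rather than
a silently huge estimate. Family clustering is ignored in the point
estimate, matching the plain logistic analysis this mirrors; the ICC
machinery's cluster bootstrap illustrates what accounting for it looks
like elsewhere in the package.

## The synthetic cohort generator

The generator exists so every stage is testable with known truth, since
cohorts like the one this package targets are not publicly deposited.

* **Pedigrees** (`simulate_pedigree()`): founder couples, sibship sizes
  uniform on a range (default 2–4) or an explicit distribution, children
  of non-final generations marrying with probability 0.6 by default.
  Consanguineous marriages (kinship in (0, 0.2], typically first cousins)
  are formed by rate-targeting control from the grandchild generation
  onward, so the achieved rate converges on the configured one (e.g. the
  28% rate typical of the emulated population).
* **Trait values** (`simulate_longitudinal_lipids()`): per-trait sex
  means/SDs default to the published baseline characteristics of the
  emulated cohort (e.g. TC 194.43/182.56 mg/dL for men/women); TG is
  log-normal (moment-matched). On the working scale each record is
  `mu_sex + age_effect (age − 40) + g + household + permanent + phase
  error`, with variance shares: additive genetic (default per-trait
  heritabilities 0.34–0.43, the emulated cohort's likelihood-based FM
  estimates), shared household 0.10, phase error 0.20, remainder
  permanent environment. The household effect is included deliberately
  even though the polygenic estimators cannot separate it — pedigree
  heritability absorbs shared environment, and the generator lets tests
  demonstrate that rather than hide it. Age effects (0.7, 0.006 log,
  0.05, 0.6 per year for TC/TG/HDL/LDL) are realistic modest trends; ages
  advance 3 years per phase; drug and CVD flags switch on with
  age/TC-dependent probabilities and persist; records after a person's
  first drop out at the missingness rate (default 0.1).
* **Disease** (`simulate_disease_status()`): liability `g + e` with
  variances `(h2, 1 − h2)` thresholded at `qnorm(1 − prevalence)`;
  defaults 0.41 and 0.40.

What it does **not** emulate: assortative mating (beyond what a user
plants), secular trends, trait-trait correlations (traits are generated
independently), realistic drug-prescription behaviour, or the exact
family-size distribution of a real register (sizes are governed by the
sibship and marriage parameters). Passing tests on generated cohorts
demonstrate internal statistical correctness under the stated model, not
that real data meet those assumptions.

## Pipeline

`run_pipeline()` chains the stages (`simulate`, `kinship`, `pairs`,
`prevalence`, `icc`, `history`, `h2-ml`, `h2-bayes`, `report`) behind a
single seed, writing TSV/JSON artifacts plus a manifest (package version,
seed, config hash). Exclusions are applied before all downstream
analyses. A thin command-line wrapper ships in `inst/cli/famlipid.R`. The
Bayesian stage of the driver runs a deliberately short schedule by
default — it is a smoke-level orchestration; for inference use
`gibbs_gaussian()`/`gibbs_probit()` directly with `mcmc_config()`.

## Problem sizes used in the test suite

Unit tests run on cohorts of tens to a few hundred families; the recovery
studies use 500-family cohorts (40 replicates, Gaussian) and 400-family
cohorts (10 replicates, probit), and the convergence check uses a
300-family cohort with two 50,000-iteration chains — sizes at which the
Monte-Carlo error of each check is small relative to its tolerance while
the whole suite stays comfortably runnable on a laptop.

## Known limitations

* Single variance component plus residual: no separate household/common
  environment component in the *estimators* (the generator has one), no
  dominance or epistasis, no marker-based relationships.
* The probit model fixes the threshold at 0 with a free intercept; no
  multi-threshold (ordinal) support.
* ICC confidence intervals are bootstrap percentiles; no closed-form
  small-sample corrections.
* The FH screen is a crude stand-in for clinical criteria.
* mg/dL only; no unit conversion.
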