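---
title: "Gene-diet interaction on AMD risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-diet interaction on AMD risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyegee)
```

## The analysis in one page

`eyegee` studies how a polygenic risk score and Mediterranean-diet
adherence jointly shape the risk of age-related macular degeneration
(AMD), with the individual eye as the unit of analysis. The chain is:

1. FFQ answers → daily gram intakes → nine-component mediSCORE →
   high/low adherence;
2. genotypes → weighted 52-variant GRS → high/low genetic risk at the
   cohort median;
3. Rotterdam stages → case/control classification → eye-level records;
4. logistic GEE with exchangeable inter-eye correlation, adjusted for age
   band, sex, smoking and physical exercise;
5. interaction measured on the multiplicative scale (exp(β_GD)) and the
   additive scale (RERI, AP, SI) with delta-method and cluster-bootstrap
   intervals.

## Diet scoring

Each FFQ answer records a frequency category (nine ordered levels), a
serving count and a seasonal flag. Daily grams are
`occasions/day × servings × grams-per-serving`, where occasions/day is the
category midpoint (0, 2/30.44, 1/7, 3/7, 5.5/7, 1, 2.5, 4.5, 6 — the
questionnaire gives only labels, so the standard FFQ midpoint convention is
used and the mapping is overridable). Seasonal items are multiplied by
0.25, spreading a roughly three-month availability window over the year.

The mediSCORE awards one point per group. Cut-offs are sex-specific
medians of the scored population by default; `mediscore()` also accepts a
fixed external cut-off table, because reference medians may come from a
larger source population than the analysis sample. Tie handling follows a
literal reading of "above the median": a beneficial group scores only for
intake strictly above the median, the detrimental groups score at or below
it. The alcohol windows (10–50 g/day men, 5–25 g/day women) are inclusive
at both ends, and the alcohol group total is interpreted as grams of
ethanol per day — the packaged catalog therefore lists ethanol grams per
serving for alcoholic items, and this assumption is deliberate and
documented rather than hidden. A subject with zero saturated-fat intake
has an undefined lipid ratio: the component scores 0 and the subject is
flagged (`ratio_missing`) rather than dropped.

## Genetic risk score

GRS = Σᵢ Nᵢβᵢ over the variant panel, with Nᵢ the risk-allele count
oriented against the declared risk allele of the weight table (never
assumed to be the VCF ALT allele). Missing genotypes are never imputed: a
missing major variant voids the score and excludes the subject; a missing
non-major variant contributes zero, and the per-subject count of missing
variants is reported so heavy missingness can be filtered downstream —
scores computed under different missingness patterns are not strictly
comparable, which is why the count is surfaced. Dichotomization is
at-or-above the median of included subjects, computed after the exclusions
(the even-count median is the midpoint of the middle two, matching the diet
module's convention).

The packaged 52-variant weight table is synthetic: the five major risk
variants carry their published rsIDs with plausible effect sizes, the other
47 rows are generated ids with small effects frozen once
(`inst/extdata/synthetic_variant_weights.csv`). It exercises the scoring
rules; it is not a reference panel.

## Case/control definition and eye records

The subject phenotype is the worst eye's Rotterdam stage: 2a, 2b, 3 or 4
makes a case; stage 0 is a control only above age 60 and stage 1 only above
70 (strict inequalities, age at examination), so participants who might
still progress are excluded rather than mislabelled. Eye-level outcomes
reuse the same stage set, so a case's unaffected eye contributes a 0 — the
only reading under which subject- and eye-level definitions agree. The
printed age bands "60–70, 70–75, >75" overlap at their joins; the package
uses the half-open partition [60, 70), [70, 75), [75, ∞) with 60–70 as
reference, configurable where it matters. Subjects dropped at this stage
(unclassifiable, invalid GRS, missing diet score, age below the bands) are
returned in an exclusion log rather than silently discarded.

## The GEE model

For eye *j* of subject *s* with covariate row x, the marginal model is
logit P(Y = 1 | x) = x'β, fitted by generalized estimating equations with
an exchangeable working correlation (any two eyes of a subject share a
common α). The solver is Fisher scoring with the moment estimators for the
scale φ and α re-evaluated from Pearson residuals at each step;
convergence is a maximum absolute coefficient change below 1e-8 within 100
iterations (standard choices; nothing in the problem is sensitive to
them). Only the robust (sandwich) covariance is reported — with paired
eyes and a working correlation that is at best approximate, naive standard
errors have no role. Clusters of size one and two are handled by
closed-form vectorized algebra (the paired-eye case), larger clusters by a
per-cluster solve, so the same function covers degenerate and general
inputs. With singleton clusters the estimating equations reduce to the
ordinary logistic score equations, which the tests exploit by
cross-checking against `glm()`; non-convergence returns the last iterate
with a flag and a warning rather than an error so bootstrap loops can
count and discard failed replicates.

## Interaction measures

Additive measures are defined for risk factors, so the protective diet
indicator is recoded (`recode_protective()`) and the joint reference
becomes (high adherence, low GRS). From the interaction fit:
OR₀₁ = exp(β_G), OR₁₀ = exp(β_D), OR₁₁ = exp(β_G + β_D + β_GD), each with
a Wald interval on its linear combination. The multiplicative measure is
exp(β_GD) = OR₁₁/(OR₀₁·OR₁₀); the additive measures are RERI, AP and SI
applied exactly as defined. Delta-method variances use the analytic
gradients of each measure in (β_G, β_D, β_GD) against the robust
covariance; RERI and AP are tested against 0 on their natural scale, SI on
the log scale with the interval back-transformed — the standard practice,
and the reason SI can reach significance when RERI and AP do not. The
bootstrap resamples subjects (clusters) with replacement, carrying both
eyes together, refits the full GEE per replicate and takes percentile
intervals; replicates that fail to converge are counted and a warning is
raised past 20%. Within-stratum ORs come from linear combinations of the
interaction fit (exp(β_D), exp(β_D + β_GD), and symmetrically for the
GRS), with stratum-subset refits offered alongside as an independent
route; protective-direction ORs for plots are exact reciprocals.

## The synthetic cohort generator

The generator exists so that every downstream stage has a truth to recover.
Its defaults are the study conditions of a cohort of this design: 612
subjects; covariate margins of roughly 57% women, 14% smokers, 44%
exercising, ages ~N(72.5, 6.5²) truncated to [55, 95]; exposure effects
β_G = log 1.788, β_D = log 2.327, β_GD = log 1.111 with covariate effects
of the magnitudes reported for age bands, sex, smoking and exercise; an
intercept of −3.15 calibrated once so the marginal case fraction lands
near 26%; a diet profile tuned once so high adherence sits near one in
five and the moderate-alcohol component near 8%; and 0.65% ungradable
eyes. Genotypes are Binomial(2, maf) per variant under linkage
equilibrium — LD is irrelevant to additive score arithmetic. FFQ answers
arise from per-group baseline frequency levels shifted by a subject-level
latent "diet quality", which induces the correlation between beneficial
components that real diets show; alcohol does not load on it.

Outcomes are *marginally specified*: the linear predictor defines each
eye's marginal probability p = logit⁻¹(x'β), and inter-eye correlation is
induced by a shared per-subject normal latent effect u_s whose conditional
probability logit⁻¹(δ + u_s) is solved (25-node Gauss–Hermite quadrature
plus Newton, to |error| < 1e-12) so that its average over u_s equals p
exactly. A plain random-intercept draw would attenuate the marginal
coefficients that GEE estimates by roughly (1 + 0.346·σ²)^{-1/2},
making "GEE recovers the generating β" false by construction; the
marginalized formulation keeps the latent-effect device *and* the recovery
property, and the package's core calibration test (200 replicates of
n = 2000) checks exactly that. Dichotomized exposures — not the continuous
scores — enter the outcome model, matching how the data are analysed, and
GRS and diet are generated independently (no joint distribution of the two
is available to emulate; dependence would be a config extension).

What the generator does not emulate: linkage disequilibrium, realistic
nutrient correlation structure beyond the single quality axis, sampling
into the study (cases arise from the population model, not outcome-
dependent sampling), and grading error. Passing tests therefore show the
*estimators* are correct under the assumed data-generating model, not that
any real cohort satisfies those assumptions.

## Numerical and design choices

- Medians everywhere use the midpoint-of-middle-two convention for even
  counts (`stats::median`).
- Degenerate inputs fail loudly and early: unknown frequency labels, item
  ids or Rotterdam stages name the offending row at load; rank-deficient
  designs name the aliased column; a design with fewer than two clusters,
  an empty sex stratum, or no included GRS subject is an error. An
  all-missing genotype row, by contrast, is a valid null result.
- The descriptive case/control table uses the rank-sum test for continuous
  variables and Pearson's chi-squared for categorical ones, switching to
  Fisher's exact test when any expected cell count is below 5 (the
  textbook rule, configurable); single-level variables are summarised with
  the test skipped.
- Problem sizes in the test suite (cohorts of 500–2000 subjects, 200
  recovery replicates, 500 bootstrap draws at n = 5000) are chosen so that
  Monte-Carlo error is small against the effects being checked while the
  suite stays quick to run.
- Delta-vs-bootstrap agreement is judged on interval-endpoint discrepancy
  relative to the interval width: RERI interval endpoints routinely sit
  near or below zero, where ratios of endpoints are numerically
  meaningless.

## Limitations

The GEE solver supports the logit link with exchangeable or independence
working correlation only — the design this package serves. No energy
adjustment or nutrient-level analysis beyond the MUFA/SFA ratio is
offered. Bootstrap intervals at small cohort sizes inherit the instability
of refitting an interaction model on sparse joint-exposure cells; the
non-convergence accounting makes that visible rather than fixing it.

## A worked run

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_config(), seed = 1)
result <- run_pipeline(cohort = cohort, seed = 1, n_boot = 200)
print(result)
plot(result$interaction)
```
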