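---
title: "Attributable cancer burden from lifestyle risk factors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable cancer burden from lifestyle risk factors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafburden)
```

`pafburden` implements a comparative risk assessment for cancer: given the
population distribution of modifiable lifestyle exposures (alcohol
consumption, high body mass index, low fruit and vegetable consumption,
physical inactivity, tobacco smoking, passive smoking), relative risks per
exposure–cancer pair, and cancer occurrence counts, it estimates the
proportion and number of cancer cases and deaths that would be avoided if
the population's exposure were shifted to a theoretical-minimum-risk
counterfactual. The bundled fixtures describe Chile in 2018 (national health
survey prevalence, GLOBOCAN occurrence, published PAF tables), but every
stage takes ordinary tibbles and works on any comparable inputs.

## The attributable-fraction model

### Categorical exposures

For an exposure observed in levels $i = 1, \dots, n$ with population
proportions $P_i$ and level relative risks $RR_i$, the population
attributable fraction against the counterfactual $P^{*}$ that places the
whole population at the theoretical-minimum-risk exposure level (TMREL) is

$$
\mathrm{PAF} \;=\;
\frac{\sum_i P_i\,RR_i - \sum_i P^{*}_i\,RR_i}{\sum_i P_i\,RR_i}
\;=\; 1 - \frac{1}{\sum_i P_i\,RR_i},
$$

the simplification holding because $RR = 1$ at the TMREL by construction
(`relative_risk_set()` enforces this). `paf_categorical()` evaluates the
ratio form; the closed form is used as an algebraic cross-check in the test
suite. The PAF is zero exactly when all $RR_i = 1$ or when the population
already sits wholly at the TMREL, and is strictly below 1 for finite risks.
Net-protective exposure patterns yield a negative PAF, which is returned
as-is with a warning — clamping to zero would silently bias aggregates.

### Continuous exposure (BMI)

BMI enters as a continuous dose. With observed density $P(x)$, counterfactual
density $P^{*}(x)$ and a dose–response curve $RR(x)$,

$$
\mathrm{PAF} \;=\;
\frac{\int RR(x)P(x)\,dx - \int RR(x)P^{*}(x)\,dx}{\int RR(x)P(x)\,dx}.
$$

Modelling choices, all configurable:

* **Densities.** $P$ is Normal(mean, sd) and $P^{*}$ is Normal(22, 1), both
  in kg/m² — the counterfactual reads the TMREL "mean BMI of 22 kg/m² with
  sd 1" as a narrow normal rather than a point mass. Both densities are
  truncated to the integration range `c(10, 60)` kg/m² (plausible adult BMI)
  and renormalised.
* **Dose–response.** The default `log_linear` model sets
  $RR(x) = b^{\,x - 22}$ above the TMREL, where $b$ is the relative risk per
  1 kg/m² increase, optionally saturated at `cap_dose`. A `log_logit`
  alternative saturates $\ln RR$ itself along a logistic curve: published
  analyses often name this family without printing its parameterisation, so
  ours is an explicitly labelled interpretation:
  $\ln RR(x) = \ln(b)\,D\,[S(\tfrac{x - 22 - D/2}{s}) - S(\tfrac{-D}{2s})]$
  with $S$ the standard logistic, saturation span $D$ (default 20 kg/m²) and
  scale $s = D/4$. The subtraction anchors $RR = 1$ continuously at the
  TMREL (the raw logistic would jump there), and $s = D/4$ makes the
  log-slope at the curve's inflection equal the log-linear slope $\ln b$ —
  a tail-slope match at the TMREL itself is impossible for this family,
  whose maximal log-slope $\ln(b)\,D/(4s)$ occurs at the midpoint.
* **No protective extrapolation.** Both forms return $RR = 1$ for
  $x \le 22$: being below the TMREL earns no protective credit, consistent
  with TMREL semantics.
* **Quadrature.** $RR(x)$ is identically 1 below the TMREL and smooth above
  it, with a derivative kink at 22 kg/m². Integrating across the kink would
  reduce Gauss–Legendre quadrature to low-order convergence, so
  `paf_continuous()` accounts for the below-TMREL probability mass
  analytically (it contributes exactly its mass) and applies 512-node
  Gauss–Legendre only on the smooth piece above the TMREL. Results are
  stable to $10^{-8}$ under grid refinement, and the test suite checks them
  against both an adaptive-quadrature oracle and a $10^6$-draw Monte-Carlo
  oracle (agreement within 3 Monte-Carlo standard errors).

### Combination across risk factors

Assuming the factors are independent (no statistical interaction),

$$
\mathrm{PAF}_{\text{combined}} = 1 - \prod_i (1 - \mathrm{PAF}_i),
$$

implemented by `combine_pafs()`. The form is commutative, associative,
reduces to inclusion–exclusion $p_1 + p_2 - p_1 p_2$ for two factors,
dominates every component for non-negative inputs, and stays below 1.

## From survey records to prevalence

`estimate_prevalence()` turns individual survey-style records into the
categorical distributions above, using the instrument conventions of the
Chilean national health survey (ENS 2016–2017):

* **Alcohol**: one standard drink carries 12.5 g of pure alcohol; bands
  abstainer $\{0\}$, light $(0, 12.5]$, moderate $(12.5, 50)$, heavy
  $[50, \infty)$ g/day. Printed band labels ("1–12.5", "12.6–49.9") leave
  gaps on the gram scale; half-open intervals restore totality while keeping
  every printed cutpoint in its printed band, and intakes below 1 g/day are
  assigned to the light band.
* **Fruits/vegetables**: one serving is 80 g; the weekly average is
  `servings × 80 × days/7` — our reading of "servings per day" combined with
  "days per week", kept configurable. Left-closed 100 g (combined) or 50 g
  (fruit-only) bands.
* **Physical activity**: GPAQ items scored at 4 MET (active transport),
  3.8/7.8 MET (moderate/vigorous occupational) and 3/6 MET
  (moderate/vigorous recreational); bands at 600, 4000 and 8000
  MET-min/week, left-closed.
* **BMI**: self-reported weight/height² used as-is (no self-report
  correction, matching the source analysis).
* **Passive smoking** is defined among never-smokers only; other records
  leave that exposure's denominator.
* **Weights**: simple survey-weighted proportions, normalised within sex —
  invariant to uniform rescaling. The multistage sampling design
  (clustering, nonresponse, design-effect variance) is out of scope; only
  point prevalence is produced.

## Attribution, subtypes and aggregation

`compute_attribution()` (first-principles path) and
`reproduce_from_paf_table()` (reproduction path from a printed PAF table)
both end in `aggregate_attribution()`, which enforces the conventions that
make published tables internally consistent:

* **Subtype restrictions** scale a subtype-specific PAF down to the site
  level by the subtype's share of site counts (cardia/non-cardia stomach,
  oesophageal adenocarcinoma/squamous cell carcinoma) — attributable counts
  accrue on the subtype share but are reported against the whole-site total.
* **Advanced prostate cancer** incidence is approximated by prostate
  deaths: the PAF applies to the death count and the result is reported
  against the whole-site case total.
* **Combination is done at site level**, on the per-exposure site PAFs,
  within each sex — this reproduces the published combined per-site values.
* **Pooled ("both sexes") PAFs** are always sex-specific attributable counts
  summed and divided by pooled totals, never products of pooled PAFs (the
  naive pooled product fails on sites with very different sex-specific
  totals).
* **Physical activity** is associated with colon cancer in the exposure
  mapping but reported against colorectum totals in the published burden
  tables; the bundled eligibility map follows the burden tables.
* **Rounding**: all arithmetic is unrounded; presentation rounds PAFs to
  0.1 percentage point and counts to integers, half away from zero
  (`round_half_away()`; `base::round()`'s half-to-even would disagree with
  printed tables on exact halves).

Reproducing from printed PAF columns (rounded to 0.1 pp) propagates small
errors into aggregates; headline percentage aggregates nevertheless match
the printed values after rounding back to 0.1 pp, and count aggregates land
within a few units. The published grand totals (15,097 attributable cases;
10,155 deaths) are matched to within a few counts but not exactly — the
original internal unrounded values are not recoverable from the printed
surface — so they are asserted loosely (2%) in the acceptance tests.

## The synthetic-data generator

`generate_survey()`, `generate_rr_table()` and `generate_occurrence()` make
every stage testable without external data. Design:

* Defaults are the study conditions the package emulates: level proportions
  and BMI means from the bundled prevalence fixture, the exposure–site
  roster from the bundled eligibility map, occurrence counts Poisson with
  mean 1000 per site/sex (the scale of national site-level counts), deaths
  by binomial thinning at 0.5 (guaranteeing deaths ≤ cases). The fixture's
  BMI standard deviations (4.5 men, 5.0 women kg/m²) are synthetic
  stand-ins at typical adult values, flagged in the fixture itself, because
  the source tables print confidence intervals of the mean rather than
  population sds.
* Raw questionnaire items are back-generated from the sampled category —
  grams drawn uniformly inside the band window, MET volume realised through
  a single randomly chosen GPAQ domain — so the derivation operations
  reproduce the intended category exactly and estimated prevalence converges
  to the configured truth at the binomial rate (checked at
  $n = 10^3$–$10^5$).
* Fruit-only and combined fruit-and-vegetable consumption are generated as
  separate questionnaire items so both marginal distributions are exactly
  controllable. The generator therefore does not enforce joint coherence
  between them (a record's fruit intake can exceed its combined intake);
  marginal prevalence, which is all the PAF machinery consumes, is faithful.
* Relative risks are log-uniform (default $[1.2, 3.0]$ across levels,
  $[1.02, 1.15]$ per BMI unit), sorted non-decreasing with RR = 1 at the
  TMREL.
* Ground truth (`ground_truth_pafs()`) is computed by separately coded
  oracle arithmetic (`oracle_paf_categorical()` uses explicit accumulation,
  `oracle_paf_continuous()` adaptive quadrature) so engine and truth share
  no code path. End-to-end recovery is exact ($10^{-10}$) on the categorical
  path and $10^{-6}$ on the quadrature path.

What passing synthetic tests do **not** show: robustness to survey
clustering and informative nonresponse, correlated exposures within
respondents, latency between exposure and cancer occurrence, or
transportability of relative risks across populations — all real-data
concerns outside the generator's statistical structure.

## Numerical and degenerate-input choices

* Printed prevalence rows can sum to 0.999 from 0.1-pp rounding;
  `read_prevalence_table()` accepts deviations up to 0.005 and renormalises,
  failing loudly beyond that.
* The distribution constructors enforce proportions summing to 1 within
  $10^{-9}$, positive sds, valid TMREL indices, and RR = 1 at the TMREL.
* Uncapped extreme per-unit risks can overflow the integrand;
  `paf_continuous()` fails with advice to set `cap_dose`.
* An empty PAF table aggregates to zero attributable everywhere; an empty
  site/sex stratum is an error.
* Test problem sizes — $10^4$ records for prevalence recovery, $10^6$
  Monte-Carlo draws, 512–2048 quadrature nodes — were chosen so each check
  runs in seconds while leaving its tolerance an order of magnitude of
  headroom.

## Limitations

Uncertainty intervals are deliberately absent (the reproduced analysis
reports none): PAFs, shares and counts are point estimates. Age structure is
ignored — inputs are aligned by sex only. The package attributes burden; it
does not model latency, intervention dynamics, or joint exposure change.
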