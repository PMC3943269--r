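---
title: "Models and methods behind recwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind recwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Recreational walking varies between residential neighborhoods: people living
in some areas walk for leisure far more than people living in others. Part of
that variation tracks measurable features of the environment — the education
level of the neighborhood, the presence and quality of green and open spaces,
the density of destinations within walking distance, nuisances such as living
under an airport flight path — and part of it is residual, either spatially
smooth (adjacent neighborhoods resembling each other) or unstructured.
`recwalk` implements the full analysis workflow for this question as applied
to a georeferenced adult cohort (the RECORD study of the Paris region: about
7,100 participants in about 660 census-tract neighborhoods, two walking
outcomes measured by questionnaire), and a synthetic-cohort generator that
reproduces the statistical structure of such data so every stage of the
workflow can be validated without access to the original cohort, which is not
public.

Two outcomes are analysed: reporting *any* recreational walking over the past
7 days (binary, prevalence around 69%), and the recreational walking time
spent *within one's own neighborhood*, coded as a 5-category ordinal variable
whose first category is exactly zero minutes and whose remaining categories
split the positive times into quartiles.

# The convolution (BYM) spatial-multilevel model

Both outcomes are modelled with two neighborhood-level random effects in the
same linear predictor:

* an exchangeable effect `u_j ~ Normal(0, sigma_u^2)` capturing unstructured
  between-neighborhood variation, and
* an intrinsic conditional-autoregressive (ICAR) effect `v_j` capturing
  spatially structured variation: conditionally,
  `v_j | v_{-j} ~ Normal(mean of neighbors, tau_v^2 / d_j)` with `d_j` the
  number of contiguity neighbors. The improper ICAR prior is identified by a
  sum-to-zero constraint, imposed by recentering at every MCMC sweep (the
  `car.normal` convention); the subtracted mean is absorbed into the
  intercept (binary model) or the cutpoints (ordinal model), so the
  likelihood is untouched and every saved draw satisfies `sum(v) = 0`.

The binary outcome uses `logit P(y=1) = x'beta + u_j + v_j`; the ordinal
outcome uses the proportional-odds cumulative logit
`logit P(y <= c) = kappa_c - (x'beta + u_j + v_j)` with four free ordered
cutpoints and no intercept.

**Priors.** The source analysis (fitted in WinBUGS) does not report its
priors, so these are the package's own declared choices: Normal(0, 10^2) on
coefficients and cutpoint anchors, half-Normal(0, 1) on `sigma_u` and
`tau_v`. All are configurable through `bym_priors()`; setting a scale to zero
removes that random effect, which gives the classical multilevel logistic
model as a special case (cross-checked against `lme4::glmer` in the test
suite).

**Sampler.** Estimation is adaptive random-walk Metropolis within Gibbs,
written in C++. The convolution pair is hierarchically centered: the total
neighborhood effect `b_j = u_j + v_j` faces the likelihood through
componentwise Metropolis updates with prior `N(v_j, sigma_u^2)`, and the ICAR
field `v_j` is then drawn from its exact Gaussian full conditional given `b`
(the likelihood is untouched), which sidesteps the notoriously slow mixing of
the non-centered convolution parametrization. Coefficients and cutpoints
(proposals violating the ordering are rejected) get componentwise random
walks, and the SD parameters get log-scale random walks plus *interweaving
rescale moves* that jointly scale the SD and its whole effect field in one
step — the prior density and transformation Jacobian cancel for the scaled
field, and these moves cross the funnel between "small SD" and "small
effects" that single-site updates cannot traverse. Proposal scales adapt
toward 0.44 acceptance in batches of 50 during burn-in only, so the
post-burn-in chain is a fixed-kernel Markov chain. Default settings are 2
chains of 6,000 iterations with 2,000 burn-in and thinning 2; all seeds
derive from one user seed, and identical seeds give bit-identical chains.
Correctness is tested against a brute-force grid-integration oracle on an
intercept-only instance (Kolmogorov–Smirnov distance below 0.02 on 10,000
thinned draws), and the exchangeable-only special case against
`lme4::glmer`.

**Convergence.** `check_convergence()` reports split-R-hat and an
autocorrelation-based effective sample size (initial-positive-sequence
truncation) per scalar parameter, with thresholds 1.1 and 100 by default.
With the standard pooled-variance formula, identical chains give
`sqrt((n-1)/n)` rather than exactly 1; the diagnostics are cross-checked
against `coda` in the tests.

# Interquartile odds ratios and the variance decomposition

Between-neighborhood variation is reported on the odds-ratio scale as
*interquartile odds ratios* (IqOR): the odds contrast between individuals in
the 25% of neighborhoods with the highest effects and the 25% with the
lowest. For a Normal effect with SD `sigma` the contrast between quartile
means is `2 k sigma` with `k = dnorm(qnorm(0.75)) / 0.25 ~= 1.27110`, so

```
IqOR = exp(2 * 1.27110 * sigma).
```

The published analyses cite this quantity without printing a formula; the
quartile-mean-contrast form above is the one place where `recwalk` picks a
convention, and it is validated against a 10-million-draw Monte-Carlo oracle
to 0.5%. Crucially, the *internal-consistency* quantities derived from IqOR
pairs are invariant to the constant `k`: squared log-IqORs add like
variances, so

```
iqor_total = exp(sqrt(ln^2(iqor_u) + ln^2(iqor_s)))
pct_structured = 100 * ln^2(iqor_s) / (ln^2(iqor_u) + ln^2(iqor_s))
```

hold whatever `k` is. `decompose()` applies this per MCMC iteration, using
the `sigma_u` draw for the unstructured SD and the *empirical*
across-neighborhood SD of the `v_j` draws for the structured SD — the ICAR
conditional SD `tau_v` is not the marginal spread of the field, so the
structured component must be measured empirically — and summarizes with
posterior medians and equal-tailed 95% credible intervals.

# The synthetic cohort generator

`generator_config()` defaults define the emulated study conditions, chosen
once from the published description of the cohort:

* 23 x 29 lattice (667 cells; the real 661 census tracts cannot form a
  rectangle), rook contiguity, 7,105 individuals allocated multinomially;
* covariate margins from the published sample description (65.6% men, age
  classes 35.5/41.7/22.9%, education, employment, occupation categories;
  incompletely printed margins renormalized);
* true effect sizes from the published final models (e.g. male OR 1.38,
  retired 1.68, air-traffic exposure 0.75, high density of destinations
  1.39). The published analysis prints separate coefficient sets for the two
  outcomes; the generator applies one shared map to both linear predictors —
  a deliberate simplification that keeps a single source of truth for
  recovery tests;
* the binary intercept is calibrated as
  `qlogis(0.69) - sum(beta * E[x])` so the marginal prevalence sits near the
  published 69% under the default covariate distribution;
* random-effect scales calibrated to the published age-sex-model IqORs:
  `sigma_u = ln(1.56) / (2 * 1.27110) ~= 0.175`, and `tau_v = 0.25` chosen so
  the ICAR field's mean marginal SD on the default lattice (0.91 at
  `tau_v = 1`, from the Laplacian pseudo-inverse) gives an empirical
  structured SD of `ln(1.77) / (2 * 1.27110) ~= 0.225`;
* ordinal cutpoints placing ~49% of individuals in category 1 (69% walk at
  all, 74% of walkers walk at least partly in their neighborhood) and
  splitting the rest evenly;
* environmental exposures as k-hop-averaged iid node noise (`k = 2` by
  default; the real exposures are strongly spatially autocorrelated but their
  generating process is unreported, so this smoothing is a modelling choice,
  as is the independence between exposure fields), quartiled over
  participants; air-traffic exposure binary at 20% of neighborhoods;
* daily regional weather for 2007–2008 (seasonal sinusoid temperature,
  gamma rainfall), averaged over the recruitment day plus the 7 previous
  days;
* 2.5% missing walking outcomes, missing at random given low education and
  low income (the published exclusion pattern).

One design point deserves emphasis: a participant who reports no recreational
walking at all necessarily reports zero neighborhood walking minutes, so by
default the generator forces ordinal category 1 whenever `walk_any = 0`
(`couple_outcomes = TRUE`). The marginal ordinal outcome is then a two-part
model rather than an exact proportional-odds model — much like real data.
Tests that check proportional-odds recovery switch this coupling off.

Hidden dot-prefixed columns (`.u`, `.v`, `.eta_bin`, `.eta_ord`) retain the
latent truth so downstream recovery is testable exactly.

**What passing tests do and do not show.** The generator emulates the
*statistical* structure the models assume (nested binary/ordinal outcomes,
convolution random effects, autocorrelated categorical exposures). It does
not emulate real Paris geography, street-network accessibility, residential
self-selection, reporting error in walking times, or correlation among the
25 real exposures. Recovery and discrimination results on synthetic data
therefore validate the estimation machinery, not the substantive published
findings, which would require the original cohort.

# Ecometrics

Neighborhood perceptions reported by residents (e.g. quality of green and
open spaces) are aggregated with a multilevel cumulative-logit model: survey
items nested in individuals nested in neighborhoods (`fit_ecometric_3level()`;
a 2-level variant serves single-item scales). Item intercepts are fixed
effects with the first item as reference, global cutpoints carry the response
scale, and the residual logistic scale fixes the latent metric. The exact
parametrization of the original ecometric models is not printed in the main
text, so this minimal 3-level ordinal specification is implemented and
documented as such. Estimation reuses the MCMC machinery of the outcome
models (no spatial term), and the neighborhood score is the posterior mean of
the neighborhood random intercept — shrunken toward zero where data are thin.
Scores are subsequently quartile-categorized like any other exposure.

Against same-source bias (the same respondents supplying both the aggregated
exposure and the outcome), `loo_scores()` recomputes each individual's
neighborhood score from the other residents' responses only. A full MCMC
refit per individual would be prohibitive, so the leave-one-out score uses an
empirical-Bayes linearization of the fitted model: each response is converted
to a conditional latent mean (truncated-logistic expectation given the fitted
cutpoints and item effects, using the closed form
`E[X | a < X < b] = [x F(x) + log(1 - F(x))]_a^b / (F(b) - F(a))`), individual
signals are averaged, and the neighborhood mean is re-shrunk with the fitted
variance components. The matching full-data empirical-Bayes score is returned
alongside so comparisons are like-with-like. Single-respondent neighborhoods
get a missing leave-one-out score.

# The five-step modelling pipeline

`run_pipeline()` reproduces the staged strategy: (1) age- and sex-adjusted
models to measure raw between-neighborhood variation; (2) joint screening of
individual and weather candidates, keeping those "independently associated"
with the outcome; (3) one-by-one pretests of each environmental variable on
top of the step-2 model; (4) progressive combination of flagged exposures
into one final model per outcome, dropping variables that lose association;
(5) weather-by-environment interaction scans. The decomposition is reported
at stages 1, 2 and 4, and choropleths of the posterior spatial effects are
exported before and after environmental adjustment.

Open choices the source leaves unstated, decided here and configurable:

* "independently associated" means a 95% interval excluding the null (the
  Bayesian analog of the conventional 5% test); the level is a config field;
* forward-combination order is descending `|estimate| / SE` from the
  pretest;
* screening, pretests and interactions use a fast approximate fitter by
  default — a ridge-penalized multilevel logistic (penalized IRLS with a
  PQL-style variance update) or a plain proportional-odds fit for the ordinal
  outcome — with Wald intervals; the stage models, final models and
  risk-score refits always use full MCMC. `screen_engine = "mcmc"` forces
  MCMC everywhere;
* no multiple-testing correction is applied at any stage, matching the
  source procedure.

# The environmental risk score

The per-individual risk score is the sum of products of the final model's
environmental coefficients (posterior medians) by the individual's exposure
values. Scores are divided into quartile categories, the final models are
re-estimated with the score categories replacing all environmental terms, and
the category odds ratios are bootstrapped: individuals are resampled with
replacement (a neighborhood block bootstrap is available since the original
clustering treatment is unreported), each replicate is refitted with the fast
approximate fitter — re-running full spatial MCMC 2,000 times would be
pointless for a percentile interval — and the median and 2.5th/97.5th
percentiles over replicates are reported. The headline (non-bootstrap)
category odds ratios come from the full MCMC refit. The published top-category
values (1.59 and 1.81) are properties of the real cohort and are not
reproduction targets for synthetic data.

# Numerical choices and degenerate inputs

* Quartile categorization is rank-based with average ranks; ties at a
  boundary go to the lower category, making the coding order-independent and
  invariant to monotone transforms. Learned cutoffs (the maxima of categories
  1–3) are stored and reproduce themselves exactly on the training data.
  Fewer than 4 distinct values is a degeneracy error, as is an all-zero
  walking-minutes vector or a two-valued risk score.
* Weather windows require all 8 calendar days (recruitment day plus 7
  previous); any missing day is an error rather than a silent partial mean.
* The ICAR field is sampled exactly in the Laplacian eigenbasis (null mode
  dropped), which is cheap at simulation scale and gives sum-to-zero by
  construction; disconnected graphs are rejected because the intrinsic prior
  is undefined across islands.
* Ordinal fits require at least 3 observed categories; unobserved categories
  produce a support warning since their cutpoints are only prior-identified.
* Cutpoint proposals violating the ordering are rejected outright, so every
  saved draw has strictly increasing cutpoints.

# Problem sizes used in the tests

The packaged checks run at desk scale, chosen to keep the full suite
comfortably under typical single-CPU budgets while leaving each check
informative: parameter-recovery replicates use 100 neighborhoods x 30
individuals (20 replicates); decomposition discrimination and the no-signal
check use 100 neighborhoods x 100 individuals, because at 30 per
neighborhood the u/v split is genuinely weakly identified (both components
can absorb the per-neighborhood estimation noise) and no sampler can sharpen
a posterior the data do not sharpen; ecometric recovery uses 60
neighborhoods x 20 individuals x 4 items; and the end-to-end pipeline
fixture a 12 x 12 lattice with 20 individuals per cell and reduced MCMC
settings. The defaults of `generator_config()` and
`mcmc_control()` remain at study scale.

# Known limitations

* The bootstrap refits omit the CAR term; intervals reflect sampling noise
  under the approximate model, not full posterior uncertainty.
* The approximate ordinal fitter has no neighborhood random intercept.
* The IqOR constant is a convention (see above); all internal-consistency
  results are invariant to it.
* One shared true-coefficient map drives both synthetic outcomes.
* The ecometric model fixes a minimal parametrization (no item
  discriminations, no differential item functioning).
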