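# recwalk

Multilevel-spatial analysis of neighborhood disparities in recreational
walking.

## The problem

Leisure walking varies between residential neighborhoods, and part of that
variation is spatially smooth: adjacent neighborhoods resemble each other.
Epidemiologists studying cohorts such as RECORD (Paris region; ~7,100 adults
in ~660 census tracts) want to know (i) how much between-neighborhood
variation in walking there is, (ii) how much of it is spatially structured
versus unstructured, (iii) which environmental characteristics — neighborhood
education, green and open spaces, density of destinations, air-traffic
exposure — explain it, and (iv) how large the overall disparity predicted by
the environment is. `recwalk` implements that entire workflow for a binary
outcome (any recreational walking) and a 5-category ordinal outcome
(neighborhood walking time, category 1 = zero minutes), together with a
synthetic-cohort generator that emulates the cohort's statistical structure
so everything is testable without the (non-public) original data.

## The models

Both outcomes get a convolution (Besag–York–Mollié) regression with two
neighborhood random effects in one linear predictor:

    logit P(y_i = 1)    = x_i' beta + u_j(i) + v_j(i)             (binary)
    logit P(y_i <= c)   = kappa_c - (x_i' beta + u_j(i) + v_j(i)) (ordinal)

with `u_j ~ N(0, sigma_u^2)` exchangeable and `v` an intrinsic CAR
(conditionally autoregressive) Gaussian Markov random field on the contiguity
graph, identified by a sum-to-zero constraint. Estimation is by
Metropolis-within-Gibbs MCMC (C++ core, hierarchically centered with
interweaving moves for the variance parameters).

Between-neighborhood spreads are reported as interquartile odds ratios,
`IqOR = exp(2 * 1.27110 * sigma)` — the odds contrast between the top and
bottom quartile of neighborhoods — and decomposed per MCMC iteration into an
unstructured component (`sigma_u`), a structured component (the empirical SD
of the CAR effects), their total, and the percentage of between-neighborhood
variance that is spatially structured. Squared log-IqORs add like variances:

    iqor_total     = exp(sqrt(ln^2 u + ln^2 s))
    pct_structured = 100 * ln^2 s / (ln^2 u + ln^2 s)

The package also provides ecometric scoring (multilevel ordinal models that
aggregate residents' survey answers into shrunken neighborhood scores, with a
leave-one-out variant against same-source bias), the five-step modelling
pipeline (age/sex models, individual+weather selection, one-by-one
environmental pretests, progressive combination, weather interactions), and
an environmental risk score with bootstrap percentile intervals.

## Worked example

```r
library(recwalk)

# a synthetic cohort: 6x6 lattice of neighborhoods, ~1,100 adults,
# a true male effect (OR 1.5) and convolution neighborhood effects
gen <- generate_cohort(generator_config(
  lattice_rows = 6, lattice_cols = 6, n_individuals = 1080,
  true_betas = list(male = log(1.5)),
  sigma_u = 0.25, tau_v = 0.4, missing_rate = 0, seed = 101
))

fit <- fit_bym_logistic(
  gen$cohort, walk_any ~ male, gen$graph,
  control = mcmc_control(n_chains = 2, n_iter = 3000, n_burnin = 1000, seed = 7)
)
tidy(fit, exponentiate = TRUE)
#> # A tibble: 4 x 7
#>   term        estimate std.error conf.low conf.high  rhat   ess
#> 1 (Intercept)    1.589     0.115   1.282      1.989  1.01  163.
#> 2 male           1.491     0.140   1.118      1.943  1.01  180.
#> 3 sigma_u        0.142     0.104   0.00807    0.390  1.03  156.
#> 4 tau_v          0.168     0.136   0.0154     0.504  1.10   23.4

decompose(fit)
#> Between-neighborhood variance decomposition (posterior median [95% CrI])
#>   iqor_unstructured    1.44 [ 1.02,  2.70]
#>   iqor_structured      1.38 [ 1.03,  2.47]
#>   iqor_total           1.82 [ 1.16,  2.99]
#>   pct_structured      41.81 [ 0.34, 99.82]
```

The `male` odds ratio (1.49, 95% CrI 1.12-1.94) recovers the generator truth
of 1.5; the outcome then carries two sources of between-neighborhood
variation whose split the decomposition quantifies, with wide intervals at
this small lattice — exactly the behaviour the credible intervals should
convey. The printed numbers are the actual output at these seeds.

Consistency arithmetic on reported IqOR components:

```r
combine_iqors(1.56, 1.77)
#> # A tibble: 1 x 2
#>   iqor_total pct_structured
#> 1       2.06           62.2
```

The full five-step pipeline runs from one config (see
`vignettes/recwalk-methods.Rmd` for the methods and
`inst/scripts/run_pipeline.R` for a shell entry point):

```r
report <- run_pipeline(pipeline_config(
  generator = generator_config(lattice_rows = 12, lattice_cols = 12,
                               n_per_neighborhood = 20, seed = 1),
  output_dir = "recwalk_run", seed = 1
))
```

which writes `report.md`, CSV tables, GeoJSON choropleths of the posterior
spatial effects before/after environmental adjustment, and a provenance
manifest.

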