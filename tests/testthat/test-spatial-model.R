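test_that("outcome coding is validated", {
  gen <- small_cohort()
  expect_error(
    fit_bym_logistic(gen$cohort, walk_time_nbhd_cat ~ male, gen$graph,
                     fast_ctrl()),
    class = "recwalk_error_invalid_argument"
  )
  co <- gen$cohort
  co$two_cat <- 1L + co$walk_any
  expect_error(
    fit_bym_ordinal(co, two_cat ~ male, gen$graph, fast_ctrl()),
    class = "recwalk_error_category_support"
  )
  co$neighborhood_id[1] <- 9999L
  expect_error(
    fit_bym_logistic(co, walk_any ~ male, gen$graph, fast_ctrl()),
    class = "recwalk_error_invalid_argument"
  )
})

test_that("posterior draws respect the structural invariants", {
  gen <- small_cohort()
  fit <- fit_bym_logistic(gen$cohort, walk_any ~ male, gen$graph, fast_ctrl())
  for (ch in fit$chains) {
    expect_true(all(abs(rowSums(ch$v)) < 1e-8))
    expect_true(all(ch$sigma_u > 0))
    expect_true(all(ch$tau_v > 0))
  }
  ofit <- fit_bym_ordinal(gen$cohort, walk_time_nbhd_cat ~ male, gen$graph,
                          fast_ctrl())
  for (ch in ofit$chains) {
    expect_true(all(abs(rowSums(ch$v)) < 1e-8))
    # cutpoints strictly increasing in every saved draw
    expect_true(all(apply(ch$kappa, 1L, function(k) all(diff(k) > 0))))
  }
})

test_that("fits are deterministic given the control seed", {
  gen <- small_cohort()
  f1 <- fit_bym_logistic(gen$cohort, walk_any ~ male, gen$graph, fast_ctrl(3))
  f2 <- fit_bym_logistic(gen$cohort, walk_any ~ male, gen$graph, fast_ctrl(3))
  expect_identical(f1$chains, f2$chains)
  f3 <- fit_bym_logistic(gen$cohort, walk_any ~ male, gen$graph, fast_ctrl(4))
  expect_false(identical(f1$chains[[1]]$beta, f3$chains[[1]]$beta))
})

test_that("relabeling neighborhoods with a matching graph permutation is a no-op", {
  gen <- small_cohort()
  co <- gen$cohort
  # bijective relabeling; row order unchanged
  ids <- gen$graph$node_ids
  perm <- setNames(rev(ids), ids)
  co2 <- co
  co2$neighborhood_id <- unname(perm[as.character(co$neighborhood_id)])
  g2 <- nbhd_graph(
    data.frame(from = unname(perm[as.character(gen$graph$edges$from)]),
               to = unname(perm[as.character(gen$graph$edges$to)])),
    node_ids = ids
  )
  f1 <- fit_bym_logistic(co, walk_any ~ male, gen$graph, fast_ctrl(5))
  f2 <- fit_bym_logistic(co2, walk_any ~ male, g2, fast_ctrl(5))
  expect_identical(f1$chains[[1]]$beta, f2$chains[[1]]$beta)
  expect_identical(f1$chains[[1]]$v, f2$chains[[1]]$v)
})

test_that("posterior credible intervals contract as the cohort grows", {
  cfg1 <- generator_config(lattice_rows = 6, lattice_cols = 6,
                           n_per_neighborhood = 15,
                           true_betas = list(male = log(1.4)),
                           sigma_u = 0.2, tau_v = 0.3, missing_rate = 0,
                           seed = 91)
  cfg2 <- generator_config(lattice_rows = 6, lattice_cols = 6,
                           n_per_neighborhood = 60,
                           true_betas = list(male = log(1.4)),
                           sigma_u = 0.2, tau_v = 0.3, missing_rate = 0,
                           seed = 91)
  w <- vapply(list(cfg1, cfg2), function(cfg) {
    gen <- generate_cohort(cfg)
    td <- tidy(fit_bym_logistic(gen$cohort, walk_any ~ male, gen$graph,
                                fast_ctrl(6)))
    diff(unlist(td[td$term == "male", c("conf.low", "conf.high")]))
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("exchangeable-only fit matches an independent multilevel logistic", {
  skip_if_not_installed("lme4")
  cfg <- generator_config(lattice_rows = 5, lattice_cols = 6,
                          n_per_neighborhood = 40,
                          true_betas = list(male = log(1.5)),
                          sigma_u = 0.4, tau_v = 0, missing_rate = 0,
                          seed = 93)
  gen <- generate_cohort(cfg)
  fit <- fit_bym_logistic(
    gen$cohort, walk_any ~ male, gen$graph,
    mcmc_control(n_chains = 2, n_iter = 3000, n_burnin = 1000, thin = 2,
                 seed = 8),
    priors = bym_priors(tau_v_scale = 0)
  )
  td <- tidy(fit)
  glfit <- lme4::glmer(walk_any ~ male + (1 | neighborhood_id),
                       data = gen$cohort, family = binomial())
  gl_beta <- lme4::fixef(glfit)[["male"]]
  gl_se <- sqrt(diag(as.matrix(lme4::vcov.merMod(glfit))))[2]
  expect_lt(abs(td$estimate[td$term == "male"] - gl_beta), 3 * gl_se)
  gl_sigma <- attr(lme4::VarCorr(glfit)$neighborhood_id, "stddev")
  expect_lt(abs(td$estimate[td$term == "sigma_u"] - gl_sigma), 0.15)
  # CAR component is switched off entirely
  expect_true(all(bym_pooled(fit, "v") == 0))
})

test_that("ordinal fit recovers generator truth at desk scale", {
  cfg <- generator_config(lattice_rows = 7, lattice_cols = 7,
                          n_per_neighborhood = 40,
                          true_betas = list(male = log(1.5)),
                          sigma_u = 0.2, tau_v = 0.3, missing_rate = 0,
                          couple_outcomes = FALSE, seed = 95)
  gen <- generate_cohort(cfg)
  fit <- fit_bym_ordinal(
    gen$cohort, walk_time_nbhd_cat ~ male, gen$graph,
    mcmc_control(n_chains = 2, n_iter = 2500, n_burnin = 1000, thin = 2,
                 seed = 10)
  )
  td <- tidy(fit)
  row <- td[td$term == "male", ]
  expect_gt(row$conf.high, log(1.5) - 0.25)
  expect_lt(row$conf.low, log(1.5) + 0.25)
  # cutpoint posterior means stay ordered and near the generator's values
  kap <- td$estimate[startsWith(td$term, "kappa_")]
  expect_true(all(diff(kap) > 0))
  expect_lt(max(abs(kap - cfg$ordinal_cutpoints)), 0.5)
})

test_that("an unobserved ordinal category triggers a support warning", {
  gen <- small_cohort()
  co <- gen$cohort
  # collapse category 4 into 3; category 4 keeps no observations but 5 remains
  co$walk_time_nbhd_cat[co$walk_time_nbhd_cat == 4L] <- 3L
  expect_warning(
    fit_bym_ordinal(co, walk_time_nbhd_cat ~ male, gen$graph, fast_ctrl(12)),
    "unobserved"
  )
})
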