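test_that("scores are coefficient-weighted sums of exposure values", {
  cohort <- data.frame(air_traffic = c(0, 1, 1, 0),
                       green_spaces = factor(c("Q1", "Q3", "Q2", "Q4"),
                                             levels = paste0("Q", 1:4)))
  s0 <- compute_scores(cohort, c(air_traffic = 0))
  expect_equal(s0, rep(0, 4))

  s1 <- compute_scores(cohort, c(air_traffic = log(0.75)))
  expect_equal(s1, c(0, log(0.75), log(0.75), 0), tolerance = 1e-12)
  expect_equal(s1[2], -0.2877, tolerance = 1e-4)

  s2 <- compute_scores(cohort, c(air_traffic = log(0.75),
                                 green_spacesQ3 = log(1.13),
                                 green_spacesQ4 = log(1.43)))
  expect_equal(s2[1], 0)
  expect_equal(s2[2], log(0.75) + log(1.13))

  expect_error(compute_scores(cohort, c(unknown_thing = 1)),
               class = "recwalk_error_contract")
  expect_error(compute_scores(cohort, setNames(1, "")),
               class = "recwalk_error_contract")
})

test_that("adding a constant to a covariate shifts scores affinely", {
  cohort <- data.frame(x = c(0.5, 1.2, -0.3))
  b <- 0.7
  s <- compute_scores(cohort, c(x = b))
  cohort2 <- data.frame(x = cohort$x + 2)
  s2 <- compute_scores(cohort2, c(x = b))
  expect_equal(s2, s + b * 2)
})

test_that("score categories delegate to quartiles and reject degenerate scores", {
  set.seed(1)
  s <- rnorm(400)
  cats <- score_categories(s)
  expect_lte(diff(range(table(cats))), 1)
  # monotone transform leaves categories unchanged
  expect_equal(as.integer(score_categories(exp(s))), as.integer(cats))
  expect_error(score_categories(rep(c(0, -0.29), 50)),
               class = "recwalk_error_degenerate_score")
})

test_that("bootstrap returns exact percentile structure", {
  gen <- small_cohort()
  co <- gen$cohort
  coefs <- c(green_spacesQ2 = 0.1, green_spacesQ3 = 0.3, green_spacesQ4 = 0.6,
             air_traffic = -0.29)
  cats <- score_categories(compute_scores(co, coefs))

  expect_error(bootstrap_ors(co, walk_any ~ male, cats, n_boot = 1),
               class = "recwalk_error_invalid_argument")

  res2 <- bootstrap_ors(co, walk_any ~ male, cats, n_boot = 2, seed = 3)
  reps <- attr(res2, "replicates")
  expect_equal(dim(reps), c(2L, 3L))
  # with two replicates the median is their midpoint
  for (cat in paste0("Q", 2:4)) {
    expect_equal(res2$or[res2$category == cat], mean(reps[, cat]))
  }
  # reference category and interval-contains-median invariants
  expect_equal(unlist(res2[res2$category == "Q1", c("or", "conf.low", "conf.high")]),
               c(or = 1, conf.low = 1, conf.high = 1))
  expect_true(all(res2$conf.low <= res2$or & res2$or <= res2$conf.high))
})

test_that("bootstrap is deterministic and supports the block variant", {
  gen <- small_cohort()
  co <- gen$cohort
  coefs <- c(green_spacesQ2 = 0.1, green_spacesQ3 = 0.3, green_spacesQ4 = 0.6)
  cats <- score_categories(compute_scores(co, coefs))
  a <- bootstrap_ors(co, walk_any ~ male, cats, n_boot = 25, seed = 5)
  b <- bootstrap_ors(co, walk_any ~ male, cats, n_boot = 25, seed = 5)
  expect_identical(attr(a, "replicates"), attr(b, "replicates"))
  expect_true(all(a$conf.low <= a$or & a$or <= a$conf.high))

  nb <- bootstrap_ors(co, walk_any ~ male, cats, n_boot = 10, seed = 5,
                      method = "neighborhood")
  expect_equal(nrow(attr(nb, "replicates")), 10L)
})

test_that("bootstrap interval width shrinks with cohort size", {
  cfg_small <- generator_config(lattice_rows = 6, lattice_cols = 6,
                                n_per_neighborhood = 15,
                                true_betas = list(density_destinations =
                                                    log(c(1.2, 1.5, 2.0))),
                                sigma_u = 0.1, tau_v = 0.1, missing_rate = 0,
                                seed = 15)
  cfg_big <- cfg_small
  cfg_big$n_per_neighborhood <- 60L
  widths <- vapply(list(cfg_small, cfg_big), function(cfg) {
    gen <- generate_cohort(cfg)
    coefs <- c(density_destinationsQ2 = log(1.2),
               density_destinationsQ3 = log(1.5),
               density_destinationsQ4 = log(2.0))
    cats <- score_categories(compute_scores(gen$cohort, coefs))
    res <- bootstrap_ors(gen$cohort, walk_any ~ male, cats, n_boot = 60,
                         seed = 6)
    r4 <- res[res$category == "Q4", ]
    log(r4$conf.high) - log(r4$conf.low)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("refitting with score categories recovers a positive gradient", {
  cfg <- generator_config(lattice_rows = 6, lattice_cols = 6,
                          n_per_neighborhood = 30,
                          true_betas = list(density_destinations =
                                              log(c(1.3, 1.8, 2.5))),
                          sigma_u = 0.1, tau_v = 0.1, missing_rate = 0,
                          seed = 16)
  gen <- generate_cohort(cfg)
  coefs <- c(density_destinationsQ2 = log(1.3),
             density_destinationsQ3 = log(1.8),
             density_destinationsQ4 = log(2.5))
  cats <- score_categories(compute_scores(gen$cohort, coefs))
  rs <- refit_with_score(gen$cohort, walk_any ~ male, gen$graph, cats,
                         fast_ctrl(9))
  expect_equal(rs$or$category, paste0("Q", 1:4))
  expect_equal(rs$or$or[1], 1)
  # strong injected gradient: top category clearly above the reference
  expect_gt(rs$or$or[4], 1)
  expect_gt(rs$or$or[4], rs$or$or[2])
})
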