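test_that("generation is deterministic given the config seed", {
  cfg <- generator_config(lattice_rows = 4, lattice_cols = 5,
                          n_individuals = 300, seed = 11)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$node_fields, g2$node_fields)
})

test_that("null model hits the target prevalence at the study size", {
  cfg <- generator_config(true_betas = list(), sigma_u = 0, tau_v = 0,
                          intercept = qlogis(0.69), missing_rate = 0,
                          seed = 21)
  gen <- generate_cohort(cfg)
  n <- nrow(gen$cohort)
  expect_equal(n, 7105L)
  se <- sqrt(0.69 * 0.31 / n)
  expect_lt(abs(mean(gen$cohort$walk_any) - 0.69), 3 * se)
})

test_that("no random effects means binomial-only between-neighborhood noise", {
  cfg <- generator_config(lattice_rows = 10, lattice_cols = 10,
                          n_per_neighborhood = 40, true_betas = list(),
                          sigma_u = 0, tau_v = 0, intercept = qlogis(0.69),
                          missing_rate = 0, seed = 31)
  gen <- generate_cohort(cfg)
  y <- gen$cohort$walk_any
  j <- gen$cohort$neighborhood_id
  means <- tapply(y, j, mean)
  p <- mean(y)
  # one-way ANOVA ICC estimate should sit near zero
  ms_b <- 40 * var(means)
  ms_w <- p * (1 - p)
  icc <- (ms_b - ms_w) / (ms_b + (40 - 1) * ms_w)
  expect_lt(abs(icc), 0.02)
  expect_equal(as.numeric(tapply(gen$cohort$.u, j, sd)), rep(0, 100))
})

test_that("a logistic refit recovers the air-traffic effect at large n", {
  cfg <- generator_config(true_betas = list(air_traffic = log(0.75)),
                          sigma_u = 0, tau_v = 0, intercept = qlogis(0.69),
                          n_individuals = 50000, missing_rate = 0, seed = 41)
  gen <- generate_cohort(cfg)
  fit <- glm(walk_any ~ air_traffic, data = gen$cohort, family = binomial())
  est <- coef(fit)[["air_traffic"]]
  se <- sqrt(diag(vcov(fit)))[["air_traffic"]]
  expect_lt(abs(est - log(0.75)), 2 * se)
})

test_that("prevalence responds monotonically to the intercept", {
  prev <- vapply(c(-1, 0, 1), function(b0) {
    cfg <- generator_config(lattice_rows = 6, lattice_cols = 6,
                            n_individuals = 2000, true_betas = list(),
                            sigma_u = 0, tau_v = 0, intercept = b0,
                            missing_rate = 0, seed = 51)
    mean(generate_cohort(cfg)$cohort$walk_any)
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("invalid configs are rejected with config errors", {
  expect_error(generator_config(true_betas = list(not_a_var = 1)),
               class = "recwalk_error_config")
  expect_error(generator_config(true_betas = list(age_class = log(1.5))),
               class = "recwalk_error_config")
  expect_error(generator_config(ordinal_cutpoints = c(1, 1, 2, 3)),
               class = "recwalk_error_invalid_argument")
  expect_error(generator_config(sigma_u = -1),
               class = "recwalk_error_invalid_argument")
  expect_error(
    generate_cohort(generator_config(lattice_rows = 10, lattice_cols = 10,
                                     n_individuals = 50)),
    class = "recwalk_error_config"
  )
})

test_that("cohort structure satisfies its invariants", {
  gen <- small_cohort()
  co <- gen$cohort
  expect_true(all(co$neighborhood_id %in% gen$graph$node_ids))
  expect_true(all(co$walk_time_nbhd_cat %in% 1:5))
  # non-walkers report zero neighborhood walking, hence category 1
  expect_true(all(co$walk_time_nbhd_cat[co$walk_any == 0] == 1L))
  expect_true(all(levels(co$nbhd_education) == paste0("Q", 1:4)))
  expect_true(all(co$air_traffic %in% 0:1))
  # weather quartiles are near-balanced (ties: shared recruitment dates)
  expect_lt(diff(range(table(co$temp_mean_cat))) / nrow(co), 0.05)
})

test_that("decoupled ordinal outcome is proportional-odds across thresholds", {
  cfg <- generator_config(lattice_rows = 5, lattice_cols = 5,
                          n_individuals = 30000,
                          true_betas = list(male = log(1.6)),
                          sigma_u = 0, tau_v = 0, missing_rate = 0,
                          couple_outcomes = FALSE, seed = 61)
  co <- generate_cohort(cfg)$cohort
  # per-threshold binary logits should agree on the male effect
  betas <- vapply(1:4, function(c) {
    coef(glm(I(walk_time_nbhd_cat > c) ~ male, data = co,
             family = binomial()))[["male"]]
  }, numeric(1))
  expect_lt(diff(range(betas)), 0.1)
})

test_that("exposure fields are spatially autocorrelated", {
  skip_if_not_installed("ape")
  gen <- small_cohort()
  W <- adjacency_matrix(gen$graph)
  mi <- ape::Moran.I(gen$node_fields$field_green_spaces, W)
  expect_gt(mi$observed, 0.2)
})

test_that("missingness is MAR toward low education and income", {
  cfg <- generator_config(missing_rate = 0.05, seed = 71)
  co <- generate_cohort(cfg)$cohort
  expect_true(any(co$walk_missing))
  expect_true(all(is.na(co$walk_any[co$walk_missing])))
  low <- co$education %in% c("none", "primary_lower_secondary")
  expect_gt(mean(co$walk_missing[low]), mean(co$walk_missing[!low]))
})

test_that("item responses are deterministic and track the latent field", {
  fx <- item_fixture()
  again <- generate_item_responses(
    fx$cohort, setNames(fx$truth, seq_along(fx$truth)), fx$item_model,
    seed = 6
  )
  expect_identical(fx$items, again)

  # strong latent contrast orders the mean responses
  cohort2 <- tibble::tibble(individual_id = 1:40,
                            neighborhood_id = rep(1:2, each = 20))
  items2 <- generate_item_responses(cohort2, c("1" = -2, "2" = 2),
                                    default_item_model(), seed = 9)
  m <- tapply(items2$response, items2$neighborhood_id, mean)
  expect_gt(m[["2"]], m[["1"]])

  im <- default_item_model()
  im$item_intercepts <- numeric(0)
  expect_error(generate_item_responses(cohort2, c("1" = 0, "2" = 0), im),
               class = "recwalk_error_invalid_argument")
})

test_that("cohort tables and configs round-trip through text formats", {
  gen <- generate_cohort(generator_config(lattice_rows = 3, lattice_cols = 3,
                                          n_individuals = 60, seed = 81))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(gen, path)
  back <- read_cohort_csv(path)
  expect_equal(back$walk_any, gen$cohort$walk_any)
  expect_equal(as.character(back$education), as.character(gen$cohort$education))
  expect_s3_class(back$nbhd_education, "factor")

  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(gen$config, cfg_path)
  cfg2 <- read_generator_config(cfg_path)
  expect_equal(cfg2$true_betas, gen$config$true_betas, tolerance = 1e-12)
  expect_equal(generate_cohort(cfg2)$cohort, gen$cohort, tolerance = 1e-12)
})
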