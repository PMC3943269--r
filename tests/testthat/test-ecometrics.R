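ec_ctrl <- function(seed = 2) {
  mcmc_control(n_chains = 2, n_iter = 1500, n_burnin = 600, thin = 2,
               seed = seed)
}

test_that("input contracts are enforced", {
  fx <- item_fixture()
  one_item <- fx$items[fx$items$item_id == 1, ]
  expect_error(fit_ecometric_3level(one_item),
               class = "recwalk_error_invalid_argument")
  expect_error(fit_ecometric_2level(fx$items),
               class = "recwalk_error_use_3_level")
  expect_error(fit_ecometric_2level(fx$items[0, ]),
               class = "recwalk_error_invalid_argument")
  single_nb <- fx$items[fx$items$neighborhood_id == 1, ]
  expect_error(fit_ecometric_3level(single_nb),
               class = "recwalk_error_identifiability")
  dup <- rbind(fx$items, fx$items[1, ])
  expect_error(fit_ecometric_3level(dup),
               class = "recwalk_error_invalid_argument")
})

test_that("3-level scores recover a strong neighborhood signal", {
  fx <- item_fixture(n_nbhd = 15, n_per = 10, latent_sd = 1, seed = 7)
  sc <- fit_ecometric_3level(fx$items, ec_ctrl())
  expect_equal(nrow(sc), 15L)
  expect_gt(cor(sc$score, fx$truth), 0.7)
  expect_gt(attr(sc, "var_neighborhood"), 0)
})

test_that("zero neighborhood signal shrinks scores toward zero", {
  fx <- item_fixture(n_nbhd = 12, n_per = 10, latent_sd = 0, seed = 8)
  sc <- fit_ecometric_3level(fx$items, ec_ctrl())
  expect_lt(attr(sc, "var_neighborhood"), attr(sc, "var_individual"))
  expect_lt(max(abs(sc$score)), 0.5)
})

test_that("2-level single-item scores order two contrasted neighborhoods", {
  cohort <- tibble::tibble(individual_id = 1:60,
                           neighborhood_id = rep(1:2, each = 30))
  im <- default_item_model()
  im$item_intercepts <- 0
  items <- generate_item_responses(cohort, c("1" = -1.5, "2" = 1.5), im,
                                   seed = 3)
  sc <- fit_ecometric_2level(items, ec_ctrl())
  expect_equal(nrow(sc), 2L)
  expect_gt(sc$score[sc$neighborhood_id == 2], sc$score[sc$neighborhood_id == 1])
})

test_that("relabeling individuals within neighborhoods leaves scores unchanged", {
  fx <- item_fixture(seed = 9)
  items2 <- fx$items
  # bijective relabeling that preserves row order
  items2$individual_id <- items2$individual_id + 10000L
  sc1 <- fit_ecometric_3level(fx$items, ec_ctrl(5))
  sc2 <- fit_ecometric_3level(items2, ec_ctrl(5))
  expect_identical(sc1$score, sc2$score)
})

test_that("relabeling items changes scores only within Monte Carlo error", {
  fx <- item_fixture(n_nbhd = 10, n_per = 12, latent_sd = 1, seed = 10)
  items2 <- fx$items
  items2$item_id <- c(2L, 1L, 3L)[items2$item_id] # swap items 1 and 2
  sc1 <- fit_ecometric_3level(fx$items, ec_ctrl(6))
  sc2 <- fit_ecometric_3level(items2, ec_ctrl(6))
  expect_gt(cor(sc1$score, sc2$score), 0.95)
  expect_lt(max(abs(sc1$score - sc2$score)), 3 * max(sc1$score_se, sc2$score_se))
})

test_that("leave-one-out scores satisfy their contracts", {
  fx <- item_fixture(n_nbhd = 8, n_per = 10, latent_sd = 1, seed = 11)
  # add one neighborhood with a single respondent and one individual with no
  # responses
  extra_items <- tibble::tibble(neighborhood_id = 99L, individual_id = 9001L,
                                item_id = 1:3, response = c(2L, 3L, 2L))
  items <- rbind(fx$items, extra_items)
  cohort <- rbind(fx$cohort,
                  tibble::tibble(individual_id = 9001L, neighborhood_id = 99L),
                  tibble::tibble(individual_id = 9002L, neighborhood_id = 1L))
  sc <- fit_ecometric_3level(items, ec_ctrl(7))
  ls <- loo_scores(sc, items, cohort)

  # single-respondent neighborhood: flagged missing
  expect_true(is.na(ls$score_loo[ls$individual_id == 9001]))
  # individual with no responses: loo equals the full empirical-Bayes score
  r <- ls[ls$individual_id == 9002, ]
  expect_equal(r$score_loo, r$score_full_eb)
  # everyone else: finite and shrunken
  rest <- ls[!ls$individual_id %in% c(9001, 9002), ]
  expect_true(all(is.finite(rest$score_loo)))
})

test_that("loo scores approach full scores as respondent counts grow", {
  set.seed(12)
  truth <- c(0.8, -0.8)
  cohort <- tibble::tibble(
    individual_id = 1:65,
    neighborhood_id = rep(c(1L, 2L), c(5, 60))
  )
  items <- generate_item_responses(cohort, setNames(truth, 1:2),
                                   default_item_model(), seed = 13)
  sc <- fit_ecometric_3level(items, ec_ctrl(8))
  ls <- loo_scores(sc, items, cohort)
  gap <- tapply(abs(ls$score_loo - ls$score_full_eb), ls$neighborhood_id, mean)
  expect_lt(gap[["2"]], gap[["1"]])
})
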