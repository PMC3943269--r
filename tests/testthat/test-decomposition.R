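test_that("sd_to_iqor matches its closed form and is monotone", {
  expect_equal(sd_to_iqor(0), 1)
  # frozen value from the quartile-contrast Monte-Carlo oracle at sigma = 0.3
  expect_equal(sd_to_iqor(0.3), 2.1440, tolerance = 1e-4)
  sig <- seq(0, 1, by = 0.1)
  expect_true(all(diff(sd_to_iqor(sig)) > 0))
  expect_error(sd_to_iqor(-0.1), class = "recwalk_error_invalid_argument")
})

test_that("empirical structured SD is the across-neighborhood sample SD", {
  expect_equal(empirical_structured_sd(c(-1, 1)), sqrt(2))
  expect_equal(empirical_structured_sd(rep(0, 10)), 0)
  m <- rbind(c(-1, 1), c(0, 0), c(2, 4))
  expect_equal(empirical_structured_sd(m), c(sqrt(2), 0, sqrt(2)))
  expect_error(empirical_structured_sd(matrix(1, 3, 1)),
               class = "recwalk_error_invalid_argument")
})

test_that("combine_iqors adds squared log components and is symmetric", {
  res <- combine_iqors(1.56, 1.77)
  expect_equal(res$iqor_total, 2.062, tolerance = 1e-3)
  expect_equal(res$pct_structured, 62.24, tolerance = 1e-2)

  expect_equal(combine_iqors(1, 1.5), tibble::tibble(iqor_total = 1.5,
                                                     pct_structured = 100))
  expect_equal(combine_iqors(1.5, 1)$iqor_total, 1.5)
  expect_equal(combine_iqors(1.5, 1)$pct_structured, 0)

  a <- combine_iqors(1.3, 1.9)$iqor_total
  b <- combine_iqors(1.9, 1.3)$iqor_total
  expect_equal(a, b)

  expect_error(combine_iqors(0.9, 1.5), class = "recwalk_error_invalid_argument")
})

test_that("published IqOR components reproduce published totals and percentages", {
  ref <- record_iqor_components()
  res <- combine_iqors(ref$iqor_unstructured, ref$iqor_structured)
  # published values are rounded to 2 decimals / whole percent
  expect_true(all(abs(res$iqor_total - ref$iqor_total_published) < 0.02))
  expect_true(all(abs(res$pct_structured - ref$pct_structured_published) < 1))
})

test_that("decompose summarizes per-iteration components correctly", {
  # constructed draws: iteration-level identity ln^2 total = ln^2 u + ln^2 s
  set.seed(10)
  draws <- list(
    sigma_u = abs(rnorm(200, 0.3, 0.05)),
    v = matrix(rnorm(200 * 30, 0, 0.4), 200, 30)
  )
  d <- decompose(draws)
  expect_setequal(d$component, c("iqor_unstructured", "iqor_structured",
                                 "iqor_total", "pct_structured"))
  s_u <- draws$sigma_u
  s_v <- apply(draws$v, 1, sd)
  tot <- sd_to_iqor(sqrt(s_u^2 + s_v^2))
  expect_equal(d$estimate[d$component == "iqor_total"], median(tot))
  lhs <- log(sd_to_iqor(sqrt(s_u^2 + s_v^2)))^2
  rhs <- log(sd_to_iqor(s_u))^2 + log(sd_to_iqor(s_v))^2
  expect_equal(lhs, rhs, tolerance = 1e-10)
  pct <- d[d$component == "pct_structured", ]
  expect_true(pct$conf.low >= 0 && pct$conf.high <= 100)
})

test_that("decompose handles the no-structure limit and contract errors", {
  draws <- list(sigma_u = rep(0.3, 50), v = matrix(0, 50, 20))
  d <- decompose(draws)
  expect_equal(d$estimate[d$component == "iqor_structured"], 1)
  pct <- d[d$component == "pct_structured", ]
  expect_equal(c(pct$conf.low, pct$conf.high), c(0, 0))

  expect_error(decompose(list(sigma_u = 1:10)), class = "recwalk_error_contract")
  expect_error(decompose(list(v = matrix(0, 5, 3))), class = "recwalk_error_contract")
  expect_error(decompose(list(sigma_u = 1:5, v = matrix(0, 4, 3))),
               class = "recwalk_error_contract")
})
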