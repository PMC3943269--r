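test_that("quartile categorization follows the rank rule", {
  q <- quartile_categorize(1:8)
  expect_equal(as.integer(q), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_s3_class(quartile_coding(q), "quartile_coding")

  # near-equal category sizes for continuous data
  set.seed(1)
  x <- runif(7105)
  q2 <- quartile_categorize(x)
  expect_lte(diff(range(table(q2))), 1)

  # ties at a boundary share a category and go to the lower one
  q3 <- quartile_categorize(c(1, 2, 2, 3, 4, 5, 6, 7))
  expect_equal(as.integer(q3), c(1, 1, 1, 2, 3, 3, 4, 4))
})

test_that("quartile categorization rejects degenerate inputs", {
  expect_error(quartile_categorize(rep(3, 10)),
               class = "recwalk_error_degenerate_variable")
  expect_error(quartile_categorize(c(1, 2, 2, 1)),
               class = "recwalk_error_degenerate_variable")
  expect_error(quartile_categorize(c(1, NA, 2, 3, 4)),
               class = "recwalk_error_invalid_argument")
})

test_that("quartile categories are invariant to monotone transforms", {
  set.seed(2)
  x <- rnorm(501)
  expect_equal(as.integer(quartile_categorize(x)),
               as.integer(quartile_categorize(exp(x))))
  expect_equal(as.integer(quartile_categorize(x)),
               as.integer(quartile_categorize(rank(x))))
})

test_that("a stored coding reproduces itself on the training data", {
  set.seed(3)
  x <- rgamma(200, 2)
  q <- quartile_categorize(x)
  reapplied <- apply_quartile_coding(x, quartile_coding(q))
  expect_equal(as.integer(reapplied), as.integer(q))
  expect_identical(quartile_coding(reapplied)$cutoffs, quartile_coding(q)$cutoffs)
})

test_that("ordinal walking coding maps zero to category 1 and quartiles the rest", {
  expect_equal(code_ordinal_walking(c(0, 0, 10, 20, 30, 40)),
               c(1L, 1L, 2L, 3L, 4L, 5L))
  # category 1 if and only if zero minutes
  set.seed(4)
  m <- ifelse(runif(400) < 0.4, 0, rexp(400, 1 / 60))
  cats <- code_ordinal_walking(m)
  expect_identical(cats == 1L, m == 0)
  expect_true(all(cats %in% 1:5))
})

test_that("ordinal walking coding rejects invalid input", {
  expect_error(code_ordinal_walking(c(-1, 5, 10, 15, 20)),
               class = "recwalk_error_invalid_argument")
  expect_error(code_ordinal_walking(rep(0, 10)),
               class = "recwalk_error_degenerate_outcome")
  expect_error(code_ordinal_walking(c(0, 5, 5, 5, 5)),
               class = "recwalk_error_degenerate_outcome")
})

test_that("weather windows average the recruitment day plus 7 previous days", {
  daily <- tibble::tibble(date = as.Date("2007-03-01") + 0:20, value = 5)
  expect_equal(weather_window_average(daily, as.Date("2007-03-10")), 5)

  daily$value <- seq_along(daily$date)
  # window 2007-03-01..03-08 holds values 1..8
  expect_equal(weather_window_average(daily, as.Date("2007-03-08")), 4.5)

  # vectorized over recruitment dates
  expect_equal(
    weather_window_average(daily, as.Date(c("2007-03-08", "2007-03-09"))),
    c(4.5, 5.5)
  )
})

test_that("a missing day in the weather window is an error", {
  daily <- tibble::tibble(date = as.Date("2007-03-01") + c(0:3, 5:10),
                          value = 1)
  expect_error(weather_window_average(daily, as.Date("2007-03-08")),
               class = "recwalk_error_missing_weather")
  expect_error(weather_window_average(daily[0, ], as.Date("2007-03-08")),
               class = "recwalk_error_missing_weather")
})
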