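#' Environmental risk score for recreational walking
#'
#' The risk score of an individual is the sum of products of the final
#' model's environmental coefficients (posterior medians, log odds-ratio
#' scale) by the individual's exposure values; higher scores mean a more
#' walking-supportive environment.
#'
#' @param cohort cohort data frame containing the exposure variables.
#' @param env_coefs named numeric vector of log odds ratios. Names follow
#'   model-matrix conventions (e.g. `air_traffic` for a binary exposure,
#'   `green_spacesQ3` for level `Q3` of factor `green_spaces`).
#' @param env_vars character vector of the exposure variable names; inferred
#'   from `env_coefs` names when omitted.
#' @return numeric score vector, one value per row of `cohort`.
#' @examples
#' cohort <- data.frame(air_traffic = c(0, 1))
#' compute_scores(cohort, c(air_traffic = log(0.75)))
#' @export
compute_scores <- function(cohort, env_coefs, env_vars = NULL) {
  cohort <- as.data.frame(cohort)
  if (length(env_coefs) == 0L) {
    abort_recwalk("`env_coefs` is empty.", "contract")
  }
  if (is.null(names(env_coefs)) || any(!nzchar(names(env_coefs)))) {
    abort_recwalk("`env_coefs` must be a named vector.", "contract")
  }
  if (is.null(env_vars)) {
    env_vars <- infer_coef_variables(names(env_coefs), names(cohort))
  }
  missing_vars <- setdiff(env_vars, names(cohort))
  if (length(missing_vars)) {
    abort_recwalk(
      sprintf("exposure variables not found in cohort: %s",
              paste(missing_vars, collapse = ", ")),
      "contract"
    )
  }
  mm <- stats::model.matrix(stats::reformulate(env_vars), data = cohort)
  unknown <- setdiff(names(env_coefs), colnames(mm))
  if (length(unknown)) {
    abort_recwalk(
      sprintf("coefficients do not match any model column: %s",
              paste(unknown, collapse = ", ")),
      "contract"
    )
  }
  as.numeric(mm[, names(env_coefs), drop = FALSE] %*% env_coefs)
}

# map model-matrix coefficient names back to cohort variable names
infer_coef_variables <- function(coef_names, columns) {
  out <- character(0)
  for (nm in coef_names) {
    hits <- columns[nm == columns | startsWith(nm, columns)]
    if (!length(hits)) {
      abort_recwalk(
        sprintf("cannot match coefficient `%s` to a cohort variable.", nm),
        "contract"
      )
    }
    out <- c(out, hits[which.max(nchar(hits))])
  }
  unique(out)
}

# posterior-median log-ORs of the environmental terms of a fitted model
extract_env_coefs <- function(fit, env_vars) {
  stopifnot(inherits(fit, "bym_fit"))
  beta <- bym_pooled(fit, "beta")
  cols <- unlist(fit$term_assign[intersect(names(fit$term_assign), env_vars)])
  if (is.null(cols) || !length(cols)) return(setNames(numeric(0), character(0)))
  apply(beta[, cols, drop = FALSE], 2L, stats::median)
}

#' Quartile categories of the risk score
#'
#' Divides the risk score into 4 categories based on its quartiles (category
#' 1 = least walking-supportive environments), via [quartile_categorize()].
#'
#' @param scores numeric risk-score vector with at least 4 distinct values.
#' @return integer categories 1-4 with the quartile coding attached.
#' @export
score_categories <- function(scores) {
  tryCatch(
    quartile_categorize(scores),
    recwalk_error_degenerate_variable = function(e) {
      abort_recwalk(
        paste(
          "risk score takes fewer than 4 distinct values (e.g. a single",
          "binary exposure); quartile categories are undefined."
        ),
        "degenerate_score"
      )
    }
  )
}

#' Refit the outcome model with risk-score categories
#'
#' Re-estimates the final convolution model after replacing all environmental
#' variables by the risk-score quartile categories, and returns the
#' exponentiated category coefficients (odds of walking in categories 2-4
#' versus the least supportive quartile).
#'
#' @param cohort cohort data frame.
#' @param formula model formula WITHOUT environmental terms (outcome,
#'   individual and weather adjusters); the score-category term is added.
#' @param graph a [nbhd_graph()].
#' @param categories integer vector from [score_categories()], aligned with
#'   `cohort` rows.
#' @param control an [mcmc_control()].
#' @param priors a [bym_priors()].
#' @return list with elements `fit` (the `bym_fit`) and `or` (tibble of
#'   category odds ratios with 95% credible intervals; category 1 is the
#'   reference with OR 1).
#' @export
refit_with_score <- function(cohort, formula, graph, categories,
                             control = mcmc_control(),
                             priors = bym_priors()) {
  cohort <- as.data.frame(cohort)
  cohort$risk_score_cat <- factor(paste0("Q", as.integer(categories)),
                                  levels = paste0("Q", 1:4))
  f2 <- stats::update.formula(formula, . ~ . + risk_score_cat)
  outcome <- all.vars(formula)[1]
  ordinal <- length(unique(stats::na.omit(cohort[[outcome]]))) > 2L
  fit <- if (ordinal) {
    fit_bym_ordinal(cohort, f2, graph, control, priors)
  } else {
    fit_bym_logistic(cohort, f2, graph, control, priors)
  }
  beta <- bym_pooled(fit, "beta")
  cols <- grep("^risk_score_cat", colnames(beta), value = TRUE)
  qs <- t(apply(beta[, cols, drop = FALSE], 2L,
                stats::quantile, probs = c(0.5, 0.025, 0.975), names = FALSE))
  or <- tibble::tibble(
    category = paste0("Q", 1:4),
    or = unname(c(1, exp(qs[, 1]))),
    conf.low = unname(c(1, exp(qs[, 2]))),
    conf.high = unname(c(1, exp(qs[, 3])))
  )
  list(fit = fit, or = or)
}

#' Bootstrap percentile intervals for the risk-score odds ratios
#'
#' Resamples the cohort with replacement (individuals by default, whole
#' neighborhoods optionally), refits the score-category model on each
#' replicate with the fast approximate fitter (penalized multilevel logistic
#' without the CAR term, or proportional-odds for the ordinal outcome), and
#' reports the median and the 2.5th/97.5th percentiles of each category's
#' odds ratio over replicates.
#'
#' @inheritParams refit_with_score
#' @param n_boot number of bootstrap replicates (the reference analysis used
#'   2000).
#' @param seed integer seed.
#' @param method `"individual"` (resample rows) or `"neighborhood"`
#'   (resample whole neighborhoods, block bootstrap).
#' @return a `risk_score_result` tibble: one row per category with `or`
#'   (replicate median; 1 for the reference category), `conf.low`,
#'   `conf.high`, `n_boot`; replicate draws in attribute `"replicates"`.
#' @export
bootstrap_ors <- function(cohort, formula, categories, n_boot = 2000L,
                          seed = 1L, method = c("individual", "neighborhood")) {
  method <- match.arg(method)
  if (n_boot < 2L) {
    abort_recwalk("`n_boot` must be at least 2.", "invalid_argument")
  }
  cohort <- as.data.frame(cohort)
  cohort$risk_score_cat <- factor(paste0("Q", as.integer(categories)),
                                  levels = paste0("Q", 1:4))
  f2 <- stats::update.formula(formula, . ~ . + risk_score_cat)
  outcome <- all.vars(formula)[1]
  outcome_type <- if (length(unique(stats::na.omit(cohort[[outcome]]))) > 2L) {
    "ordinal"
  } else {
    "binary"
  }

  one_rep <- function(df) {
    tab <- tryCatch(
      approx_fit(df, f2, outcome_type = outcome_type),
      error = function(e) NULL
    )
    if (is.null(tab)) return(rep(NA_real_, 3L))
    rows <- match(paste0("risk_score_catQ", 2:4), tab$term)
    exp(tab$estimate[rows])
  }

  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      df <- if (method == "individual") {
        cohort[sample.int(nrow(cohort), replace = TRUE), ]
      } else {
        nb <- unique(cohort$neighborhood_id)
        take <- sample(nb, length(nb), replace = TRUE)
        dplyr::bind_rows(lapply(take, function(j) cohort[cohort$neighborhood_id == j, ]))
      }
      one_rep(df)
    }, numeric(3L))
  })
  reps <- t(reps) # n_boot x 3
  colnames(reps) <- paste0("Q", 2:4)
  ok <- stats::complete.cases(reps)
  if (!any(ok)) {
    abort_recwalk("all bootstrap replicates failed to fit.", "contract")
  }
  qs <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.5, 0.025, 0.975), names = FALSE)
  out <- tibble::tibble(
    category = paste0("Q", 1:4),
    or = unname(c(1, qs[1, ])),
    conf.low = unname(c(1, qs[2, ])),
    conf.high = unname(c(1, qs[3, ])),
    n_boot = as.integer(n_boot)
  )
  attr(out, "replicates") <- reps
  attr(out, "n_failed") <- sum(!ok)
  class(out) <- c("risk_score_result", class(out))
  out
}

#' @export
print.risk_score_result <- function(x, ...) {
  cat(sprintf("Risk-score category odds ratios (bootstrap, %d replicates)\n",
              x$n_boot[1]))
  NextMethod()
}

# report sentence in the style of the published disparity summary
risk_score_sentence <- function(result, outcome_label = "reporting recreational walking") {
  rows <- result[result$category != "Q1", ]
  parts <- sprintf("%.2f (95%% CI: %.2f, %.2f) times", rows$or, rows$conf.low,
                   rows$conf.high)
  sprintf(
    paste(
      "Compared to the environments with the lowest environmental",
      "supportiveness of walking, the odds of %s were %s higher in the three",
      "categories of increasing environmental supportiveness."
    ),
    outcome_label, paste(parts, collapse = ", ")
  )
}
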