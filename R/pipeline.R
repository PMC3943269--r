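#' Pipeline configuration
#'
#' Bundles inputs and settings for [run_pipeline()]: either a generator
#' configuration (synthetic run) or paths to a cohort CSV and adjacency edge
#' list, the candidate variable lists for the staged modelling strategy, MCMC
#' and bootstrap settings, and the output directory.
#'
#' @param generator a [generator_config()] for a synthetic run, or `NULL`.
#' @param cohort_path,graph_path,items_path input files, used when
#'   `generator` is `NULL` (`items_path` optional).
#' @param output_dir directory for the report and artifacts (created if
#'   needed).
#' @param outcomes named character vector: the binary and ordinal outcome
#'   columns.
#' @param base_vars always-kept adjusters (age and sex).
#' @param individual_vars,weather_vars,env_vars candidate variable names.
#' @param use_ecometrics fit ecometric scores from item responses and add
#'   their quartiles as an extra environmental candidate.
#' @param level credible/confidence level for "independently associated".
#' @param screen_engine `"approx"` (fast penalized fits) or `"mcmc"` for the
#'   screening, pretest and interaction stages; stage models and the final
#'   models always use MCMC.
#' @param control an [mcmc_control()].
#' @param priors a [bym_priors()].
#' @param n_boot bootstrap replicates for the risk score.
#' @param bootstrap_method `"individual"` or `"neighborhood"`.
#' @param seed master seed for everything the pipeline randomizes.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = NULL,
                            cohort_path = NULL, graph_path = NULL,
                            items_path = NULL,
                            output_dir = tempfile("recwalk_run_"),
                            outcomes = c(binary = "walk_any",
                                         ordinal = "walk_time_nbhd_cat"),
                            base_vars = c("age_class", "male"),
                            individual_vars = c("living_alone", "education",
                                                "employment", "occupation",
                                                "income", "non_ownership",
                                                "hdi_class"),
                            weather_vars = c("rainfall_cat", "temp_mean_cat"),
                            env_vars = c("nbhd_education", "green_spaces",
                                         "density_destinations", "air_traffic",
                                         "road_traffic_nuisance", "insecurity"),
                            use_ecometrics = FALSE,
                            level = 0.95,
                            screen_engine = c("approx", "mcmc"),
                            control = mcmc_control(),
                            priors = bym_priors(),
                            n_boot = 200L,
                            bootstrap_method = "individual",
                            seed = 1L) {
  screen_engine <- match.arg(screen_engine)
  if (is.null(generator) && (is.null(cohort_path) || is.null(graph_path))) {
    abort_recwalk("provide either `generator` or `cohort_path` + `graph_path`.",
                  "config")
  }
  structure(
    list(generator = generator, cohort_path = cohort_path,
         graph_path = graph_path, items_path = items_path,
         output_dir = output_dir, outcomes = outcomes, base_vars = base_vars,
         individual_vars = individual_vars, weather_vars = weather_vars,
         env_vars = env_vars, use_ecometrics = use_ecometrics, level = level,
         screen_engine = screen_engine, control = control, priors = priors,
         n_boot = as.integer(n_boot), bootstrap_method = bootstrap_method,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# coefficient table for one model under the selected engine
fit_coef_table <- function(cohort, formula, graph, outcome_type, engine,
                           level, control, priors) {
  if (engine == "approx") {
    tab <- approx_fit(cohort, formula, outcome_type = outcome_type,
                      level = level)
    attr(tab, "terms_obj") <- attr(attr(tab, "fit"), "terms") %||%
      attr(tab, "fit")$terms
    tab
  } else {
    fit <- if (outcome_type == "binary") {
      fit_bym_logistic(cohort, formula, graph, control, priors)
    } else {
      fit_bym_ordinal(cohort, formula, graph, control, priors)
    }
    td <- tidy(fit, conf.level = level)
    td <- td[!td$term %in% c("(Intercept)", "sigma_u", "tau_v") &
               !startsWith(td$term, "kappa_"), ]
    attr(td, "terms_obj") <- fit$terms
    td
  }
}

# variables with at least one non-reference level whose interval excludes 0
associated_variables <- function(coef_tab, candidates) {
  vars <- term_variable(attr(coef_tab, "terms_obj"), coef_tab$term)
  hit <- coef_tab$conf.low > 0 | coef_tab$conf.high < 0
  strength <- abs(coef_tab$estimate) / pmax(coef_tab$std.error, 1e-12)
  assoc <- tapply(hit, vars, any)
  str_by_var <- tapply(strength, vars, max)
  keep <- intersect(candidates, names(assoc)[assoc])
  keep[order(-str_by_var[keep])]
}

#' Step 1: age- and sex-adjusted models
#'
#' Fits the convolution models for both outcomes with only age and sex, to
#' assess raw between-neighborhood variability, and decomposes it into
#' structured and unstructured IqORs.
#'
#' @param cohort cohort data frame (missing outcomes already excluded).
#' @param graph a [nbhd_graph()].
#' @param control an [mcmc_control()].
#' @param priors a [bym_priors()].
#' @param outcomes named character vector (`binary`, `ordinal`) of outcome
#'   columns.
#' @param base_vars adjuster variable names.
#' @return list with `fits` (per outcome) and `decomposition` (tibble with an
#'   `outcome` column).
#' @export
step_age_sex <- function(cohort, graph, control = mcmc_control(),
                         priors = bym_priors(),
                         outcomes = c(binary = "walk_any",
                                      ordinal = "walk_time_nbhd_cat"),
                         base_vars = c("age_class", "male")) {
  fits <- list(
    binary = fit_bym_logistic(
      cohort, stats::reformulate(base_vars, outcomes[["binary"]]),
      graph, control, priors
    ),
    ordinal = fit_bym_ordinal(
      cohort, stats::reformulate(base_vars, outcomes[["ordinal"]]),
      graph, control, priors
    )
  )
  list(fits = fits, decomposition = stage_decomposition(fits, "age_sex"))
}

stage_decomposition <- function(fits, stage) {
  dplyr::bind_rows(lapply(names(fits), function(oc) {
    d <- decompose(fits[[oc]])
    d$outcome <- oc
    d$stage <- stage
    d
  }))
}

#' Step 2: retain individual and weather variables
#'
#' Fits one model per outcome with the base adjusters plus all candidates,
#' and retains the candidates independently associated with the outcome (at
#' least one non-reference level with an interval excluding the null).
#'
#' @inheritParams step_age_sex
#' @param candidates candidate variable names.
#' @param outcome outcome column name.
#' @param outcome_type `"binary"` or `"ordinal"`.
#' @param level interval level for the retention criterion.
#' @param engine `"approx"` or `"mcmc"`.
#' @return character vector of retained variable names (may be empty; base
#'   adjusters are always kept upstream).
#' @export
select_individual_weather <- function(cohort, candidates, graph,
                                      outcome = "walk_any",
                                      outcome_type = "binary",
                                      base_vars = c("age_class", "male"),
                                      level = 0.95,
                                      engine = "approx",
                                      control = mcmc_control(),
                                      priors = bym_priors()) {
  if (length(candidates) == 0L) {
    abort_recwalk("candidate list is empty.", "invalid_argument")
  }
  missing_cols <- setdiff(c(candidates, base_vars, outcome), names(cohort))
  if (length(missing_cols)) {
    abort_recwalk(sprintf("columns not in cohort: %s",
                          paste(missing_cols, collapse = ", ")), "config")
  }
  f <- stats::reformulate(c(base_vars, candidates), outcome)
  tab <- fit_coef_table(cohort, f, graph, outcome_type, engine, level,
                        control, priors)
  associated_variables(tab, candidates)
}

#' Step 3: pretest environmental variables one by one
#'
#' Adds each environmental candidate alone to the step-2 model and records
#' whether any of its levels is associated with the outcome.
#'
#' @inheritParams select_individual_weather
#' @param env_list environmental candidate variable names.
#' @param adjusters variables retained at step 2 (plus base adjusters).
#' @return tibble with one row per (variable, outcome): `variable`,
#'   `outcome`, `flagged`, `strength` (max |estimate|/SE over levels),
#'   `n_fits` attribute equals `length(env_list)`.
#' @export
pretest_environment <- function(cohort, env_list, graph,
                                outcome = "walk_any",
                                outcome_type = "binary",
                                adjusters = c("age_class", "male"),
                                level = 0.95,
                                engine = "approx",
                                control = mcmc_control(),
                                priors = bym_priors()) {
  missing_cols <- setdiff(c(env_list, adjusters, outcome), names(cohort))
  if (length(missing_cols)) {
    abort_recwalk(sprintf("columns not in cohort: %s",
                          paste(missing_cols, collapse = ", ")), "config")
  }
  rows <- lapply(env_list, function(v) {
    f <- stats::reformulate(c(adjusters, v), outcome)
    tab <- fit_coef_table(cohort, f, graph, outcome_type, engine, level,
                          control, priors)
    vars <- term_variable(attr(tab, "terms_obj"), tab$term)
    own <- vars == v & !is.na(vars)
    tibble::tibble(
      variable = v,
      outcome = outcome,
      flagged = any(tab$conf.low[own] > 0 | tab$conf.high[own] < 0),
      strength = max(abs(tab$estimate[own]) /
                       pmax(tab$std.error[own], 1e-12))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_fits") <- length(env_list)
  out
}

#' Step 4: progressively combine flagged environmental variables
#'
#' Adds the pretest-flagged variables in order of decreasing evidence
#' strength; after each addition, variables whose intervals all cover the
#' null are dropped again. The surviving set enters one final MCMC model.
#'
#' @inheritParams pretest_environment
#' @param pretest result of [pretest_environment()] for this outcome.
#' @return list with `fit` (final `bym_fit`), `retained_env` (character),
#'   `or_table` (tidy coefficient table, OR scale) and `decomposition`.
#' @export
build_final_model <- function(cohort, pretest, graph,
                              outcome = "walk_any",
                              outcome_type = "binary",
                              adjusters = c("age_class", "male"),
                              level = 0.95,
                              engine = "approx",
                              control = mcmc_control(),
                              priors = bym_priors()) {
  flagged <- pretest[pretest$flagged, ]
  order_vars <- flagged$variable[order(-flagged$strength)]
  included <- character(0)
  for (v in order_vars) {
    trial <- c(included, v)
    f <- stats::reformulate(c(adjusters, trial), outcome)
    tab <- fit_coef_table(cohort, f, graph, outcome_type, engine, level,
                          control, priors)
    included <- associated_variables(tab, trial)
  }
  f_final <- stats::reformulate(c(adjusters, included), outcome)
  fit <- if (outcome_type == "binary") {
    fit_bym_logistic(cohort, f_final, graph, control, priors)
  } else {
    fit_bym_ordinal(cohort, f_final, graph, control, priors)
  }
  or_table <- tidy(fit, exponentiate = TRUE, conf.level = level)
  list(
    fit = fit,
    retained_env = included,
    or_table = or_table,
    decomposition = decompose(fit)
  )
}

#' Step 5: weather-by-environment interaction scan
#'
#' Tests, one pair at a time, product terms between the retained weather
#' variables and the retained environmental variables.
#'
#' @inheritParams build_final_model
#' @param weather_vars retained weather variable names.
#' @param env_vars retained environmental variable names.
#' @param final_terms all main-effect terms of the final model.
#' @return tibble (`weather`, `env`, `outcome`, `flagged`, `strength`); zero
#'   rows when either list is empty.
#' @export
test_weather_interactions <- function(cohort, weather_vars, env_vars, graph,
                                      final_terms,
                                      outcome = "walk_any",
                                      outcome_type = "binary",
                                      level = 0.95,
                                      engine = "approx",
                                      control = mcmc_control(),
                                      priors = bym_priors()) {
  if (length(weather_vars) == 0L || length(env_vars) == 0L) {
    return(tibble::tibble(weather = character(0), env = character(0),
                          outcome = character(0), flagged = logical(0),
                          strength = numeric(0)))
  }
  pairs <- expand.grid(weather = weather_vars, env = env_vars,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    wv <- pairs$weather[i]; ev <- pairs$env[i]
    f <- stats::reformulate(c(final_terms, paste0(wv, ":", ev)), outcome)
    tab <- tryCatch(
      fit_coef_table(cohort, f, graph, outcome_type, engine, level,
                     control, priors),
      error = function(e) NULL
    )
    if (is.null(tab)) {
      return(tibble::tibble(weather = wv, env = ev, outcome = outcome,
                            flagged = NA, strength = NA_real_))
    }
    inter <- grepl(":", tab$term, fixed = TRUE)
    tibble::tibble(
      weather = wv, env = ev, outcome = outcome,
      flagged = any(tab$conf.low[inter] > 0 | tab$conf.high[inter] < 0),
      strength = if (any(inter)) {
        max(abs(tab$estimate[inter]) / pmax(tab$std.error[inter], 1e-12))
      } else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort_recwalk(sprintf("pipeline stage `%s` failed: %s", name,
                          conditionMessage(e)), "stage", parent = e)
  })
}

#' Run the full five-step modelling pipeline
#'
#' Executes, for both outcomes: (1) age- and sex-adjusted convolution models
#' with variance decomposition; (2) retention of individual and weather
#' variables; (3) one-by-one environmental pretests; (4) progressive
#' combination into final models with decomposition; (5) weather-by-
#' environment interaction tests; then the environmental risk score with
#' bootstrap intervals. Writes a Markdown report, CSV tables, GeoJSON
#' choropleths of the posterior spatial effects before and after
#' environmental adjustment, and a JSON manifest, all under
#' `config$output_dir`.
#'
#' @param config a [pipeline_config()].
#' @return a `recwalk_report` (invisible list of all stage results and
#'   artifact paths).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort_recwalk("`config` must come from pipeline_config().", "config")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- inputs ----
  inputs <- run_stage("inputs", {
    if (!is.null(config$generator)) {
      gen <- generate_cohort(config$generator)
      items <- if (config$use_ecometrics) {
        generate_item_responses(
          gen$cohort,
          setNames(gen$node_fields$field_green_spaces, gen$node_fields$node_id),
          config$generator$item_model,
          seed = config$generator$seed + 1L
        )
      } else NULL
      list(cohort = gen$cohort, graph = gen$graph, items = items, gen = gen)
    } else {
      cohort <- read_cohort_csv(config$cohort_path)
      graph <- read_adjacency(config$graph_path)
      items <- if (!is.null(config$items_path)) {
        tibble::as_tibble(utils::read.csv(config$items_path))
      } else NULL
      list(cohort = cohort, graph = graph, items = items)
    }
  })
  cohort <- inputs$cohort
  graph <- inputs$graph

  all_vars <- c(config$base_vars, config$individual_vars, config$weather_vars,
                config$env_vars, unname(config$outcomes))
  missing_cols <- setdiff(all_vars, names(cohort))
  if (length(missing_cols)) {
    abort_recwalk(sprintf("config references missing cohort columns: %s",
                          paste(missing_cols, collapse = ", ")), "config")
  }

  # exclude participants with missing walking outcomes
  keep <- !is.na(cohort[[config$outcomes[["binary"]]]]) &
    !is.na(cohort[[config$outcomes[["ordinal"]]]])
  cohort <- cohort[keep, , drop = FALSE]

  # ---- ecometrics ----
  env_vars <- config$env_vars
  eco <- NULL
  if (config$use_ecometrics && !is.null(inputs$items)) {
    eco <- run_stage("ecometrics", {
      sc <- fit_ecometric_3level(
        inputs$items,
        control = mcmc_control(
          n_chains = config$control$n_chains,
          n_iter = config$control$n_iter, n_burnin = config$control$n_burnin,
          thin = config$control$thin, seed = config$seed + 11L
        ),
        priors = config$priors
      )
      sc
    })
    idx <- match(cohort$neighborhood_id, eco$neighborhood_id)
    raw_scores <- eco$score[idx]
    cohort$ecometric_score_cat <- factor(
      paste0("Q", quartile_categorize(raw_scores)), levels = paste0("Q", 1:4)
    )
    env_vars <- c(env_vars, "ecometric_score_cat")
  }

  ctrl <- config$control
  stage_seed <- function(k) mcmc_control(
    n_chains = ctrl$n_chains, n_iter = ctrl$n_iter, n_burnin = ctrl$n_burnin,
    thin = ctrl$thin, seed = config$seed + k
  )

  # ---- step 1 ----
  s1 <- run_stage("age_sex", {
    step_age_sex(cohort, graph, stage_seed(1L), config$priors,
                 config$outcomes, config$base_vars)
  })

  # ---- step 2 ----
  s2 <- run_stage("individual_weather", {
    lapply(setNames(names(config$outcomes), names(config$outcomes)), function(oc) {
      retained <- select_individual_weather(
        cohort, c(config$individual_vars, config$weather_vars), graph,
        outcome = config$outcomes[[oc]], outcome_type = oc,
        base_vars = config$base_vars, level = config$level,
        engine = config$screen_engine, control = stage_seed(2L),
        priors = config$priors
      )
      f <- stats::reformulate(c(config$base_vars, retained), config$outcomes[[oc]])
      fit <- if (oc == "binary") {
        fit_bym_logistic(cohort, f, graph, stage_seed(3L), config$priors)
      } else {
        fit_bym_ordinal(cohort, f, graph, stage_seed(4L), config$priors)
      }
      list(retained = retained, fit = fit)
    })
  })
  s2_fits <- lapply(s2, `[[`, "fit")
  s2_decomp <- stage_decomposition(s2_fits, "individual_level")

  # ---- step 3 ----
  s3 <- run_stage("pretest", {
    dplyr::bind_rows(lapply(names(config$outcomes), function(oc) {
      pretest_environment(
        cohort, env_vars, graph,
        outcome = config$outcomes[[oc]], outcome_type = oc,
        adjusters = c(config$base_vars, s2[[oc]]$retained),
        level = config$level, engine = config$screen_engine,
        control = stage_seed(5L), priors = config$priors
      )
    }))
  })

  # ---- step 4 ----
  s4 <- run_stage("final_model", {
    lapply(setNames(names(config$outcomes), names(config$outcomes)), function(oc) {
      build_final_model(
        cohort, s3[s3$outcome == config$outcomes[[oc]], ], graph,
        outcome = config$outcomes[[oc]], outcome_type = oc,
        adjusters = c(config$base_vars, s2[[oc]]$retained),
        level = config$level, engine = config$screen_engine,
        control = stage_seed(6L), priors = config$priors
      )
    })
  })
  s4_decomp <- stage_decomposition(lapply(s4, `[[`, "fit"), "environmental")

  # ---- step 5 ----
  s5 <- run_stage("interactions", {
    dplyr::bind_rows(lapply(names(config$outcomes), function(oc) {
      test_weather_interactions(
        cohort,
        weather_vars = intersect(s2[[oc]]$retained, config$weather_vars),
        env_vars = s4[[oc]]$retained_env, graph,
        final_terms = c(config$base_vars, s2[[oc]]$retained,
                        s4[[oc]]$retained_env),
        outcome = config$outcomes[[oc]], outcome_type = oc,
        level = config$level, engine = config$screen_engine,
        control = stage_seed(7L), priors = config$priors
      )
    }))
  })

  # ---- risk score ----
  risk <- run_stage("risk_score", {
    lapply(setNames(names(config$outcomes), names(config$outcomes)), function(oc) {
      env_retained <- s4[[oc]]$retained_env
      if (length(env_retained) == 0L) return(NULL)
      coefs <- extract_env_coefs(s4[[oc]]$fit, env_retained)
      if (!length(coefs)) return(NULL)
      scores <- compute_scores(cohort, coefs, env_vars = env_retained)
      cats <- tryCatch(score_categories(scores),
                       recwalk_error_degenerate_score = function(e) NULL)
      if (is.null(cats)) return(NULL)
      f_base <- stats::reformulate(c(config$base_vars, s2[[oc]]$retained),
                                   config$outcomes[[oc]])
      refit <- refit_with_score(cohort, f_base, graph, cats,
                                stage_seed(8L), config$priors)
      boot <- bootstrap_ors(cohort, f_base, cats, n_boot = config$n_boot,
                            seed = config$seed + 9L,
                            method = config$bootstrap_method)
      list(scores = scores, categories = cats, refit = refit, boot = boot,
           sentence = risk_score_sentence(
             boot,
             if (oc == "binary") "reporting recreational walking"
             else "reporting a higher recreational walking time in one's neighborhood"
           ))
    })
  })

  decomposition <- dplyr::bind_rows(s1$decomposition, s2_decomp, s4_decomp)

  report <- structure(
    list(
      descriptives = cohort_descriptives(cohort),
      decomposition = decomposition,
      selection = lapply(s2, `[[`, "retained"),
      pretest = s3,
      final = s4,
      interactions = s5,
      risk = risk,
      ecometrics = eco,
      stage1 = s1, stage2 = s2,
      cohort_n = nrow(cohort),
      graph = graph,
      config = config
    ),
    class = "recwalk_report"
  )

  run_stage("artifacts", write_report_artifacts(report, config$output_dir))
  invisible(report)
}

#' @export
print.recwalk_report <- function(x, ...) {
  cat(sprintf("<recwalk_report> %d individuals, %d neighborhoods\n",
              x$cohort_n, n_nodes(x$graph)))
  cat("\nVariance decomposition by stage:\n")
  print(as.data.frame(x$decomposition[
    x$decomposition$component %in% c("iqor_structured", "pct_structured"), ]))
  for (oc in names(x$risk)) {
    if (!is.null(x$risk[[oc]])) cat("\n", x$risk[[oc]]$sentence, "\n", sep = "")
  }
  invisible(x)
}

# percentage table of the main individual variables
cohort_descriptives <- function(cohort) {
  vars <- intersect(c("age_class", "male", "living_alone", "education",
                      "employment", "occupation", "non_ownership"),
                    names(cohort))
  dplyr::bind_rows(lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.factor(x)) {
      tab <- table(x) / length(x)
      tibble::tibble(variable = v, level = names(tab),
                     pct = round(100 * as.numeric(tab), 1))
    } else {
      tibble::tibble(variable = v, level = "yes",
                     pct = round(100 * mean(x == 1), 1))
    }
  }))
}
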