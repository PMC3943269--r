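#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the source cohort: about 7105
#' adults nested in ~661 contiguous census-tract neighborhoods (a 23 x 29
#' lattice, 667 cells, is the closest rectangle), a binary
#' recreational-walking outcome with ~69% prevalence, a 5-category ordinal
#' neighborhood-walking-time outcome with a point mass at category 1 (zero
#' minutes), sociodemographic margins matching the published sample
#' description, spatially autocorrelated environmental exposures, and
#' convolution (exchangeable + intrinsic CAR) neighborhood effects.
#'
#' `true_betas` is a named list of log odds ratios: a scalar for binary
#' covariates, a vector over non-reference levels for categorical ones.
#' Defaults are the published final-model estimates (e.g. male 1.38, retired
#' 1.68, air traffic 0.75, high density of destinations 1.39). When
#' `intercept` is `NULL` it is calibrated as
#' `qlogis(target_prevalence) - sum(beta * E[x])` under the generator's
#' covariate distribution, so the marginal prevalence stays near the target.
#'
#' @param lattice_rows,lattice_cols lattice dimensions.
#' @param n_individuals total cohort size, allocated to neighborhoods
#'   multinomially (every neighborhood gets at least one resident); ignored
#'   when `n_per_neighborhood` is given.
#' @param n_per_neighborhood fixed number of residents per neighborhood.
#' @param intercept binary-outcome intercept on the log-odds scale, or `NULL`
#'   to calibrate to `target_prevalence`.
#' @param target_prevalence marginal prevalence used for calibration.
#' @param true_betas named list of true log odds ratios (see Details).
#' @param sigma_u SD of the exchangeable neighborhood effect.
#' @param tau_v conditional SD of the intrinsic CAR effect.
#' @param ordinal_cutpoints 4 strictly increasing cutpoints of the ordinal
#'   outcome on the latent logistic scale.
#' @param env_spatial_range k-hop radius over which node noise is averaged to
#'   make exposures spatially autocorrelated.
#' @param item_model list describing the ecometric item battery:
#'   `item_intercepts` (one per item, first is the reference), `thresholds`
#'   (K-1 increasing values), `sigma_individual`.
#' @param missing_rate fraction of participants with missing walking outcomes,
#'   missing at random given low education/income.
#' @param couple_outcomes force ordinal category 1 for non-walkers (a
#'   non-walker has zero neighborhood walking minutes). Disable to obtain an
#'   exactly proportional-odds ordinal outcome.
#' @param scheme lattice contiguity, `"rook"` or `"queen"`.
#' @param seed integer seed driving all generator randomness.
#' @return a `generator_config` list.
#' @export
generator_config <- function(lattice_rows = 23L, lattice_cols = 29L,
                             n_individuals = 7105L,
                             n_per_neighborhood = NULL,
                             intercept = NULL,
                             target_prevalence = 0.69,
                             true_betas = default_true_betas(),
                             sigma_u = 0.175,
                             tau_v = 0.25,
                             ordinal_cutpoints = default_ordinal_cutpoints(),
                             env_spatial_range = 2L,
                             item_model = default_item_model(),
                             missing_rate = 0.025,
                             couple_outcomes = TRUE,
                             scheme = "rook",
                             seed = 1L) {
  if (lattice_rows < 1L || lattice_cols < 1L ||
      lattice_rows * lattice_cols < 2L) {
    abort_recwalk("lattice must have >= 2 cells.", "invalid_argument")
  }
  if (sigma_u < 0 || tau_v < 0) {
    abort_recwalk("random-effect SDs must be nonnegative.", "invalid_argument")
  }
  if (length(ordinal_cutpoints) != 4L ||
      any(diff(ordinal_cutpoints) <= 0)) {
    abort_recwalk("`ordinal_cutpoints` must be 4 strictly increasing values.",
                  "invalid_argument")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort_recwalk("`missing_rate` must be in [0, 1).", "invalid_argument")
  }
  cfg <- structure(
    list(
      lattice_rows = as.integer(lattice_rows),
      lattice_cols = as.integer(lattice_cols),
      n_individuals = as.integer(n_individuals),
      n_per_neighborhood = if (is.null(n_per_neighborhood)) NULL else as.integer(n_per_neighborhood),
      intercept = intercept,
      target_prevalence = target_prevalence,
      true_betas = true_betas,
      sigma_u = sigma_u,
      tau_v = tau_v,
      ordinal_cutpoints = as.numeric(ordinal_cutpoints),
      env_spatial_range = as.integer(env_spatial_range),
      item_model = item_model,
      missing_rate = missing_rate,
      couple_outcomes = isTRUE(couple_outcomes),
      scheme = scheme,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_true_betas(cfg$true_betas)
  cfg
}

# covariate catalogue: level labels (first = reference) and population
# frequencies used both for sampling and for intercept calibration.
# Frequencies follow the published sample description; categories printed
# with incomplete margins are renormalized.
covariate_catalogue <- function() {
  norm <- function(p) p / sum(p)
  list(
    male = list(type = "binary", p = 0.656),
    age_class = list(type = "factor",
                     levels = c("30-44", "45-59", "60-79"),
                     p = norm(c(0.355, 0.417, 0.229))),
    living_alone = list(type = "binary", p = 0.298),
    education = list(type = "factor",
                     levels = c("upper_tertiary", "higher_secondary",
                                "primary_lower_secondary", "none"),
                     p = norm(c(0.381, 0.295, 0.241, 0.075))),
    employment = list(type = "factor",
                      levels = c("employed", "unemployed", "retired"),
                      p = norm(c(0.617, 0.151, 0.177))),
    occupation = list(type = "factor",
                      levels = c("high_white_collar", "intermediate",
                                 "low_white_collar", "blue_collar"),
                      p = norm(c(0.397, 0.055, 0.382, 0.110))),
    income = list(type = "factor",
                  levels = paste0("Q", 1:4), p = rep(0.25, 4)),
    non_ownership = list(type = "binary", p = 0.454),
    hdi_class = list(type = "factor",
                     levels = c("france", "high", "intermediate", "low"),
                     p = c(0.80, 0.08, 0.07, 0.05)),
    rainfall_cat = list(type = "quartile"),
    temp_mean_cat = list(type = "quartile"),
    nbhd_education = list(type = "env_quartile"),
    green_spaces = list(type = "env_quartile"),
    density_destinations = list(type = "env_quartile"),
    air_traffic = list(type = "env_binary", p = 0.2),
    road_traffic_nuisance = list(type = "env_quartile"),
    insecurity = list(type = "env_quartile")
  )
}

#' @rdname generator_config
#' @export
default_true_betas <- function() {
  list(
    male = log(1.38),
    age_class = log(c(1.01, 1.02)),
    living_alone = log(0.80),
    education = log(c(1.12, 1.01, 0.81)),
    employment = log(c(1.15, 1.68)),
    occupation = log(c(0.83, 0.83, 0.79)),
    non_ownership = log(1.18),
    rainfall_cat = log(c(0.85, 0.82, 0.78)),
    temp_mean_cat = log(c(1.14, 1.40, 1.37)),
    nbhd_education = log(c(1.17, 1.45, 1.47)),
    green_spaces = log(c(0.97, 1.13, 1.43)),
    density_destinations = log(c(1.09, 1.14, 1.39)),
    air_traffic = log(0.75)
  )
}

# marginal ordinal category probabilities: 69% report any walking, 74% of
# walkers do some of it in their neighborhood -> P(category 1) ~ 0.49, the
# rest split equally over categories 2-5
default_ordinal_cutpoints <- function() {
  p1 <- 1 - 0.69 * 0.74
  cum <- p1 + (1 - p1) * c(0, 0.25, 0.5, 0.75)
  qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6))
}

#' @rdname generator_config
#' @export
default_item_model <- function() {
  list(
    item_intercepts = c(0, 0.3, -0.3, 0.6),
    thresholds = c(-1, 0, 1),
    sigma_individual = 1
  )
}

validate_true_betas <- function(true_betas) {
  cat <- covariate_catalogue()
  for (nm in names(true_betas)) {
    if (!nm %in% names(cat)) {
      abort_recwalk(sprintf("unknown covariate `%s` in `true_betas`.", nm), "config")
    }
    want <- switch(cat[[nm]]$type,
                   binary = 1L, env_binary = 1L,
                   factor = length(cat[[nm]]$levels) - 1L,
                   quartile = 3L, env_quartile = 3L)
    if (length(true_betas[[nm]]) != want) {
      abort_recwalk(sprintf(
        "`true_betas$%s` must have length %d (non-reference levels).", nm, want
      ), "config")
    }
  }
  invisible(TRUE)
}

# expected model-matrix value of each covariate (for intercept calibration)
expected_covariate_means <- function() {
  cat <- covariate_catalogue()
  lapply(cat, function(cv) {
    switch(cv$type,
           binary = cv$p,
           env_binary = cv$p,
           factor = cv$p[-1L],
           quartile = rep(0.25, 3),
           env_quartile = rep(0.25, 3))
  })
}

calibrate_intercept <- function(config) {
  if (!is.null(config$intercept)) return(config$intercept)
  em <- expected_covariate_means()
  shift <- sum(vapply(names(config$true_betas), function(nm) {
    sum(config$true_betas[[nm]] * em[[nm]])
  }, numeric(1)))
  qlogis(config$target_prevalence) - shift
}

# average iid node noise over the k-hop neighborhood of each node
smooth_field_khop <- function(graph, noise, k) {
  if (k <= 0) return(noise)
  ig <- as_igraph(graph)
  nb <- igraph::ego(ig, order = k, nodes = seq_len(n_nodes(graph)))
  vapply(nb, function(ids) mean(noise[as.integer(ids)]), numeric(1))
}

#' Generate a synthetic cohort
#'
#' Builds the lattice contiguity graph, draws the exchangeable and intrinsic
#' CAR neighborhood effects, spatially smooths environmental exposure fields,
#' samples individual covariates, weather windows, and both walking outcomes
#' from the convolution logistic / cumulative-logit models, and flags
#' missing-at-random walking outcomes. Latent truth is retained in
#' dot-prefixed columns (`.u`, `.v`, `.eta_bin`, `.eta_ord`) so downstream
#' recovery can be tested exactly.
#'
#' @param config a [generator_config()].
#' @return a `recwalk_cohort`: list with elements `cohort` (tibble), `graph`
#'   ([nbhd_graph()]), `node_fields` (per-neighborhood truth: effects and raw
#'   exposure fields) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort_recwalk("`config` must come from generator_config().", "config")
  }
  validate_true_betas(config$true_betas)
  graph <- make_lattice(config$lattice_rows, config$lattice_cols,
                        scheme = config$scheme)
  J <- n_nodes(graph)
  catl <- covariate_catalogue()
  intercept <- calibrate_intercept(config)

  with_seed(config$seed, {
    # neighborhood effects
    u <- if (config$sigma_u > 0) rnorm(J, 0, config$sigma_u) else numeric(J)
    v <- sample_car_field(graph, config$tau_v)

    # exposure fields: smoothed iid noise, one field per environmental variable
    env_vars <- names(catl)[startsWith(vapply(catl, `[[`, "", "type"), "env")]
    fields <- lapply(env_vars, function(nm) {
      smooth_field_khop(graph, rnorm(J), config$env_spatial_range)
    })
    names(fields) <- env_vars

    # allocation of individuals to neighborhoods
    if (!is.null(config$n_per_neighborhood)) {
      sizes <- rep(config$n_per_neighborhood, J)
    } else {
      n <- config$n_individuals
      if (n < J) {
        abort_recwalk("`n_individuals` must be at least the number of neighborhoods.",
                      "config")
      }
      sizes <- as.vector(stats::rmultinom(1, n - J, rep(1, J))) + 1L
    }
    n <- sum(sizes)
    nbhd <- rep(graph$node_ids, sizes)

    cohort <- tibble::tibble(
      individual_id = seq_len(n),
      neighborhood_id = nbhd
    )

    # individual covariates
    draw_cov <- function(cv) {
      switch(cv$type,
             binary = rbinom(n, 1L, cv$p),
             factor = factor(sample(cv$levels, n, replace = TRUE, prob = cv$p),
                             levels = cv$levels),
             NULL)
    }
    for (nm in names(catl)) {
      val <- draw_cov(catl[[nm]])
      if (!is.null(val)) cohort[[nm]] <- val
    }

    # weather: daily regional series for 2007-2008, 8-day window means
    days <- seq(as.Date("2007-01-01"), as.Date("2008-12-31"), by = "day")
    doy <- as.integer(format(days, "%j"))
    temp_daily <- tibble::tibble(
      date = days,
      value = 11 + 8 * sin(2 * pi * (doy - 105) / 365.25) + rnorm(length(days), 0, 3)
    )
    rain_daily <- tibble::tibble(
      date = days,
      value = rgamma(length(days), shape = 0.8, scale = 2.5)
    )
    cohort$recruitment_date <- sample(days[days >= as.Date("2007-01-08")], n,
                                      replace = TRUE)
    ud <- unique(cohort$recruitment_date)
    tm <- weather_window_average(temp_daily, ud)
    rm_ <- weather_window_average(rain_daily, ud)
    cohort$temp_mean_8d <- tm[match(cohort$recruitment_date, ud)]
    cohort$rainfall_8d <- rm_[match(cohort$recruitment_date, ud)]
    cohort$temp_mean_cat <- factor(paste0("Q", quartile_categorize(cohort$temp_mean_8d)),
                                   levels = paste0("Q", 1:4))
    cohort$rainfall_cat <- factor(paste0("Q", quartile_categorize(cohort$rainfall_8d)),
                                  levels = paste0("Q", 1:4))

    # environmental exposures: per-individual value of the neighborhood field,
    # quartiled over participants (air traffic: binary exposure area)
    node_pos <- match(cohort$neighborhood_id, graph$node_ids)
    for (nm in env_vars) {
      val <- fields[[nm]][node_pos]
      if (catl[[nm]]$type == "env_binary") {
        thr <- stats::quantile(fields[[nm]], 1 - catl[[nm]]$p, names = FALSE)
        cohort[[nm]] <- as.integer(fields[[nm]] > thr)[node_pos]
      } else {
        cohort[[nm]] <- factor(paste0("Q", quartile_categorize(val)),
                               levels = paste0("Q", 1:4))
      }
    }

    # linear predictor from the true coefficient map
    eta_fixed <- rep(0, n)
    for (nm in names(config$true_betas)) {
      b <- config$true_betas[[nm]]
      x <- cohort[[nm]]
      if (is.factor(x)) {
        lev <- as.integer(x)
        contrib <- c(0, b)[lev]
      } else {
        contrib <- b * as.numeric(x)
      }
      eta_fixed <- eta_fixed + contrib
    }
    re <- u[node_pos] + v[node_pos]
    eta_bin <- intercept + eta_fixed + re
    eta_ord <- eta_fixed + re

    cohort$walk_any <- rbinom(n, 1L, plogis(eta_bin))
    latent <- eta_ord + stats::rlogis(n)
    ord <- 1L + rowSums(outer(latent, config$ordinal_cutpoints, `>`))
    if (config$couple_outcomes) ord[cohort$walk_any == 0L] <- 1L
    cohort$walk_time_nbhd_cat <- as.integer(ord)

    # missing-at-random outcome exclusions, weighted toward low education/income
    if (config$missing_rate > 0) {
      wgt <- exp(0.7 * (cohort$education %in% c("none", "primary_lower_secondary")) +
                   0.7 * (cohort$income == "Q1"))
      p_miss <- pmin(config$missing_rate * wgt / mean(wgt), 1)
      cohort$walk_missing <- rbinom(n, 1L, p_miss) == 1L
      cohort$walk_any[cohort$walk_missing] <- NA_integer_
      cohort$walk_time_nbhd_cat[cohort$walk_missing] <- NA_integer_
    } else {
      cohort$walk_missing <- FALSE
    }

    # hidden truth
    cohort$.u <- u[node_pos]
    cohort$.v <- v[node_pos]
    cohort$.eta_bin <- eta_bin
    cohort$.eta_ord <- eta_ord

    node_fields <- tibble::tibble(node_id = graph$node_ids, u = u, v = v)
    for (nm in env_vars) node_fields[[paste0("field_", nm)]] <- fields[[nm]]

    structure(
      list(cohort = cohort, graph = graph, node_fields = node_fields,
           config = config, intercept = intercept),
      class = "recwalk_cohort"
    )
  })
}

#' @export
print.recwalk_cohort <- function(x, ...) {
  cat(sprintf(
    "<recwalk_cohort> %d individuals in %d neighborhoods (%dx%d lattice, seed %d)\n",
    nrow(x$cohort), n_nodes(x$graph),
    x$config$lattice_rows, x$config$lattice_cols, x$config$seed
  ))
  invisible(x)
}

#' Generate graded item responses for the ecometric model
#'
#' Simulates survey item responses with a cumulative-logit item model: the
#' latent propensity of individual i in neighborhood j is
#' `latent_scores[j] + e_i` with `e_i ~ Normal(0, sigma_individual^2)`, and
#' the response to item t falls in category c when
#' `latent + logistic error` lies between `thresholds[c-1] + intercept_t`
#' and `thresholds[c] + intercept_t`.
#'
#' @param cohort a cohort tibble (needs `individual_id`, `neighborhood_id`).
#' @param latent_scores named numeric vector of neighborhood latent scores;
#'   names are neighborhood ids (or unnamed in graph order matching the
#'   neighborhoods present).
#' @param item_model list as in [default_item_model()].
#' @param seed integer seed.
#' @return an item-response tibble (`neighborhood_id`, `individual_id`,
#'   `item_id`, `response`).
#' @export
generate_item_responses <- function(cohort, latent_scores,
                                    item_model = default_item_model(),
                                    seed = 1L) {
  n_items <- length(item_model$item_intercepts)
  if (n_items < 1L) {
    abort_recwalk("item model must contain at least one item.", "invalid_argument")
  }
  ids <- unique(cohort$neighborhood_id)
  if (is.null(names(latent_scores))) {
    if (length(latent_scores) != length(ids)) {
      abort_recwalk("`latent_scores` must cover every neighborhood in the cohort.",
                    "invalid_argument")
    }
    names(latent_scores) <- ids
  }
  if (!all(as.character(ids) %in% names(latent_scores))) {
    abort_recwalk("`latent_scores` must cover every neighborhood in the cohort.",
                  "invalid_argument")
  }
  thr <- item_model$thresholds
  with_seed(seed, {
    n <- nrow(cohort)
    e <- rnorm(n, 0, item_model$sigma_individual)
    base <- latent_scores[as.character(cohort$neighborhood_id)] + e
    out <- lapply(seq_len(n_items), function(t) {
      lat <- base + stats::rlogis(n)
      resp <- 1L + rowSums(outer(lat, thr + item_model$item_intercepts[t], `>`))
      tibble::tibble(
        neighborhood_id = cohort$neighborhood_id,
        individual_id = cohort$individual_id,
        item_id = t,
        response = as.integer(resp)
      )
    })
    dplyr::arrange(dplyr::bind_rows(out), .data$individual_id, .data$item_id)
  })
}

#' Read / write cohort tables and generator configs
#'
#' Cohort tables round-trip as plain CSV (factors re-leveled from the
#' catalogue); generator configurations as YAML.
#'
#' @param x a cohort tibble or `generator_config`.
#' @param path file path.
#' @return the read object, or `path` invisibly for writers.
#' @export
write_cohort_csv <- function(x, path) {
  if (inherits(x, "recwalk_cohort")) x <- x$cohort
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  catl <- covariate_catalogue()
  for (nm in intersect(names(df), names(catl))) {
    cv <- catl[[nm]]
    if (cv$type == "factor") {
      df[[nm]] <- factor(df[[nm]], levels = cv$levels)
    } else if (cv$type %in% c("quartile", "env_quartile")) {
      df[[nm]] <- factor(df[[nm]], levels = paste0("Q", 1:4))
    }
  }
  if ("recruitment_date" %in% names(df)) {
    df$recruitment_date <- as.Date(df$recruitment_date)
  }
  tibble::as_tibble(df)
}

#' @rdname write_cohort_csv
#' @export
write_generator_config <- function(x, path) {
  yaml::write_yaml(unclass(x), path, precision = 15L)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$true_betas <- lapply(raw$true_betas, as.numeric)
  do.call(generator_config, raw)
}
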