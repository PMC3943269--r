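#' Ecometric neighborhood scores from survey item responses
#'
#' Aggregates residents' graded answers about their neighborhood into
#' neighborhood-level latent scores with a multilevel cumulative-logit model:
#' items nested in individuals nested in neighborhoods (3-level), or, for a
#' single-item battery, responses nested in neighborhoods (2-level). Item
#' intercepts are fixed effects (first item is the reference), global
#' cutpoints carry the response scale, and the residual logistic scale fixes
#' the latent metric. Estimation uses the same Metropolis-within-Gibbs MCMC
#' machinery as the spatial outcome models, without a spatial term; scores
#' are posterior means of the neighborhood random intercepts (naturally
#' shrunken toward zero where data are thin).
#'
#' @param items an item-response table: columns `neighborhood_id`,
#'   `individual_id`, `item_id`, `response` (positive integer categories).
#' @param control an [mcmc_control()].
#' @param priors a [bym_priors()]; `sigma_u_scale` is the half-Normal scale
#'   of the neighborhood SD and the individual-level SD uses the same scale.
#' @return an `ecometric_scores` object: a tibble with one row per
#'   neighborhood (`neighborhood_id`, `score`, `score_se`) carrying the
#'   variance components (`var_neighborhood`, `var_individual`), the
#'   individual-effect posterior means, fitted cutpoints/item effects, and
#'   diagnostics-ready chains as attributes.
#' @export
fit_ecometric_3level <- function(items,
                                 control = mcmc_control(n_iter = 4000L, n_burnin = 1500L),
                                 priors = bym_priors()) {
  fit_ecometric(items, control, priors, levels = 3L)
}

#' @rdname fit_ecometric_3level
#' @export
fit_ecometric_2level <- function(items,
                                 control = mcmc_control(n_iter = 4000L, n_burnin = 1500L),
                                 priors = bym_priors()) {
  fit_ecometric(items, control, priors, levels = 2L)
}

fit_ecometric <- function(items, control, priors, levels) {
  items <- as.data.frame(items)
  need <- c("neighborhood_id", "individual_id", "item_id", "response")
  if (nrow(items) == 0L || !all(need %in% names(items))) {
    abort_recwalk(
      "`items` must be a nonempty table with neighborhood_id, individual_id, item_id, response.",
      "invalid_argument"
    )
  }
  if (anyDuplicated(items[c("individual_id", "item_id")])) {
    abort_recwalk("each (individual, item) pair may appear at most once.",
                  "invalid_argument")
  }
  item_levels <- sort(unique(items$item_id))
  if (levels == 2L && length(item_levels) > 1L) {
    abort_recwalk("multiple items supplied; use fit_ecometric_3level().",
                  "use_3_level")
  }
  if (levels == 3L && length(item_levels) < 2L) {
    abort_recwalk("the 3-level model needs at least 2 items.", "invalid_argument")
  }
  nb_levels <- unique(items$neighborhood_id)
  if (length(nb_levels) < 2L) {
    abort_recwalk("ecometric scores need at least 2 neighborhoods.",
                  "identifiability")
  }

  y <- as.integer(items$response)
  if (anyNA(y) || any(y < 1L)) {
    abort_recwalk("responses must be positive integer categories.", "invalid_argument")
  }
  K <- max(y)
  if (length(unique(y)) < 2L) {
    abort_recwalk("responses are constant; the latent scale is unidentified.",
                  "identifiability")
  }

  # item fixed effects, first item as reference
  if (length(item_levels) > 1L) {
    X <- stats::model.matrix(~ factor(item_id, levels = item_levels),
                             data = items)[, -1L, drop = FALSE]
    colnames(X) <- paste0("item_", item_levels[-1L])
  } else {
    X <- matrix(numeric(0), nrow = nrow(items), ncol = 0L)
  }

  nbhd0 <- match(items$neighborhood_id, nb_levels) - 1L
  use_w <- levels == 3L
  ind_levels <- unique(items$individual_id)
  indiv0 <- if (use_w) match(items$individual_id, ind_levels) - 1L else integer(0)

  seeds <- chain_seeds(control)
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    with_seed(seeds[ch], {
      raw <- bym_mcmc_cpp(
        y = y, X = X, nbhd = nbhd0, J = length(nb_levels),
        indiv = indiv0, M = if (use_w) length(ind_levels) else 0L,
        adj = integer(0), adj_start = integer(length(nb_levels) + 1L),
        ordinal = TRUE, K = K,
        use_u = TRUE, use_v = FALSE, use_w = use_w,
        intercept_col = -1L,
        beta_prior_sd = priors$beta_sd,
        sigma_u_scale = priors$sigma_u_scale,
        tau_v_scale = 1e-12,
        sigma_w_scale = priors$sigma_u_scale,
        n_iter = control$n_iter, n_burnin = control$n_burnin,
        thin = control$thin
      )
      raw
    })
  })

  u_all <- do.call(rbind, lapply(chains, `[[`, "u"))
  sigma_nb <- do.call(c, lapply(chains, function(ch) as.numeric(ch$sigma_u)))
  sigma_ind <- do.call(c, lapply(chains, function(ch) as.numeric(ch$sigma_w)))
  w_mean <- Reduce(`+`, lapply(chains, `[[`, "w_mean")) / length(chains)
  kappa <- do.call(rbind, lapply(chains, function(ch) ch$kappa))
  beta <- do.call(rbind, lapply(chains, function(ch) ch$beta))

  pairs <- unique(items[c("neighborhood_id", "individual_id")])
  n_ind <- table(factor(pairs$neighborhood_id, levels = nb_levels))
  out <- tibble::tibble(
    neighborhood_id = nb_levels,
    score = colMeans(u_all),
    score_se = apply(u_all, 2L, stats::sd),
    n_individuals = as.integer(n_ind)
  )
  out <- out[order(out$neighborhood_id), ]
  attr(out, "var_neighborhood") <- stats::median(sigma_nb^2)
  attr(out, "var_individual") <- if (use_w) stats::median(sigma_ind^2) else NA_real_
  attr(out, "cutpoints") <- if (K > 2L) colMeans(kappa)[seq_len(K - 1L)] else NULL
  attr(out, "item_effects") <- if (ncol(X) > 0L) setNames(colMeans(beta), colnames(X)) else numeric(0)
  attr(out, "item_levels") <- item_levels
  attr(out, "individual_effects") <- tibble::tibble(
    individual_id = ind_levels,
    effect = if (use_w) as.numeric(w_mean) else rep(0, length(ind_levels))
  )
  attr(out, "n_categories") <- K
  attr(out, "sigma_chains") <- list(neighborhood = sigma_nb, individual = sigma_ind)
  attr(out, "levels") <- levels
  class(out) <- c("ecometric_scores", class(out))
  out
}

#' @export
print.ecometric_scores <- function(x, ...) {
  cat(sprintf(
    "<ecometric_scores> %d neighborhoods (%d-level fit); var components: neighborhood %.3f, individual %s\n",
    nrow(x), attr(x, "levels"), attr(x, "var_neighborhood"),
    if (is.na(attr(x, "var_individual"))) "-" else sprintf("%.3f", attr(x, "var_individual"))
  ))
  NextMethod()
}

# expected value of a standard logistic variable truncated to (a, b):
# antiderivative of x * dlogis(x) is x * plogis(x) + log(1 - plogis(x))
truncated_logistic_mean <- function(a, b) {
  Fint <- function(x) {
    ifelse(is.infinite(x),
           ifelse(x > 0, 0, 0),
           x * plogis(x) + plogis(x, log.p = TRUE, lower.tail = FALSE))
  }
  p <- plogis(b) - plogis(a)
  ifelse(p <= 0, (a + b) / 2, (Fint(b) - Fint(a)) / p)
}

#' Leave-one-out ecometric neighborhood scores
#'
#' For each cohort individual, recomputes their neighborhood's score from the
#' other residents' responses only, so that the score attached to an
#' individual's outcome never contains their own answers (the standard guard
#' against same-source bias). Uses an empirical-Bayes linearization of the
#' fitted model: each response is converted to a conditional latent mean
#' (truncated-logistic expectation given the fitted cutpoints and item
#' effects), individual-level signals are averaged, and the neighborhood mean
#' is re-shrunk with the fitted variance components. The analogous full-data
#' empirical-Bayes score is returned for like-with-like comparison.
#'
#' @param scores an `ecometric_scores` from [fit_ecometric_3level()].
#' @param items the item-response table the model was fitted to.
#' @param cohort cohort tibble (`individual_id`, `neighborhood_id`); defaults
#'   to the individuals present in `items`.
#' @return tibble with one row per individual: `individual_id`,
#'   `neighborhood_id`, `score_full` (MCMC posterior mean),
#'   `score_full_eb` (empirical-Bayes full score), `score_loo` (leave-one-out
#'   score; `NA` for single-respondent neighborhoods).
#' @export
loo_scores <- function(scores, items, cohort = NULL) {
  if (!inherits(scores, "ecometric_scores")) {
    abort_recwalk("`scores` must come from fit_ecometric_3level().", "invalid_argument")
  }
  items <- as.data.frame(items)
  if (is.null(cohort)) {
    cohort <- unique(items[c("individual_id", "neighborhood_id")])
  }
  cohort <- as.data.frame(cohort)[c("individual_id", "neighborhood_id")]

  K <- attr(scores, "n_categories")
  kappa <- attr(scores, "cutpoints")
  item_eff <- attr(scores, "item_effects")
  item_levels <- attr(scores, "item_levels")
  var_nb <- attr(scores, "var_neighborhood")
  var_ind <- attr(scores, "var_individual")
  if (is.na(var_ind)) var_ind <- 0

  # latent pseudo-signal per response: E[theta + eps | category], theta flat
  alpha <- setNames(rep(0, length(item_levels)), item_levels)
  if (length(item_eff)) alpha[as.character(item_levels[-1L])] <- item_eff
  bounds <- c(-Inf, if (K > 2L) kappa else 0, Inf)
  a <- bounds[items$response] - alpha[as.character(items$item_id)]
  b <- bounds[items$response + 1L] - alpha[as.character(items$item_id)]
  z <- truncated_logistic_mean(a, b)

  per_ind <- stats::aggregate(
    list(z = z), by = list(individual_id = items$individual_id,
                           neighborhood_id = items$neighborhood_id),
    FUN = mean
  )
  n_items_per <- stats::aggregate(
    list(t = z), by = list(individual_id = items$individual_id), FUN = length
  )
  per_ind$t <- n_items_per$t[match(per_ind$individual_id, n_items_per$individual_id)]

  # measurement variance of an individual's mean signal
  per_ind$meas_var <- var_ind + (pi^2 / 3) / per_ind$t

  shrink <- function(zbar, m, meas_var) {
    if (m < 1L) return(NA_real_)
    lambda <- var_nb / (var_nb + meas_var / m)
    lambda * zbar
  }

  out <- lapply(seq_len(nrow(cohort)), function(r) {
    id <- cohort$individual_id[r]
    nb <- cohort$neighborhood_id[r]
    grp <- per_ind[per_ind$neighborhood_id == nb, ]
    full_eb <- shrink(mean(grp$z), nrow(grp), mean(grp$meas_var))
    others <- grp[grp$individual_id != id, ]
    contributed <- id %in% grp$individual_id
    loo <- if (!contributed) {
      full_eb
    } else if (nrow(others) == 0L) {
      NA_real_
    } else {
      shrink(mean(others$z), nrow(others), mean(others$meas_var))
    }
    c(full_eb = full_eb %||% NA_real_, loo = loo)
  })
  out <- do.call(rbind, out)

  tibble::tibble(
    individual_id = cohort$individual_id,
    neighborhood_id = cohort$neighborhood_id,
    score_full = scores$score[match(cohort$neighborhood_id, scores$neighborhood_id)],
    score_full_eb = out[, "full_eb"],
    score_loo = out[, "loo"]
  )
}
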