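#' MCMC settings
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter total iterations per chain, including burn-in.
#' @param n_burnin iterations discarded as burn-in (`< n_iter`); proposal
#'   scales adapt only during burn-in.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; per-chain streams are derived from it.
#' @return an `mcmc_control` list.
#' @export
mcmc_control <- function(n_chains = 2L, n_iter = 6000L, n_burnin = 2000L,
                         thin = 2L, seed = 1L) {
  if (n_iter <= n_burnin) {
    abort_recwalk("`n_iter` must exceed `n_burnin`.", "invalid_argument")
  }
  if (thin < 1L || n_chains < 1L) {
    abort_recwalk("`thin` and `n_chains` must be positive.", "invalid_argument")
  }
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         n_burnin = as.integer(n_burnin), thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "mcmc_control"
  )
}

#' Prior settings for the convolution models
#'
#' Fixed effects and ordinal cutpoint anchors get Normal(0, `beta_sd`^2)
#' priors; the unstructured SD `sigma_u` and the CAR conditional SD `tau_v`
#' get half-Normal priors with the given scales. Setting a scale to 0 removes
#' that random effect from the model (the effect is fixed at zero).
#'
#' @param beta_sd Normal prior SD for regression coefficients and cutpoints.
#' @param sigma_u_scale half-Normal scale for the exchangeable effect SD.
#' @param tau_v_scale half-Normal scale for the CAR conditional SD.
#' @return a `bym_priors` list.
#' @export
bym_priors <- function(beta_sd = 10, sigma_u_scale = 1, tau_v_scale = 1) {
  if (beta_sd <= 0 || sigma_u_scale < 0 || tau_v_scale < 0) {
    abort_recwalk("prior scales must be nonnegative (`beta_sd` positive).",
                  "invalid_argument")
  }
  structure(list(beta_sd = beta_sd, sigma_u_scale = sigma_u_scale,
                 tau_v_scale = tau_v_scale),
            class = "bym_priors")
}

# derive independent per-chain seeds from the control seed
chain_seeds <- function(control) {
  with_seed(control$seed, sample.int(.Machine$integer.max - 1L, control$n_chains))
}

# shared front end for both outcome types
fit_bym <- function(data, formula, graph, control, priors, ordinal) {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y_raw <- stats::model.response(mf)
  trms <- attr(mf, "terms")

  if (ordinal) {
    y <- as.integer(y_raw)
    if (anyNA(y) || any(y < 1L)) {
      abort_recwalk("ordinal outcome must be coded as positive integers 1..K.",
                    "invalid_argument")
    }
    K <- max(y)
    if (length(unique(y)) < 3L) {
      abort_recwalk("ordinal outcome has fewer than 3 observed categories.",
                    "category_support")
    }
    if (!all(seq_len(K) %in% y)) {
      rlang::warn(paste(
        "some ordinal categories are unobserved;",
        "the corresponding cutpoints are weakly identified."
      ))
    }
    X <- stats::model.matrix(trms, mf)
    icol <- match("(Intercept)", colnames(X))
    if (!is.na(icol)) X <- X[, -icol, drop = FALSE] # cutpoints take its place
  } else {
    y <- as.integer(y_raw)
    if (anyNA(y) || !all(y %in% c(0L, 1L))) {
      abort_recwalk("binary outcome must be coded 0/1.", "invalid_argument")
    }
    K <- 2L
    X <- stats::model.matrix(trms, mf)
  }

  if (!("neighborhood_id" %in% names(data))) {
    abort_recwalk("`data` must have a `neighborhood_id` column.", "invalid_argument")
  }
  nbhd_ids <- data$neighborhood_id[as.integer(rownames(mf))]
  if (length(nbhd_ids) != length(y)) nbhd_ids <- data$neighborhood_id
  if (!all(nbhd_ids %in% graph$node_ids)) {
    abort_recwalk("some neighborhood_id values are absent from the adjacency graph.",
                  "invalid_argument")
  }
  # index neighborhoods by first appearance so relabelings that preserve row
  # order produce bit-identical chains
  nb_levels <- unique(nbhd_ids)
  nbhd0 <- match(nbhd_ids, nb_levels) - 1L
  J <- length(nb_levels)

  # adjacency restricted to observed neighborhoods, in first-appearance order
  sub <- subgraph_for(graph, nb_levels)
  use_v <- priors$tau_v_scale > 0 && J >= 2L && length(sub$adj) > 0L
  use_u <- priors$sigma_u_scale > 0
  if (priors$tau_v_scale > 0 && !use_v && J >= 2L) {
    rlang::warn("no contiguity edges among observed neighborhoods; CAR effect dropped.")
  }

  icol_c <- if (!ordinal) match("(Intercept)", colnames(X)) - 1L else -1L
  if (is.na(icol_c)) icol_c <- -1L

  seeds <- chain_seeds(control)
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    with_seed(seeds[ch], {
      raw <- bym_mcmc_cpp(
        y = y, X = X, nbhd = nbhd0, J = J,
        indiv = integer(0), M = 0L,
        adj = sub$adj, adj_start = sub$start,
        ordinal = ordinal, K = K,
        use_u = use_u, use_v = use_v, use_w = FALSE,
        intercept_col = icol_c,
        beta_prior_sd = priors$beta_sd,
        sigma_u_scale = max(priors$sigma_u_scale, 1e-12),
        tau_v_scale = max(priors$tau_v_scale, 1e-12),
        sigma_w_scale = 1e-12,
        n_iter = control$n_iter, n_burnin = control$n_burnin,
        thin = control$thin
      )
      tidy_chain(raw, colnames(X), J, K, ordinal, use_u, use_v)
    })
  })

  structure(
    list(
      chains = chains,
      outcome = if (ordinal) "ordinal" else "binary",
      formula = formula,
      terms = trms,
      term_assign = term_columns(trms, X, ordinal),
      coef_names = colnames(X),
      neighborhood_levels = nb_levels,
      graph = graph,
      n_obs = length(y),
      n_categories = K,
      use_u = use_u, use_v = use_v,
      priors = priors, control = control
    ),
    class = "bym_fit"
  )
}

# restrict the adjacency structure to the neighborhoods present in the data,
# returned as 0-based concatenated lists in `levels` order
subgraph_for <- function(graph, levels) {
  keep <- graph$edges$from %in% levels & graph$edges$to %in% levels
  e <- graph$edges[keep, , drop = FALSE]
  J <- length(levels)
  nb <- vector("list", J)
  fi <- match(e$from, levels)
  ti <- match(e$to, levels)
  for (k in seq_along(fi)) {
    nb[[fi[k]]] <- c(nb[[fi[k]]], ti[k])
    nb[[ti[k]]] <- c(nb[[ti[k]]], fi[k])
  }
  nb <- lapply(nb, function(x) sort(unique(x)) - 1L)
  list(adj = as.integer(unlist(nb, use.names = FALSE)),
       start = c(0L, cumsum(vapply(nb, length, integer(1)))))
}

tidy_chain <- function(raw, coef_names, J, K, ordinal, use_u, use_v) {
  beta <- raw$beta
  colnames(beta) <- coef_names
  out <- list(
    beta = beta,
    sigma_u = as.numeric(raw$sigma_u),
    tau_v = as.numeric(raw$tau_v),
    u = if (use_u) raw$u else matrix(0, nrow(beta), J),
    v = if (use_v) raw$v else matrix(0, nrow(beta), J)
  )
  if (ordinal) {
    kappa <- raw$kappa[, seq_len(K - 1L), drop = FALSE]
    colnames(kappa) <- paste0("kappa_", seq_len(K - 1L))
    out$kappa <- kappa
  }
  out
}

# map model terms to model-matrix columns (used by selection steps)
term_columns <- function(trms, X, ordinal) {
  labels <- attr(trms, "term.labels")
  assign <- attr(X, "assign")
  if (is.null(assign)) return(NULL)
  if (!ordinal) {
    # intercept keeps assign == 0
    split(colnames(X)[assign != 0], labels[assign[assign != 0]])
  } else {
    split(colnames(X)[assign != 0], labels[assign[assign != 0]])
  }
}

#' Fit the convolution (BYM) logistic model
#'
#' Models a binary outcome with `logit P(y = 1) = x'beta + u_j + v_j`, where
#' `u_j` is an exchangeable Normal neighborhood effect and `v_j` an intrinsic
#' CAR effect on the contiguity graph, identified by sum-to-zero recentering
#' at every sweep. Estimation is by adaptive Metropolis-within-Gibbs MCMC.
#'
#' @param data a cohort data frame with a `neighborhood_id` column and the
#'   model variables.
#' @param formula model formula; the response must be 0/1.
#' @param graph a [nbhd_graph()] covering every neighborhood in `data`.
#' @param control an [mcmc_control()].
#' @param priors a [bym_priors()].
#' @return a `bym_fit`: per-chain posterior draws of the coefficients,
#'   variance parameters and both neighborhood effect vectors, plus model
#'   metadata. Summarize with [tidy()][generics::tidy],
#'   [glance()][generics::glance], [decompose()], [check_convergence()].
#' @examples
#' \donttest{
#' g <- make_lattice(4, 4)
#' cohort <- generate_cohort(generator_config(
#'   lattice_rows = 4, lattice_cols = 4, n_individuals = 320, seed = 1
#' ))$cohort
#' fit <- fit_bym_logistic(cohort, walk_any ~ male, g,
#'   control = mcmc_control(n_iter = 600, n_burnin = 300, seed = 1)
#' )
#' tidy(fit)
#' }
#' @export
fit_bym_logistic <- function(data, formula, graph,
                             control = mcmc_control(),
                             priors = bym_priors()) {
  fit_bym(data, formula, graph, control, priors, ordinal = FALSE)
}

#' Fit the convolution (BYM) cumulative-logit model
#'
#' Proportional-odds model for an ordinal outcome coded 1..K:
#' `logit P(y <= c) = kappa_c - (x'beta + u_j + v_j)` with ordered cutpoints
#' `kappa` (no intercept) and the same convolution random-effect structure as
#' [fit_bym_logistic()].
#'
#' @inheritParams fit_bym_logistic
#' @return a `bym_fit`; cutpoint draws are in element `kappa` of each chain.
#' @export
fit_bym_ordinal <- function(data, formula, graph,
                            control = mcmc_control(),
                            priors = bym_priors()) {
  fit_bym(data, formula, graph, control, priors, ordinal = TRUE)
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf(
    "<bym_fit> %s outcome, %d obs in %d neighborhoods; %d chains x %d saved draws\n",
    x$outcome, x$n_obs, length(x$neighborhood_levels),
    length(x$chains), nrow(x$chains[[1]]$beta)
  ))
  print(tidy(x))
  invisible(x)
}

# stack all scalar parameters into an iterations x parameters matrix per chain
bym_parameter_matrices <- function(fit, include_effects = FALSE) {
  lapply(fit$chains, function(ch) {
    m <- cbind(ch$beta,
               if (!is.null(ch$kappa)) ch$kappa,
               sigma_u = ch$sigma_u, tau_v = ch$tau_v)
    if (include_effects) {
      u <- ch$u; colnames(u) <- paste0("u_", seq_len(ncol(u)))
      v <- ch$v; colnames(v) <- paste0("v_", seq_len(ncol(v)))
      m <- cbind(m, u, v)
    }
    m
  })
}

# pooled draws of one component across chains
bym_pooled <- function(fit, what) {
  parts <- lapply(fit$chains, `[[`, what)
  if (is.matrix(parts[[1]])) do.call(rbind, parts) else do.call(c, parts)
}
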