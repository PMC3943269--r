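# shared small fixtures, built in code

# dense adjacency matrix of a nbhd_graph (for independent Moran's I checks)
adjacency_matrix <- function(graph) {
  J <- n_nodes(graph)
  W <- matrix(0, J, J)
  i <- match(graph$edges$from, graph$node_ids)
  k <- match(graph$edges$to, graph$node_ids)
  for (e in seq_along(i)) {
    W[i[e], k[e]] <- 1
    W[k[e], i[e]] <- 1
  }
  W
}

# a small cohort used by several model tests (memoized per test run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(generator_config(
        lattice_rows = 6, lattice_cols = 6, n_individuals = 1080,
        true_betas = list(male = log(1.5)),
        sigma_u = 0.25, tau_v = 0.4, missing_rate = 0, seed = 101
      ))
    }
    cache
  }
})

fast_ctrl <- function(seed = 7, n_chains = 2) {
  mcmc_control(n_chains = n_chains, n_iter = 1200, n_burnin = 500,
               thin = 2, seed = seed)
}

# build an item-response fixture with known neighborhood latents
item_fixture <- function(n_nbhd = 12, n_per = 8, latent_sd = 0.8,
                         n_items = 3, seed = 5) {
  set.seed(seed)
  truth <- rnorm(n_nbhd, 0, latent_sd)
  cohort <- tibble::tibble(
    individual_id = seq_len(n_nbhd * n_per),
    neighborhood_id = rep(seq_len(n_nbhd), each = n_per)
  )
  im <- default_item_model()
  im$item_intercepts <- im$item_intercepts[seq_len(n_items)]
  items <- generate_item_responses(cohort, setNames(truth, seq_len(n_nbhd)),
                                   im, seed = seed + 1)
  list(items = items, cohort = cohort, truth = truth, item_model = im)
}
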