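#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a convolution model fit
#'
#' @param x a `bym_fit`.
#' @param exponentiate report odds ratios instead of log odds ratios.
#' @param conf.level credible-interval mass (equal-tailed).
#' @param ... unused.
#' @return a tibble with one row per scalar parameter: `term`, `estimate`
#'   (posterior median), `std.error` (posterior SD), `conf.low`, `conf.high`,
#'   `rhat`, `ess`.
#' @method tidy bym_fit
#' @export
tidy.bym_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  mats <- bym_parameter_matrices(x)
  pooled <- do.call(rbind, mats)
  probs <- c((1 - conf.level) / 2, 1 - (1 - conf.level) / 2)
  conv <- suppressWarnings(
    if (length(mats) >= 2L) check_convergence(x) else NULL
  )
  params <- colnames(pooled)
  out <- tibble::tibble(
    term = params,
    estimate = apply(pooled, 2L, stats::median),
    std.error = apply(pooled, 2L, stats::sd),
    conf.low = apply(pooled, 2L, stats::quantile, probs = probs[1], names = FALSE),
    conf.high = apply(pooled, 2L, stats::quantile, probs = probs[2], names = FALSE)
  )
  if (!is.null(conv)) {
    out$rhat <- conv$rhat[match(out$term, conv$parameter)]
    out$ess <- conv$ess[match(out$term, conv$parameter)]
  }
  if (exponentiate) {
    sdpar <- out$term %in% c("sigma_u", "tau_v")
    out$estimate[!sdpar] <- exp(out$estimate[!sdpar])
    out$conf.low[!sdpar] <- exp(out$conf.low[!sdpar])
    out$conf.high[!sdpar] <- exp(out$conf.high[!sdpar])
  }
  out
}

#' One-row model summary
#'
#' @param x a `bym_fit`.
#' @param ... unused.
#' @return a tibble with sample sizes, draw counts, and worst-case
#'   convergence diagnostics.
#' @method glance bym_fit
#' @export
glance.bym_fit <- function(x, ...) {
  conv <- suppressWarnings(
    if (length(x$chains) >= 2L) check_convergence(x) else NULL
  )
  tibble::tibble(
    outcome = x$outcome,
    nobs = x$n_obs,
    n_neighborhoods = length(x$neighborhood_levels),
    n_chains = length(x$chains),
    n_draws = nrow(x$chains[[1]]$beta) * length(x$chains),
    max_rhat = if (is.null(conv)) NA_real_ else max(conv$rhat, na.rm = TRUE),
    min_ess = if (is.null(conv)) NA_real_ else min(conv$ess, na.rm = TRUE),
    converged = if (is.null(conv)) NA else attr(conv, "pass")
  )
}

#' Posterior means of the neighborhood effects
#'
#' @param fit a `bym_fit`.
#' @return tibble with `neighborhood_id`, posterior means `u` (unstructured)
#'   and `v` (spatially structured), and the combined effect.
#' @export
neighborhood_effects <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  u <- colMeans(bym_pooled(fit, "u"))
  v <- colMeans(bym_pooled(fit, "v"))
  tibble::tibble(
    neighborhood_id = fit$neighborhood_levels,
    u = u, v = v, total = u + v
  )
}

#' Forest plot of posterior odds ratios
#'
#' @param object a `bym_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bym_fit
#' @export
autoplot.bym_fit <- function(object, ...) {
  td <- tidy(object, exponentiate = TRUE)
  td <- td[!td$term %in% c("sigma_u", "tau_v", "(Intercept)") &
             !startsWith(td$term, "kappa_"), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CrI)", y = NULL)
}

#' Dot-and-interval plot of a variance decomposition
#'
#' @param object a `recwalk_decomposition`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot recwalk_decomposition
#' @export
autoplot.recwalk_decomposition <- function(object, ...) {
  iq <- object[object$component != "pct_structured", ]
  ggplot2::ggplot(iq, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Interquartile odds ratio (95% CrI)")
}

#' Choropleth of a neighborhood-level quantity on the lattice
#'
#' @param graph a [nbhd_graph()] with lattice cells attached.
#' @param values numeric vector, either named by node id or in
#'   `graph$node_ids` order.
#' @param title optional plot title.
#' @return a ggplot tile map.
#' @export
plot_spatial_effects <- function(graph, values, title = NULL) {
  if (is.null(graph$cells)) {
    abort_recwalk("graph has no lattice cells; cannot draw a choropleth.",
                  "invalid_argument")
  }
  if (!is.null(names(values))) {
    values <- values[as.character(graph$node_ids)]
  }
  df <- graph$cells
  df$value <- as.numeric(values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "effect") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
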