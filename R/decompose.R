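#' Convert a random-effect SD to an interquartile odds ratio
#'
#' The interquartile odds ratio (IqOR) expresses a between-neighborhood
#' standard deviation on the log-odds scale as the odds-ratio contrast
#' between individuals in the 25% of neighborhoods with the highest effects
#' and the 25% with the lowest: `IqOR = exp(2 * k * sigma)` where
#' `k = dnorm(qnorm(0.75)) / 0.25 ~= 1.27110` is the mean of the upper
#' quartile of a standard Normal.
#'
#' @param sigma nonnegative random-effect SD (vectorized).
#' @return odds ratio(s) `>= 1`.
#' @examples
#' sd_to_iqor(0.3)
#' @export
sd_to_iqor <- function(sigma) {
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma < 0)) {
    abort_recwalk("`sigma` must be nonnegative.", "invalid_argument")
  }
  exp(2 * K_IQOR * sigma)
}

# inverse map, used when combining printed IqOR components
iqor_to_sd <- function(iqor) log(iqor) / (2 * K_IQOR)

#' Empirical SD of the spatially structured effects, per iteration
#'
#' The marginal spread of an intrinsic CAR field is not its conditional SD
#' `tau`; the structured component of the between-neighborhood variance is
#' therefore measured empirically as the across-neighborhood sample SD of the
#' CAR effects at each MCMC iteration.
#'
#' @param v_draws matrix of CAR effects, iterations in rows, neighborhoods in
#'   columns (a plain vector is treated as a single iteration).
#' @return numeric vector, one SD per iteration.
#' @examples
#' empirical_structured_sd(c(-1, 1))
#' @export
empirical_structured_sd <- function(v_draws) {
  if (is.vector(v_draws)) v_draws <- matrix(v_draws, nrow = 1L)
  if (ncol(v_draws) < 2L) {
    abort_recwalk("need at least 2 neighborhoods to compute a spread.", "invalid_argument")
  }
  apply(v_draws, 1L, stats::sd)
}

#' Combine unstructured and structured IqORs
#'
#' Squared log-IqORs add like variances (the quartile-contrast constant
#' cancels): the total IqOR is `exp(sqrt(ln^2 u + ln^2 s))` and the share of
#' between-neighborhood variance that is spatially structured is
#' `100 * ln^2 s / (ln^2 u + ln^2 s)`.
#'
#' @param iqor_u unstructured-component IqOR (`>= 1`).
#' @param iqor_s structured-component IqOR (`>= 1`).
#' @return a tibble with columns `iqor_total` and `pct_structured`.
#' @examples
#' combine_iqors(1.56, 1.77)
#' @export
combine_iqors <- function(iqor_u, iqor_s) {
  if (!is.numeric(iqor_u) || !is.numeric(iqor_s) ||
      anyNA(iqor_u) || anyNA(iqor_s) || any(iqor_u < 1) || any(iqor_s < 1)) {
    abort_recwalk("IqORs must be numeric and >= 1.", "invalid_argument")
  }
  lu2 <- log(iqor_u)^2
  ls2 <- log(iqor_s)^2
  tot2 <- lu2 + ls2
  pct <- ifelse(tot2 == 0, 0, 100 * ls2 / tot2)
  tibble::tibble(iqor_total = exp(sqrt(tot2)), pct_structured = pct)
}

#' Decompose posterior between-neighborhood variation into IqORs
#'
#' For each saved MCMC iteration, takes the unstructured SD (`sigma_u` draw)
#' and the empirical SD of the CAR effects, forms the total SD
#' `sqrt(s_u^2 + s_v^2)` and the structured share `100 * s_v^2 / total^2`,
#' maps the SDs through [sd_to_iqor()], and summarizes each quantity by its
#' posterior median and equal-tailed 95% credible interval.
#'
#' @param samples a `bym_fit` from [fit_bym_logistic()] or [fit_bym_ordinal()],
#'   or a list with elements `sigma_u` (vector of draws) and `v` (draw matrix,
#'   iterations x neighborhoods).
#' @param probs credible-interval tail probabilities.
#' @return a `recwalk_decomposition`: a tibble with one row per component
#'   (`iqor_unstructured`, `iqor_structured`, `iqor_total`, `pct_structured`)
#'   and columns `estimate` (posterior median), `conf.low`, `conf.high`.
#' @export
decompose <- function(samples, probs = c(0.025, 0.975)) {
  comp <- decompose_components(samples)
  s_u <- comp$sigma_u
  v <- comp$v
  if (is.null(s_u) || is.null(v)) {
    abort_recwalk(
      "`samples` must provide sigma_u draws and CAR effect draws (v).",
      "contract"
    )
  }
  if (is.vector(v)) v <- matrix(v, ncol = length(v))
  if (length(s_u) != nrow(v)) {
    abort_recwalk("sigma_u draws and v draws have different iteration counts.", "contract")
  }
  s_v <- empirical_structured_sd(v)
  tot2 <- s_u^2 + s_v^2
  pct <- ifelse(tot2 == 0, 0, 100 * s_v^2 / tot2)
  summarize_draws <- function(x) {
    qs <- stats::quantile(x, probs = probs, names = FALSE)
    c(estimate = stats::median(x), conf.low = qs[1], conf.high = qs[2])
  }
  rows <- rbind(
    iqor_unstructured = summarize_draws(sd_to_iqor(s_u)),
    iqor_structured = summarize_draws(sd_to_iqor(s_v)),
    iqor_total = summarize_draws(sd_to_iqor(sqrt(tot2))),
    pct_structured = summarize_draws(pct)
  )
  out <- tibble::tibble(
    component = rownames(rows),
    estimate = unname(rows[, "estimate"]),
    conf.low = unname(rows[, "conf.low"]),
    conf.high = unname(rows[, "conf.high"])
  )
  class(out) <- c("recwalk_decomposition", class(out))
  out
}

# accept either a bym_fit or a bare list of draws
decompose_components <- function(samples) {
  if (inherits(samples, "bym_fit")) {
    list(
      sigma_u = do.call(c, lapply(samples$chains, function(ch) ch$sigma_u)),
      v = do.call(rbind, lapply(samples$chains, function(ch) ch$v))
    )
  } else if (is.list(samples)) {
    list(sigma_u = samples$sigma_u, v = samples$v)
  } else {
    abort_recwalk("`samples` must be a bym_fit or a list of draws.", "contract")
  }
}

#' @export
print.recwalk_decomposition <- function(x, ...) {
  cat("Between-neighborhood variance decomposition (posterior median [95% CrI])\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-18s %6.2f [%5.2f, %5.2f]\n",
      x$component[i], x$estimate[i], x$conf.low[i], x$conf.high[i]
    ))
  }
  invisible(x)
}
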