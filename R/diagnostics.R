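# split-Rhat: split each chain in half, compare between/within half-chain
# variances (pooled-variance formulation)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2) * 2
    x <- x[seq_len(n)]
    list(x[seq_len(n / 2)], x[n / 2 + seq_len(n / 2)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) {
    return(if (stats::var(means) == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size from pooled autocorrelations, Geyer's initial
# positive sequence truncation, averaged across chains
ess_geyer <- function(chains) {
  n <- min(lengths(chains))
  m <- length(chains)
  if (n < 4) return(NA_real_)
  acovs <- lapply(chains, function(x) {
    x <- x[seq_len(n)]
    stats::acf(x, lag.max = min(n - 1, 500), type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  acov <- Reduce(`+`, acovs) / m
  if (acov[1] == 0) return(NA_real_)
  rho <- acov / acov[1]
  # integrated autocorrelation time: -1 + 2 * sum of adjacent-lag pairs
  # (rho_{2k} + rho_{2k+1}), truncated at the first negative pair
  pair_sum <- 0
  k <- 0
  repeat {
    i1 <- 2 * k + 1 # 1-based index of rho_{2k}
    i2 <- 2 * k + 2 # rho_{2k+1}
    if (i2 > length(rho)) break
    p <- rho[i1] + rho[i2]
    if (p < 0) break
    pair_sum <- pair_sum + p
    k <- k + 1
  }
  tau_int <- max(-1 + 2 * pair_sum, 1e-12)
  min(m * n / tau_int, m * n)
}

#' Convergence diagnostics for a fitted model
#'
#' Computes split-R-hat and an autocorrelation-based effective sample size
#' for every scalar model parameter (coefficients, cutpoints, `sigma_u`,
#' `tau_v`), and flags the fit as passing when all R-hat values are below
#' `rhat_max` and all effective sample sizes exceed `ess_min`.
#'
#' @param fit a `bym_fit` (needs >= 2 chains), or a list of equal-length
#'   numeric vectors (one chain each) for a single parameter.
#' @param rhat_max split-R-hat threshold (default 1.1).
#' @param ess_min effective-sample-size threshold (default 100).
#' @return a `recwalk_convergence` tibble with columns `parameter`, `rhat`,
#'   `ess`, `ok`, carrying attributes `pass`, `rhat_max`, `ess_min`.
#' @export
check_convergence <- function(fit, rhat_max = 1.1, ess_min = 100) {
  if (inherits(fit, "bym_fit")) {
    if (length(fit$chains) < 2L) {
      abort_recwalk("convergence diagnostics need at least 2 chains.",
                    "insufficient_chains")
    }
    mats <- bym_parameter_matrices(fit)
    params <- colnames(mats[[1]])
    rows <- lapply(params, function(p) {
      chains <- lapply(mats, function(m) m[, p])
      # fixed-at-zero components show as constant chains; skip them
      if (all(vapply(chains, function(x) stats::var(x) == 0, logical(1)))) {
        return(NULL)
      }
      tibble::tibble(parameter = p,
                     rhat = split_rhat(chains),
                     ess = ess_geyer(chains))
    })
    out <- dplyr::bind_rows(rows)
  } else if (is.list(fit) && all(vapply(fit, is.numeric, logical(1)))) {
    if (length(fit) < 2L) {
      abort_recwalk("convergence diagnostics need at least 2 chains.",
                    "insufficient_chains")
    }
    out <- tibble::tibble(parameter = "x",
                          rhat = split_rhat(fit),
                          ess = ess_geyer(fit))
  } else {
    abort_recwalk("`fit` must be a bym_fit or a list of chain vectors.",
                  "invalid_argument")
  }
  out$ok <- is.finite(out$rhat) & out$rhat < rhat_max & out$ess > ess_min
  attr(out, "pass") <- all(out$ok)
  attr(out, "rhat_max") <- rhat_max
  attr(out, "ess_min") <- ess_min
  class(out) <- c("recwalk_convergence", class(out))
  out
}

#' @export
print.recwalk_convergence <- function(x, ...) {
  cat(sprintf("Convergence: %s (split-Rhat < %.2f, ESS > %g)\n",
              if (attr(x, "pass")) "PASS" else "FAIL",
              attr(x, "rhat_max"), attr(x, "ess_min")))
  NextMethod()
}
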