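# Fast approximate fits used where full MCMC would be wasteful: variable
# screening, one-by-one exposure pretests, interaction scans, and the
# bootstrap refits. Binary outcomes get a penalized-likelihood multilevel
# logistic fit (ridge-penalized neighborhood intercepts, PQL-style variance
# update); ordinal outcomes get a plain proportional-odds fit (MASS::polr,
# no neighborhood term). Wald intervals stand in for credible intervals.

approx_logistic <- function(data, formula, sigma_u = NULL, max_outer = 8L) {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  nb <- factor(data$neighborhood_id)
  J <- nlevels(nb)
  Z <- stats::model.matrix(~ nb - 1)
  A <- cbind(X, Z)
  p <- ncol(X)
  n <- nrow(X)

  est_sigma <- is.null(sigma_u)
  sigma2 <- if (est_sigma) 0.25 else sigma_u^2
  theta <- rep(0, ncol(A))
  theta[1] <- qlogis(pmin(pmax(mean(y), 0.02), 0.98))

  fit_inner <- function(sigma2, theta) {
    pen <- c(rep(0, p), rep(1 / max(sigma2, 1e-8), J))
    for (it in 1:25) {
      eta <- drop(A %*% theta)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-8)
      z <- eta + (y - mu) / w
      AtW <- t(A * w)
      H <- AtW %*% A
      diag(H) <- diag(H) + pen
      theta_new <- solve(H, AtW %*% z)
      if (max(abs(theta_new - theta)) < 1e-8) {
        theta <- drop(theta_new)
        break
      }
      theta <- drop(theta_new)
    }
    list(theta = theta, H = H)
  }

  res <- fit_inner(sigma2, theta)
  if (est_sigma) {
    for (o in seq_len(max_outer)) {
      u <- res$theta[p + seq_len(J)]
      Hin <- solve(res$H)
      t_uu <- diag(Hin)[p + seq_len(J)]
      dof <- pmax(J - sum(t_uu) / max(sigma2, 1e-8), 1)
      sigma2_new <- max(sum(u^2) / dof, 1e-6)
      if (abs(sigma2_new - sigma2) < 1e-5) {
        sigma2 <- sigma2_new
        break
      }
      sigma2 <- sigma2_new
      res <- fit_inner(sigma2, res$theta)
    }
  }

  Hin <- solve(res$H)
  beta <- res$theta[seq_len(p)]
  se <- sqrt(pmax(diag(Hin)[seq_len(p)], 0))
  names(beta) <- names(se) <- colnames(X)
  list(
    coef = beta, se = se,
    u = setNames(res$theta[p + seq_len(J)], levels(nb)),
    sigma_u = sqrt(sigma2), terms = attr(mf, "terms")
  )
}

approx_ordinal <- function(data, formula) {
  data <- as.data.frame(data)
  resp <- all.vars(formula)[1]
  data[[resp]] <- factor(data[[resp]], ordered = TRUE)
  fit <- MASS::polr(formula, data = data, Hess = TRUE)
  vc <- stats::vcov(fit)
  cf <- stats::coef(fit)
  list(
    coef = cf,
    se = sqrt(diag(vc))[names(cf)],
    sigma_u = NA_real_,
    terms = stats::terms(fit)
  )
}

# unified approximate fit -> broom-shaped coefficient table
approx_fit <- function(data, formula, outcome_type = c("binary", "ordinal"),
                       level = 0.95, sigma_u = NULL) {
  outcome_type <- match.arg(outcome_type)
  f <- if (outcome_type == "binary") {
    approx_logistic(data, formula, sigma_u = sigma_u)
  } else {
    approx_ordinal(data, formula)
  }
  zq <- qnorm(1 - (1 - level) / 2)
  keep <- names(f$coef) != "(Intercept)"
  tab <- tibble::tibble(
    term = names(f$coef)[keep],
    estimate = unname(f$coef[keep]),
    std.error = unname(f$se[keep]),
    conf.low = unname(f$coef[keep] - zq * f$se[keep]),
    conf.high = unname(f$coef[keep] + zq * f$se[keep])
  )
  attr(tab, "fit") <- f
  attr(tab, "outcome_type") <- outcome_type
  tab
}

# map coefficient-table rows to the model variable they belong to
term_variable <- function(terms_obj, term_names) {
  labels <- attr(terms_obj, "term.labels")
  out <- rep(NA_character_, length(term_names))
  # longest-prefix match handles factor expansions like educationnone
  for (lb in labels[order(nchar(labels), decreasing = TRUE)]) {
    hit <- is.na(out) & (term_names == lb | startsWith(term_names, lb))
    out[hit] <- lb
  }
  out
}
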