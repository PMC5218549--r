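# design matrix with intercept, in canonical covariate order
.design_matrix <- function(df, covariates) {
  missing <- setdiff(covariates, names(df))
  if (length(missing) > 0) stop("covariates not in table: ", paste(missing, collapse = ", "))
  x <- cbind("(intercept)" = 1, as.matrix(as.data.frame(df)[, covariates, drop = FALSE]))
  storage.mode(x) <- "double"
  x
}

#' Fit a standard (non-spatial) probit model by maximum likelihood
#'
#' Latent-utility binary choice: `y* = x'beta + e`, `e ~ N(0,1)`, outcome 1
#' iff `y* > 0`, so `P(y=1) = Phi(x'beta)`. Estimated by maximum likelihood
#' (IRLS on the exact likelihood via [stats::glm()]); standard errors from
#' the inverse observed information; two-sided Wald p-values.
#'
#' @param df survey tibble.
#' @param covariates covariate columns; default [model_covariates()] for the
#'   all-owner specification.
#' @param outcome outcome column (binary).
#' @param model_label label carried into reports.
#' @return object of class `probit_fit`: coefficients (incl. intercept),
#'   vcov, log-likelihood, p-values, fitted probabilities, percent correctly
#'   predicted.
#' @export
#' @examples
#' s <- simulate_survey(sim_config(n = 200, seed = 1))
#' f <- fit_probit(s)
#' glance(f)
fit_probit <- function(df, covariates = model_covariates("all"), outcome = "wth",
                       model_label = "probit") {
  y <- df[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  if (length(unique(y)) < 2) stop("outcome does not contain both classes")
  x <- .design_matrix(df, covariates)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("design matrix rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    x, y, family = stats::binomial("probit"),
    control = list(epsilon = 1e-12, maxit = 200)
  ))
  beta <- fit$coefficients
  eta <- drop(x %*% beta)
  if (!fit$converged || max(abs(beta)) > 1e2 || max(abs(eta)) > 30) {
    stop("probit estimation diverged (likely perfect separation)")
  }
  p <- pnorm(eta)
  # observed information of the probit log-likelihood at the MLE
  lambda1 <- dnorm(eta) / pmax(p, 1e-300)          # inverse Mills, y = 1
  lambda0 <- -dnorm(eta) / pmax(1 - p, 1e-300)     # y = 0
  lam <- ifelse(y == 1, lambda1, lambda0)
  wts <- lam * (lam + eta)
  info <- crossprod(x * sqrt(pmax(wts, 0)))
  vc <- solve(info)
  dimnames(vc) <- list(colnames(x), colnames(x))
  se <- sqrt(diag(vc))
  z <- beta / se
  loglik <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(
    list(
      coefficients = beta,
      vcov = vc,
      se = se,
      p_values = 2 * pnorm(-abs(z)),
      loglik = loglik,
      fitted = p,
      pct_correct = percent_correct(p, y),
      covariates = covariates,
      outcome = outcome,
      n = nrow(x),
      model_label = model_label,
      converged = fit$converged
    ),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> %s: n = %d, logLik = %.2f, %% correct = %.1f\n",
              x$model_label, x$n, x$loglik, x$pct_correct))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Marginal effects at covariate means
#'
#' Probability change in the outcome for a one-unit covariate change,
#' evaluated at the covariate means: `phi(xbar'beta) * beta_r` (the default,
#' applied to every covariate including dummies). `mode = "discrete"`
#' instead reports, for binary covariates, the discrete probability change
#' `Phi(. | x_r = 1) - Phi(. | x_r = 0)` with the remaining covariates at
#' their means.
#'
#' @param fit a `probit_fit`.
#' @param df the estimation table (for covariate means).
#' @param mode `"pdf"` (density-scaled, default) or `"discrete"`.
#' @return tibble with `term` and `effect`.
#' @export
marginal_effects_at_means <- function(fit, df, mode = c("pdf", "discrete")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "probit_fit"))
  covs <- fit$covariates
  xbar <- c(1, vapply(covs, function(v) mean(df[[v]]), numeric(1)))
  names(xbar) <- c("(intercept)", covs)
  beta <- fit$coefficients
  idx <- sum(xbar * beta)
  eff <- dnorm(idx) * beta[covs]
  if (mode == "discrete") {
    for (v in intersect(covs, .dummy_names)) {
      x1 <- xbar; x1[v] <- 1
      x0 <- xbar; x0[v] <- 0
      eff[v] <- pnorm(sum(x1 * beta)) - pnorm(sum(x0 * beta))
    }
  }
  tibble::tibble(term = covs, effect = unname(eff))
}

#' Percent of observations correctly predicted
#'
#' Classifies an observation as 1 iff its predicted probability exceeds 0.5
#' (ties classify as 0) and returns the percentage agreeing with the
#' observed outcomes.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param y observed binary outcomes.
#' @return percentage in `[0, 100]`.
#' @export
percent_correct <- function(probs, y) {
  if (length(probs) != length(y)) stop("probs and y have different lengths")
  if (any(probs < 0 | probs > 1)) stop("probabilities outside [0, 1]")
  100 * mean(as.integer(probs > 0.5) == y)
}
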