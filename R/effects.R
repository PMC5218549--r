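#' Impact matrix of one covariate in the SAR probit
#'
#' For covariate r, the n x n matrix of partial derivatives of the outcome
#' probabilities with respect to that covariate across observations:
#' `S_r = D (I - rho W)^-1 beta_r`, where `D = diag(phi(eta_i))` and
#' `eta = (I - rho W)^-1 X beta` is the reduced-form latent mean. Entry
#' `[i, j]` is the effect of changing the covariate at observation j on the
#' outcome probability of observation i; off-diagonal entries are the
#' spatial spillovers.
#'
#' @param beta_r coefficient of the covariate of interest.
#' @param beta full coefficient vector (incl. intercept, matching `x`).
#' @param rho spatial dependence value, `|rho| < 1`.
#' @param w a `weight_matrix` or square matrix.
#' @param x design matrix with intercept column.
#' @return dense n x n matrix.
#' @export
effects_matrix <- function(beta_r, beta, rho, w, x) {
  stopifnot(abs(rho) < 1)
  wm <- as.matrix(.as_w_matrix(w))
  n <- nrow(wm)
  a_inv <- solve(diag(n) - rho * wm)
  eta <- drop(a_inv %*% (x %*% beta))
  dnorm(eta) * a_inv * beta_r
}

#' Average direct, indirect, and total marginal effects
#'
#' Decomposes each covariate's average impact on the outcome probability.
#' For a SAR probit fit, with `S_r` the covariate's impact matrix
#' ([effects_matrix()]): direct = `mean(diag(S_r))` (own-observation effect),
#' total = mean of row sums of `S_r`, and indirect = total - direct (the
#' spillover share), so additivity holds exactly. By default the
#' decomposition is evaluated at the posterior means of `beta` and `rho`
#' (`mode = "posterior_mean"`); `mode = "draws"` instead averages the
#' decomposition over thinned posterior draws.
#'
#' For a standard probit fit the density-scaled effects at covariate means
#' are returned in both the direct and total columns with zero indirect
#' (no spatial process).
#'
#' @param fit a `sar_fit` or `probit_fit`.
#' @param data the estimation table.
#' @param w the `weight_matrix` used in estimation (SAR fits only).
#' @param mode evaluation mode for SAR fits.
#' @param thin keep every `thin`-th draw in `mode = "draws"`.
#' @return tibble of class `effects_tbl`: `term`, `direct`, `indirect`,
#'   `total`, with evaluation metadata in attributes `rho`, `mode`.
#' @export
#' @examples
#' s <- simulate_survey(sim_config(n = 80, seed = 3))
#' f <- fit_probit(s)
#' average_effects(f, s)
average_effects <- function(fit, data, w = NULL,
                            mode = c("posterior_mean", "draws"), thin = 50) {
  mode <- match.arg(mode)
  if (inherits(fit, "probit_fit")) {
    eff <- marginal_effects_at_means(fit, data)
    out <- tibble::tibble(term = eff$term, direct = eff$effect,
                          indirect = 0, total = eff$effect)
    attr(out, "rho") <- 0
    attr(out, "mode") <- "at_means"
    class(out) <- c("effects_tbl", class(out))
    return(out)
  }
  stopifnot(inherits(fit, "sar_fit"))
  if (is.null(w)) stop("average_effects for a SAR fit needs the weight matrix")
  wm <- as.matrix(.as_w_matrix(w))
  x <- .design_matrix(data, fit$covariates)
  if (nrow(wm) != nrow(x)) stop("weight matrix and table dimensions differ")
  n <- nrow(x)

  decomp <- function(beta, rho) {
    a_inv <- solve(diag(n) - rho * wm)
    eta <- drop(a_inv %*% (x %*% beta))
    phi <- dnorm(eta)
    # S_r = diag(phi) A^-1 beta_r: trace and full sum scale linearly in beta_r
    diag_scale <- mean(phi * diag(a_inv))
    total_scale <- mean(phi * rowSums(a_inv))
    b <- beta[fit$covariates]
    cbind(direct = diag_scale * b, total = total_scale * b)
  }

  if (mode == "posterior_mean") {
    rho <- if (fit$rho_fixed) fit$prior$rho_support[1] else mean(fit$rho_draws)
    d <- decomp(colMeans(fit$beta_draws), rho)
  } else {
    keep <- seq(1, nrow(fit$beta_draws), by = thin)
    acc <- 0
    for (j in keep) {
      rho_j <- if (fit$rho_fixed) fit$prior$rho_support[1] else fit$rho_draws[j]
      acc <- acc + decomp(fit$beta_draws[j, ], rho_j)
    }
    d <- acc / length(keep)
  }
  out <- tibble::tibble(
    term = fit$covariates,
    direct = unname(d[, "direct"]),
    indirect = unname(d[, "total"] - d[, "direct"]),
    total = unname(d[, "total"])
  )
  attr(out, "rho") <- if (fit$rho_fixed) fit$prior$rho_support[1] else mean(fit$rho_draws)
  attr(out, "mode") <- mode
  class(out) <- c("effects_tbl", class(out))
  out
}

#' Average indirect share of total marginal effects
#'
#' Mean over the selected covariates of `|indirect| / |total|`, in percent —
#' the headline summary of how much of each covariate's impact is spatial
#' spillover.
#'
#' @param effects an `effects_tbl` (or any tibble with `term`, `indirect`,
#'   `total`).
#' @param terms covariates to average over; default all.
#' @return percentage.
#' @export
indirect_share <- function(effects, terms = NULL) {
  if (is.null(terms)) terms <- effects$term
  missing <- setdiff(terms, effects$term)
  if (length(missing) > 0) stop("terms not in effects table: ",
                                paste(missing, collapse = ", "))
  rows <- effects[match(terms, effects$term), ]
  if (any(rows$total == 0)) stop("zero total effect for: ",
                                 paste(rows$term[rows$total == 0], collapse = ", "))
  100 * mean(abs(rows$indirect) / abs(rows$total))
}
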