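#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a probit fit
#'
#' @param x a `probit_fit`.
#' @param ... unused.
#' @return tibble with term, estimate, std_error, statistic, p_value.
#' @method tidy probit_fit
#' @export
tidy.probit_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$se),
    statistic = unname(x$coefficients / x$se),
    p_value = unname(x$p_values)
  )
}

#' @rdname tidy.probit_fit
#' @method glance probit_fit
#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, loglik = x$loglik, pct_correct = x$pct_correct,
    converged = x$converged, model_label = x$model_label
  )
}

#' Tidy a Bayesian SAR probit fit
#'
#' One row per parameter (the spatial dependence parameter first unless
#' fixed): posterior mean, posterior SD, batch-means Monte Carlo SE, the
#' normal-approximation two-sided tail p ([bayesian_pvalue()]), and the
#' posterior probability of a positive value.
#'
#' @param x a `sar_fit`.
#' @param ... unused.
#' @return tibble.
#' @method tidy sar_fit
#' @export
tidy.sar_fit <- function(x, ...) {
  x$summaries
}

#' @rdname tidy.sar_fit
#' @method glance sar_fit
#' @export
glance.sar_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_chains = x$config$n_chains,
    n_retained = length(x$rho_draws),
    rho_mean = if (x$rho_fixed) x$prior$rho_support[1] else mean(x$rho_draws),
    rho_sd = if (x$rho_fixed) 0 else sd(x$rho_draws),
    pct_correct = x$pct_correct,
    model_label = x$model_label
  )
}
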