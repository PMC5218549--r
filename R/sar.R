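#' Prior for the Bayesian SAR probit
#'
#' Defaults follow the benchmark analysis: independent N(0, 1) priors on
#' every coefficient (including the intercept) and a uniform prior for the
#' spatial dependence parameter rho on (0, 1). A degenerate support
#' (`rho_support = c(a, a)`) fixes rho at that value; fixing it at zero
#' reduces the model to an independent probit.
#'
#' @param beta_mean prior mean, scalar or per-coefficient vector.
#' @param beta_var prior variance (> 0), scalar or per-coefficient vector.
#' @param rho_support interval for the uniform prior on rho, inside (-1, 1).
#' @return object of class `sar_prior`.
#' @export
sar_prior <- function(beta_mean = 0, beta_var = 1, rho_support = c(0, 1)) {
  stopifnot(all(beta_var > 0), length(rho_support) == 2,
            rho_support[1] <= rho_support[2],
            rho_support[1] > -1, rho_support[2] <= 1)
  structure(list(beta_mean = beta_mean, beta_var = beta_var,
                 rho_support = as.numeric(rho_support)),
            class = "sar_prior")
}

#' MCMC configuration for the SAR probit sampler
#'
#' Defaults follow the benchmark analysis: 20,000 sampling iterations with
#' 5,000 discarded as burn-in. Rho is drawn by griddy Gibbs on a grid of the
#' stated step; log-determinants are computed once from the eigenvalues of W
#' and reused. Chains are independent restarts with seeds `seed`,
#' `seed + 1`, ...; retained draws are pooled.
#'
#' @param n_draws total iterations per chain.
#' @param burn_in discarded initial iterations per chain (`< n_draws`).
#' @param rho_grid_step grid step for the griddy Gibbs rho draw, in (0, 0.01].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param n_chains number of independent chains.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_draws = 20000, burn_in = 5000, rho_grid_step = 0.001,
                        seed = NULL, n_chains = 2) {
  stopifnot(burn_in < n_draws, burn_in >= 0,
            rho_grid_step > 0, rho_grid_step <= 0.01, n_chains >= 1)
  structure(list(n_draws = as.integer(n_draws), burn_in = as.integer(burn_in),
                 rho_grid_step = rho_grid_step, seed = seed,
                 n_chains = as.integer(n_chains)),
            class = "mcmc_config")
}

.as_w_matrix <- function(w) {
  if (inherits(w, "weight_matrix")) w$w else methods::as(Matrix::Matrix(w, sparse = TRUE), "CsparseMatrix")
}

# eigenvalues of a row-standardized W: W = D^-1 A with A symmetric, so W is
# similar to the symmetric D^-1/2 A D^-1/2 and has real spectrum in [-1, 1]
.w_eigenvalues <- function(w) {
  wm <- .as_w_matrix(w)
  n <- nrow(wm)
  deg <- Matrix::rowSums(wm != 0)
  sym_ok <- FALSE
  if (all(deg > 0)) {
    s <- Matrix::Diagonal(n, sqrt(deg)) %*% wm %*% Matrix::Diagonal(n, 1 / sqrt(deg))
    sym_ok <- isTRUE(all.equal(as.matrix(s), t(as.matrix(s)), tolerance = 1e-10))
  }
  if (sym_ok) {
    eigen(as.matrix(s), symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(as.matrix(wm), only.values = TRUE)$values
    if (max(abs(Im(ev))) > 1e-8) return(ev)
    Re(ev)
  }
}

#' Log-determinant of (I - rho W) on a grid of rho values
#'
#' Computed exactly from the eigenvalues of W (feasible for the sample sizes
#' these models target), once, for reuse inside the griddy Gibbs step:
#' `log|I - rho W| = sum(log(1 - rho * lambda))`.
#'
#' @param w a `weight_matrix` or square matrix.
#' @param grid numeric vector of rho values.
#' @return tibble with columns `rho`, `logdet`.
#' @export
logdet_grid <- function(w, grid) {
  ev <- .w_eigenvalues(w)
  ld <- vapply(grid, function(r) {
    f <- 1 - r * ev
    if (is.complex(f)) {
      if (any(Mod(f) < 1e-14)) return(-Inf)
      sum(log(Mod(f)))
    } else {
      if (any(f <= 0)) return(-Inf)
      sum(log(f))
    }
  }, numeric(1))
  if (any(!is.finite(ld))) {
    stop("I - rho W is singular at grid value(s): ",
         paste(utils::head(grid[!is.finite(ld)], 3), collapse = ", "))
  }
  tibble::tibble(rho = grid, logdet = ld)
}

# aligned CSC value arrays for H(rho) = I - rho (W + W') + rho^2 W'W
# over the union sparsity pattern; all three components are non-negative so
# the union pattern has no cancellation
.h_pattern <- function(wm) {
  n <- nrow(wm)
  # force general (non-symmetric, non-unit-diagonal) CSC storage so the @i/@p/@x
  # slots enumerate every structural entry
  gen <- function(a) methods::as(methods::as(a, "generalMatrix"), "CsparseMatrix")
  i_n <- gen(Matrix::Diagonal(n, x = rep(1, n)))
  m <- gen(wm + Matrix::t(wm))
  k <- gen(Matrix::crossprod(wm))
  u <- gen(i_n + m + k)
  key <- function(a) {
    list(key = a@i + rep.int(0:(n - 1), diff(a@p)) * n, x = a@x)
  }
  ku <- key(u)
  align <- function(a) {
    ka <- key(a)
    v <- numeric(length(ku$key))
    v[match(ka$key, ku$key)] <- ka$x
    v
  }
  list(p = u@p, i = u@i, id = align(i_n), m = align(m), k = align(k))
}

#' One Gibbs sweep over the latent utilities
#'
#' Given the outcome vector and current `beta` and `rho`, performs one
#' single-site Gibbs sweep (in index order) over the latent utilities of the
#' SAR probit. Each site is drawn from its exact univariate conditional
#' normal, with precision `H = (I - rho W)'(I - rho W)`, truncated to
#' `(0, Inf)` where the outcome is 1 and `(-Inf, 0]` where it is 0.
#'
#' This is the low-level building block of [fit_sar_probit()]; it is exposed
#' for inspection and testing.
#'
#' @param y binary outcome vector.
#' @param beta current coefficient vector (incl. intercept, matching `x`).
#' @param rho current spatial dependence value.
#' @param w a `weight_matrix` or sparse matrix.
#' @param x design matrix (with intercept column).
#' @param ystar current latent vector.
#' @param n_sweeps number of full sweeps.
#' @return updated latent vector.
#' @export
draw_latent <- function(y, beta, rho, w, x, ystar, n_sweeps = 1) {
  wm <- .as_w_matrix(w)
  pat <- .h_pattern(wm)
  hx <- pat$id - rho * pat$m + rho^2 * pat$k
  xb <- drop(x %*% beta)
  b <- xb - rho * as.numeric(Matrix::crossprod(wm, xb))
  gibbs_latent_sweep(pat$p, pat$i, hx, b, ystar, as.integer(y), n_sweeps)
}

#' Conjugate draw of the coefficient vector
#'
#' With the error variance fixed at 1 (probit identification), the model in
#' reduced form is `(I - rho W) y* = X beta + e`, so given `y*` and `rho` the
#' coefficients have the conjugate normal conditional
#' `N(bbar, B)` with `B = (X'X + T^-1)^-1` and
#' `bbar = B (X'(I - rho W) y* + T^-1 m)` for prior mean/covariance (m, T).
#'
#' @inheritParams draw_latent
#' @param prior a [sar_prior()].
#' @return drawn coefficient vector.
#' @export
draw_beta <- function(ystar, rho, w, x, prior = sar_prior()) {
  wm <- .as_w_matrix(w)
  k <- ncol(x)
  m <- rep_len(prior$beta_mean, k)
  tinv <- rep_len(1 / prior$beta_var, k)
  prec <- crossprod(x) + diag(tinv, k)
  ch <- chol(prec)
  ay <- ystar - rho * as.numeric(wm %*% ystar)
  bbar <- backsolve(ch, forwardsolve(t(ch), crossprod(x, ay) + tinv * m))
  drop(bbar + backsolve(ch, rnorm(k)))
}

#' Griddy Gibbs draw of the spatial dependence parameter
#'
#' Evaluates the log conditional kernel
#' `log|I - rho W| - 0.5 * ||(I - rho W) y* - X beta||^2`
#' on the grid spanning the prior support, exponentiates after subtracting
#' the maximum, and samples by inverse CDF with linear interpolation within
#' grid cells.
#'
#' @inheritParams draw_beta
#' @param logdets precomputed [logdet_grid()] table over the prior support.
#' @return drawn rho value.
#' @export
draw_rho <- function(ystar, beta, w, x, prior = sar_prior(),
                     logdets = NULL) {
  wm <- .as_w_matrix(w)
  if (is.null(logdets)) {
    grid <- .rho_grid(prior, 0.001)
    logdets <- logdet_grid(wm, grid)
  }
  wy <- as.numeric(wm %*% ystar)
  d0 <- ystar - drop(x %*% beta)
  .rho_inverse_cdf(logdets$rho, logdets$logdet, sum(d0^2), sum(d0 * wy), sum(wy^2))
}

.rho_grid <- function(prior, step) {
  lo <- prior$rho_support[1]
  hi <- prior$rho_support[2]
  grid <- seq(lo, hi, by = step)
  # drop grid points where I - rho W can be singular (rho = +/-1)
  grid[abs(grid) < 1 - 1e-12]
}

# inverse-CDF sample from the rho conditional tabulated on a grid;
# quadratic-in-rho residual term: ||(I-rho W)y* - X beta||^2 = a - 2 rho b + rho^2 c
.rho_inverse_cdf <- function(grid, logdet, a, b, c) {
  lk <- logdet - 0.5 * (a - 2 * grid * b + grid^2 * c)
  wts <- exp(lk - max(lk))
  if (!any(is.finite(wts)) || sum(wts) <= 0) stop("degenerate rho conditional")
  m <- length(grid)
  if (m == 1) return(grid)
  # trapezoid cell masses, then linear CDF interpolation within the cell
  cell <- (wts[-m] + wts[-1]) / 2 * diff(grid)
  cdf <- cumsum(cell)
  u <- runif(1) * cdf[m - 1]
  j <- findInterval(u, c(0, cdf), rightmost.closed = TRUE)
  j <- min(max(j, 1), m - 1)
  rem <- u - if (j > 1) cdf[j - 1] else 0
  grid[j] + (grid[j + 1] - grid[j]) * rem / cell[j]
}

#' Posterior tail p-value from MCMC draws
#'
#' Two-sided tail of the standard normal at `|mean(draws)| / sd(draws)`: the
#' normal-approximation analogue of a frequentist p-value for a posterior
#' summarized by its mean and standard deviation. The posterior probability
#' of a positive sign is a complementary summary reported by
#' [tidy.sar_fit()].
#'
#' @param draws numeric vector of at least 100 retained draws.
#' @return p-value in (0, 1].
#' @export
bayesian_pvalue <- function(draws) {
  if (length(draws) < 100) stop("need at least 100 retained draws")
  s <- sd(draws)
  if (s == 0) stop("draws have zero variance")
  2 * pnorm(-abs(mean(draws) / s))
}

# batch-means Monte Carlo standard error of the mean of a (dependent) chain
.mcse <- function(x, n_batches = 25) {
  n <- length(x)
  nb <- max(2, min(n_batches, floor(n / 10)))
  size <- floor(n / nb)
  bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * size + 1):(b * size)]),
               numeric(1))
  sd(bm) / sqrt(nb)
}

#' Fit a Bayesian spatial autoregressive probit by MCMC
#'
#' Latent-utility model with a spatial lag in the latent variable:
#' `y* = rho W y* + X beta + e`, `e ~ N(0, I_n)` (error variance fixed at 1
#' for binary-outcome identification), outcome 1 iff `y* > 0`. The sampler
#' cycles, per iteration: one single-site Gibbs sweep over `y*` from its
#' exact truncated-normal conditionals; a conjugate normal draw of `beta`;
#' and a griddy Gibbs draw of `rho` using exact eigenvalue-based
#' log-determinants. Initialization: `beta` at the probit MLE, `rho` at the
#' support midpoint, `y*` at +/- 0.5 by outcome.
#'
#' @param df survey tibble.
#' @param w a `weight_matrix` matching `nrow(df)`; built from the table's
#'   coordinates when `NULL`.
#' @param covariates covariate columns.
#' @param outcome outcome column.
#' @param prior a [sar_prior()].
#' @param config an [mcmc_config()].
#' @param model_label label carried into reports.
#' @return object of class `sar_fit`: pooled retained `beta_draws` (matrix),
#'   `rho_draws`, chain ids, posterior `latent_mean`, fitted marginal
#'   probabilities and percent correctly predicted at posterior means, and a
#'   summary table (posterior mean, SD, MC SE, tail p, sign probability).
#' @export
#' @examples
#' s <- simulate_survey(sim_config(n = 80, seed = 2))
#' f <- fit_sar_probit(s, config = mcmc_config(n_draws = 400, burn_in = 100,
#'                                             seed = 2, n_chains = 1))
#' glance(f)
fit_sar_probit <- function(df, w = NULL, covariates = model_covariates("all"),
                           outcome = "wth", prior = sar_prior(),
                           config = mcmc_config(), model_label = "sar_probit") {
  stopifnot(inherits(prior, "sar_prior"), inherits(config, "mcmc_config"))
  if (is.null(w)) w <- spatial_weights(df)
  wm <- .as_w_matrix(w)
  y <- df[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  if (length(unique(y)) < 2) stop("outcome does not contain both classes")
  x <- .design_matrix(df, covariates)
  n <- nrow(x); k <- ncol(x)
  if (nrow(wm) != n) stop("weight matrix dimension (", nrow(wm),
                          ") does not match table size (", n, ")")

  lo <- prior$rho_support[1]; hi <- prior$rho_support[2]
  rho_fixed <- (hi - lo) < .Machine$double.eps
  grid <- NULL; ld <- NULL
  if (!rho_fixed) {
    grid <- .rho_grid(prior, config$rho_grid_step)
    ld <- logdet_grid(w, grid)
  }

  pat <- .h_pattern(wm)
  wt <- Matrix::t(wm)
  m0 <- rep_len(prior$beta_mean, k)
  tinv <- rep_len(1 / prior$beta_var, k)
  prec <- crossprod(x) + diag(tinv, k)
  ch <- chol(prec)

  beta0 <- tryCatch(
    fit_probit(df, covariates = covariates, outcome = outcome)$coefficients,
    error = function(e) rep(0, k)
  )
  n_keep <- config$n_draws - config$burn_in
  beta_draws <- matrix(NA_real_, n_keep * config$n_chains, k,
                       dimnames = list(NULL, colnames(x)))
  rho_draws <- numeric(n_keep * config$n_chains)
  chain_id <- rep(seq_len(config$n_chains), each = n_keep)
  latent_sum <- numeric(n)
  yint <- as.integer(y)

  for (chain in seq_len(config$n_chains)) {
    if (!is.null(config$seed)) set.seed(config$seed + chain - 1L)
    beta <- beta0
    rho <- if (rho_fixed) lo else (lo + hi) / 2
    ystar <- ifelse(y == 1, 0.5, -0.5)
    for (it in seq_len(config$n_draws)) {
      hx <- pat$id - rho * pat$m + rho^2 * pat$k
      xb <- drop(x %*% beta)
      b <- xb - rho * as.numeric(wt %*% xb)
      ystar <- gibbs_latent_sweep(pat$p, pat$i, hx, b, ystar, yint, 1L)
      if (max(abs(ystar)) > 1e6) stop("latent draws diverged (||y*|| too large)")
      wy <- as.numeric(wm %*% ystar)
      ay <- ystar - rho * wy
      bbar <- backsolve(ch, forwardsolve(t(ch), crossprod(x, ay) + tinv * m0))
      beta <- drop(bbar + backsolve(ch, rnorm(k)))
      if (!rho_fixed) {
        d0 <- ystar - drop(x %*% beta)
        rho <- .rho_inverse_cdf(ld$rho, ld$logdet, sum(d0^2), sum(d0 * wy), sum(wy^2))
      }
      if (it > config$burn_in) {
        row <- (chain - 1L) * n_keep + (it - config$burn_in)
        beta_draws[row, ] <- beta
        rho_draws[row] <- rho
        latent_sum <- latent_sum + ystar
      }
    }
  }

  beta_mean <- colMeans(beta_draws)
  rho_mean <- mean(rho_draws)
  summaries <- tibble::tibble(
    term = c(if (!rho_fixed) "spatial_dependence", colnames(x)),
    estimate = c(if (!rho_fixed) rho_mean, unname(beta_mean)),
    std_error = c(if (!rho_fixed) sd(rho_draws), unname(apply(beta_draws, 2, sd))),
    mcse = c(if (!rho_fixed) .mcse(rho_draws),
             unname(apply(beta_draws, 2, .mcse))),
    p_value = c(if (!rho_fixed) bayesian_pvalue(rho_draws),
                unname(apply(beta_draws, 2, bayesian_pvalue))),
    prob_positive = c(if (!rho_fixed) mean(rho_draws > 0),
                      unname(colMeans(beta_draws > 0)))
  )

  # marginal fitted probabilities at posterior means:
  # y* ~ N(mu, (A'A)^-1), p_i = Phi(mu_i / sigma_i)
  a_inv <- solve(diag(n) - rho_mean * as.matrix(wm))
  mu <- drop(a_inv %*% (x %*% beta_mean))
  sigma <- sqrt(rowSums(a_inv^2))
  fitted <- pnorm(mu / sigma)

  structure(
    list(
      beta_draws = beta_draws,
      rho_draws = rho_draws,
      chain_id = chain_id,
      rho_fixed = rho_fixed,
      latent_mean = latent_sum / (n_keep * config$n_chains),
      summaries = summaries,
      fitted = fitted,
      pct_correct = percent_correct(fitted, y),
      covariates = covariates,
      outcome = outcome,
      n = n,
      prior = prior,
      config = config,
      model_label = model_label
    ),
    class = "sar_fit"
  )
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf(
    "<sar_fit> %s: n = %d, %d chain(s) x %d retained draws, %% correct = %.1f\n",
    x$model_label, x$n, x$config$n_chains,
    x$config$n_draws - x$config$burn_in, x$pct_correct
  ))
  if (!x$rho_fixed) {
    cat(sprintf("rho posterior mean %.3f (sd %.3f)\n",
                mean(x$rho_draws), sd(x$rho_draws)))
  } else {
    cat(sprintf("rho fixed at %.3f\n", x$prior$rho_support[1]))
  }
  print(x$summaries, n = Inf)
  invisible(x)
}

#' Compare posterior summaries across independent sampler runs
#'
#' Convergence heuristic: refit the model with different run lengths or
#' seeds and compare posterior means and spreads parameter by parameter. A
#' parameter's means agree when their difference is within `tol_rel`
#' (relative to the larger absolute mean) or within `tol_sd` pooled posterior
#' standard deviations (the absolute fallback for parameters near zero);
#' posterior SDs agree when within `tol_rel_sd` relative. The report also
#' carries batch-means Monte Carlo standard errors.
#'
#' @param ... two or more `sar_fit` objects sharing a model specification;
#'   the first is the reference.
#' @param tol_rel relative tolerance on posterior means (default 5%).
#' @param tol_sd absolute tolerance on means, in pooled posterior SDs.
#' @param tol_rel_sd relative tolerance on posterior SDs.
#' @return tibble with one row per (run, parameter): differences, tolerances
#'   applied, and `pass`; overall verdict in `attr(, "pass")`.
#' @export
convergence_check <- function(..., tol_rel = 0.05, tol_sd = 0.5,
                              tol_rel_sd = 0.10) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "sar_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2) stop("need at least two runs")
  ref <- fits[[1]]
  for (f in fits[-1]) {
    if (!identical(f$covariates, ref$covariates) ||
        !identical(f$outcome, ref$outcome) || f$n != ref$n) {
      stop("runs do not share a model specification")
    }
  }
  draws <- function(f) {
    d <- f$beta_draws
    if (!f$rho_fixed) d <- cbind(d, spatial_dependence = f$rho_draws)
    d
  }
  d1 <- draws(ref)
  out <- purrr::map_dfr(seq_along(fits)[-1], function(j) {
    d2 <- draws(fits[[j]])
    params <- intersect(colnames(d1), colnames(d2))
    purrr::map_dfr(params, function(p) {
      m1 <- mean(d1[, p]); m2 <- mean(d2[, p])
      s1 <- sd(d1[, p]); s2 <- sd(d2[, p])
      pooled_sd <- sqrt((s1^2 + s2^2) / 2)
      dm <- abs(m1 - m2)
      mean_ok <- dm <= max(tol_rel * max(abs(m1), abs(m2)), tol_sd * pooled_sd)
      sd_ok <- abs(s1 - s2) <= tol_rel_sd * max(s1, s2)
      tibble::tibble(
        run = j, parameter = p,
        mean_ref = m1, mean_run = m2, mean_diff = dm,
        rel_diff_mean = dm / max(abs(m1), abs(m2), .Machine$double.eps),
        mcse_ref = .mcse(d1[, p]), mcse_run = .mcse(d2[, p]),
        sd_ref = s1, sd_run = s2,
        rel_diff_sd = abs(s1 - s2) / max(s1, s2, .Machine$double.eps),
        mean_ok = mean_ok, sd_ok = sd_ok, pass = mean_ok && sd_ok
      )
    })
  })
  attr(out, "pass") <- all(out$pass)
  out
}
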