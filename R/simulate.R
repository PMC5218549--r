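# inverse-CDF draw from N(mean, sd) truncated to [0, Inf)
.rtnorm_pos <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' Configuration for the synthetic owner-table generator
#'
#' Defaults reproduce the conditions of the benchmark study: n = 242 owners,
#' parcels scattered over a 200 x 120 km region (about the forested extent
#' the study sampled, sized so Delaunay neighbor distances fall in the
#' reported 2.6-42.8 km range), spatial dependence `rho_true = 0.167`,
#' coefficients `beta_true` from the published all-owner SAR model
#' ([default_beta()]), Bernoulli covariates at the published sample means,
#' truncated-normal distance covariates at the published means/SDs (miles),
#' standardized sawtimber volume as N(0, 1), and a 25% absentee rate. The
#' two income indicators are mutually exclusive by construction.
#'
#' @param n number of owners (>= 10).
#' @param region c(width, height) of the rectangle, km.
#' @param rho_true spatial dependence in `[0, 1)`.
#' @param beta_true named coefficient vector: `(intercept)` then covariates.
#' @param covariate_means named Bernoulli probabilities for the dummy
#'   covariates (absentee excluded; see `absentee_prob`).
#' @param distance_params named list of `c(mean, sd)` per distance covariate
#'   (miles).
#' @param absentee_prob probability an owner is absentee.
#' @param clusters number of Gaussian settlement clusters; 0 = uniform
#'   points.
#' @param cluster_sd cluster spread, km.
#' @param seed integer seed; same seed, same dataset.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n = 242, region = c(200, 120), rho_true = 0.167,
                       beta_true = default_beta(),
                       covariate_means = NULL, distance_params = NULL,
                       absentee_prob = 0.25, clusters = 0, cluster_sd = 10,
                       seed = NULL) {
  stopifnot(n >= 10, rho_true >= 0, rho_true < 1,
            absentee_prob >= 0, absentee_prob <= 1,
            length(region) == 2, all(region > 0))
  desc <- published_table("descriptives")
  means <- stats::setNames(desc$mean_all, desc$variable)
  if (is.null(covariate_means)) {
    covariate_means <- means[setdiff(.dummy_names, "absentee")]
  }
  stopifnot(all(covariate_means >= 0), all(covariate_means <= 1))
  if (is.null(distance_params)) {
    sds <- stats::setNames(desc$sd_all, desc$variable)
    distance_params <- lapply(.distance_names, function(v) c(mean = means[[v]], sd = sds[[v]]))
    names(distance_params) <- .distance_names
  }
  need <- c("(intercept)", .covariate_names)
  if (!all(need %in% names(beta_true))) {
    stop("beta_true must name: ", paste(setdiff(need, names(beta_true)), collapse = ", "))
  }
  structure(
    list(n = as.integer(n), region = region, rho_true = rho_true,
         beta_true = beta_true[need], covariate_means = covariate_means,
         distance_params = distance_params, absentee_prob = absentee_prob,
         clusters = clusters, cluster_sd = cluster_sd, seed = seed),
    class = "sim_config"
  )
}

#' Simulate parcel locations
#'
#' Uniform points over the configured rectangle, or (with `clusters > 0`)
#' Gaussian blobs around uniformly placed cluster centres to mimic
#' county-level settlement clustering. Coordinates are planar km.
#'
#' @param cfg a [sim_config()].
#' @return tibble with `x`, `y` (km).
#' @export
simulate_points <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  if (cfg$clusters > 0) {
    cx <- runif(cfg$clusters, 0, cfg$region[1])
    cy <- runif(cfg$clusters, 0, cfg$region[2])
    g <- sample.int(cfg$clusters, n, replace = TRUE)
    tibble::tibble(
      x = pmin(pmax(rnorm(n, cx[g], cfg$cluster_sd), 0), cfg$region[1]),
      y = pmin(pmax(rnorm(n, cy[g], cfg$cluster_sd), 0), cfg$region[2])
    )
  } else {
    tibble::tibble(x = runif(n, 0, cfg$region[1]), y = runif(n, 0, cfg$region[2]))
  }
}

#' Simulate the covariate matrix
#'
#' Dummy covariates are Bernoulli at their configured means; the income
#' indicators are drawn from one three-way categorical (>= 50k / unknown /
#' neither) so they are never both 1; distance covariates are normal
#' truncated at zero; squared market access is set to the square;
#' standardized sawtimber volume is N(0, 1); absentee is Bernoulli
#' (`absentee_prob`), independent of the other covariates.
#'
#' @param cfg a [sim_config()].
#' @param n number of rows (defaults to `cfg$n`).
#' @return tibble of the 16 model covariates.
#' @export
simulate_covariates <- function(cfg, n = cfg$n) {
  stopifnot(inherits(cfg, "sim_config"))
  pm <- cfg$covariate_means
  out <- tibble::tibble(.rows = n)
  for (v in setdiff(.dummy_names, c("absentee", "income_ge_50k", "income_unknown"))) {
    out[[v]] <- as.numeric(runif(n) < pm[[v]])
  }
  p50 <- pm[["income_ge_50k"]]; punk <- pm[["income_unknown"]]
  stopifnot(p50 + punk <= 1)
  u <- runif(n)
  out$income_ge_50k <- as.numeric(u < p50)
  out$income_unknown <- as.numeric(u >= p50 & u < p50 + punk)
  out$absentee <- as.numeric(runif(n) < cfg$absentee_prob)
  for (v in .distance_names) {
    prm <- cfg$distance_params[[v]]
    out[[v]] <- .rtnorm_pos(n, prm[["mean"]], prm[["sd"]])
  }
  out$market_access_sq <- out$market_access^2
  out$sawtimber_volume <- rnorm(n)
  out[, .covariate_names]
}

#' Simulate outcomes from the SAR latent process
#'
#' Builds W from the coordinates by Delaunay triangulation, then draws
#' `e ~ N(0, I)`, solves `y* = (I - rho W)^-1 (X beta + e)`, and sets the
#' outcome to 1 exactly where `y* > 0`.
#'
#' @param coords tibble/matrix of planar km coordinates.
#' @param x covariate tibble (16 canonical columns).
#' @param cfg a [sim_config()].
#' @return survey tibble with `id`, `wth`, covariates, and `lon`/`lat`
#'   columns carrying the planar km coordinates (`attr(, "planar") = TRUE`);
#'   the latent vector and generation truth are in attributes `latent` and
#'   `truth`.
#' @export
simulate_outcomes <- function(coords, x, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- nrow(coords)
  stopifnot(nrow(x) == n)
  w <- spatial_weights(coords, planar = TRUE)
  xm <- cbind(1, as.matrix(x[, .covariate_names]))
  beta <- cfg$beta_true
  eps <- rnorm(n)
  a <- Matrix::Diagonal(n) - cfg$rho_true * w$w
  ystar <- as.numeric(Matrix::solve(a, xm %*% beta + eps))
  df <- tibble::as_tibble(x)
  df <- tibble::add_column(df, id = as.character(seq_len(n)),
                           wth = as.numeric(ystar > 0), .before = 1)
  df$lon <- coords[, 1]
  df$lat <- coords[, 2]
  out <- validate_survey(df, quiet = TRUE)
  attr(out, "planar") <- TRUE
  attr(out, "latent") <- ystar
  attr(out, "truth") <- list(rho = cfg$rho_true, beta = beta, seed = cfg$seed)
  attr(out, "weights") <- w
  out
}

#' Simulate a complete synthetic owner table
#'
#' Runs [simulate_points()], [simulate_covariates()], and
#' [simulate_outcomes()] under one seed. The result passes
#' [validate_survey()] by construction and carries the generating truth in
#' attributes. Note the `lon`/`lat` columns hold planar km (use
#' `spatial_weights(df, planar = TRUE)` or reuse `attr(df, "weights")`).
#'
#' @param cfg a [sim_config()].
#' @return survey tibble (see [simulate_outcomes()]).
#' @export
#' @examples
#' s <- simulate_survey(sim_config(n = 60, seed = 1))
#' mean(s$wth)
simulate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pts <- simulate_points(cfg)          # seeds the RNG when cfg$seed is set
  x <- simulate_covariates(cfg)
  simulate_outcomes(pts, x, cfg)
}

#' Write a synthetic table plus its generation manifest
#'
#' Emits the canonical CSV consumed by [read_survey()] and a JSON manifest
#' recording the seed, configuration, and generating truth.
#'
#' @param df a [simulate_survey()] result.
#' @param stem output path stem.
#' @param cfg the [sim_config()] used.
#' @return `stem`, invisibly.
#' @export
write_simulation <- function(df, stem, cfg) {
  write_survey(df, paste0(stem, ".csv"))
  truth <- attr(df, "truth")
  manifest <- list(
    seed = cfg$seed, n = cfg$n, region_km = cfg$region,
    rho_true = cfg$rho_true, beta_true = as.list(truth$beta),
    absentee_prob = cfg$absentee_prob, clusters = cfg$clusters
  )
  jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Parameter-recovery experiment for the SAR probit
#'
#' Repeatedly simulates a dataset from the configured truth, fits the
#' Bayesian SAR probit, and records posterior means and 95% equal-tailed
#' credible intervals. Reports bias, RMSE, and interval coverage for rho and
#' every coefficient. Replicate-level fit errors are recorded, not fatal.
#'
#' @param cfg a [sim_config()]; replicate r uses seed `cfg$seed + r`.
#' @param replicates number of replicates (>= 5).
#' @param mcmc an [mcmc_config()] for the per-replicate fits.
#' @param prior a [sar_prior()].
#' @return tibble with one row per parameter: truth, bias, rmse, coverage;
#'   per-replicate results in `attr(, "replicates")`, errors in
#'   `attr(, "failures")`.
#' @export
recovery_experiment <- function(cfg, replicates = 20,
                                mcmc = mcmc_config(n_draws = 5000, burn_in = 1000,
                                                   n_chains = 1),
                                prior = sar_prior()) {
  stopifnot(replicates >= 5, inherits(cfg, "sim_config"))
  base_seed <- if (is.null(cfg$seed)) 0L else cfg$seed
  failures <- character(0)
  rows <- purrr::map_dfr(seq_len(replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- base_seed + r
    res <- tryCatch({
      s <- simulate_survey(cfg_r)
      w <- attr(s, "weights")
      mc <- mcmc
      mc$seed <- base_seed + 10000L + r
      fit <- fit_sar_probit(s, w = w, prior = prior, config = mc)
      draws <- cbind(fit$beta_draws, spatial_dependence = fit$rho_draws)
      truth <- c(attr(s, "truth")$beta, spatial_dependence = cfg$rho_true)
      names(truth)[seq_len(ncol(fit$beta_draws))] <- colnames(fit$beta_draws)
      purrr::map_dfr(colnames(draws), function(p) {
        d <- draws[, p]
        ci <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
        tv <- truth[[p]]
        tibble::tibble(replicate = r, parameter = p, truth = tv,
                       estimate = mean(d), lower = ci[1], upper = ci[2],
                       covered = tv >= ci[1] & tv <= ci[2])
      })
    }, error = function(e) {
      failures <<- c(failures, sprintf("replicate %d: %s", r, conditionMessage(e)))
      NULL
    })
    res
  })
  if (nrow(rows) == 0) stop("all replicates failed: ", paste(failures, collapse = " | "))
  report <- rows |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      truth = dplyr::first(.data$truth),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$covered),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  attr(report, "replicates") <- rows
  attr(report, "failures") <- failures
  report
}
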