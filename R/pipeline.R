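#' Configuration for a full four-model replication run
#'
#' Exactly one of `input` (path to a survey CSV/XLSX) or `sim` (a
#' [sim_config()]) must be given. The run fits the four benchmark model
#' specifications: standard probit on all owners (Model 1) and residential
#' owners (Model 2), and Bayesian SAR probit on the same two samples
#' (Models 3 and 4), each spatial model on a weight matrix re-triangulated
#' for its own estimation sample.
#'
#' @param input path to a survey file, or `NULL`.
#' @param sim a [sim_config()], or `NULL`.
#' @param prior a [sar_prior()].
#' @param mcmc an [mcmc_config()].
#' @param out_dir output directory for report files; `NULL` writes nothing.
#' @param seed seed applied to the MCMC (and, for simulation, the generator
#'   unless `sim$seed` is set).
#' @param planar_coords treat coordinates as planar km (automatic for
#'   simulated input).
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = NULL, prior = sar_prior(),
                       mcmc = mcmc_config(), out_dir = NULL, seed = 1L,
                       planar_coords = FALSE) {
  if (is.null(input) == is.null(sim)) {
    stop("exactly one of 'input' and 'sim' must be given")
  }
  structure(list(input = input, sim = sim, prior = prior, mcmc = mcmc,
                 out_dir = out_dir, seed = seed, planar_coords = planar_coords),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full four-model replication pipeline
#'
#' Loads or simulates the owner table; splits residential/absentee; builds
#' Delaunay weight matrices for the full and residential samples; fits
#' Models 1-4; computes the effect decompositions; runs a two-run
#' convergence comparison for the all-owner SAR model; and (with `out_dir`)
#' writes coefficient/effects tables as CSV, neighbor stats and weights, and
#' a run log. With a fixed seed the run is reproducible end-to-end.
#'
#' @param cfg a [run_config()].
#' @return list with elements `data`, `split`, `weights` (full/residential),
#'   `fits` (model1..model4), `effects`, `neighbor_stats`, `convergence`,
#'   and `tables` (the [report_tables()] output).
#' @export
run_replication <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  planar <- cfg$planar_coords
  data <- .stage("dataset", {
    if (!is.null(cfg$input)) {
      read_survey(cfg$input, quiet = TRUE)
    } else {
      sim <- cfg$sim
      if (is.null(sim$seed)) sim$seed <- cfg$seed
      s <- simulate_survey(sim)
      planar <- TRUE
      s
    }
  })
  split <- .stage("dataset", split_residential(data))
  if (!all(c("lon", "lat") %in% names(data))) {
    .stage("spatial_weights", stop("table has no lon/lat coordinates"))
  }
  w_all <- .stage("spatial_weights", spatial_weights(data, planar = planar))
  w_res <- .stage("spatial_weights",
                  spatial_weights(split$residential, planar = planar))
  covs_all <- model_covariates("all")
  covs_res <- model_covariates("residential")

  fits <- list()
  fits$model1 <- .stage("probit_mle",
    fit_probit(data, covs_all, model_label = "Model 1 (standard, all owners)"))
  fits$model2 <- .stage("probit_mle",
    fit_probit(split$residential, covs_res,
               model_label = "Model 2 (standard, residential)"))
  mc <- cfg$mcmc
  if (is.null(mc$seed)) mc$seed <- cfg$seed
  fits$model3 <- .stage("sar_probit",
    fit_sar_probit(data, w_all, covs_all, prior = cfg$prior, config = mc,
                   model_label = "Model 3 (SAR, all owners)"))
  mc4 <- mc; mc4$seed <- mc$seed + 100L
  fits$model4 <- .stage("sar_probit",
    fit_sar_probit(split$residential, w_res, covs_res, prior = cfg$prior,
                   config = mc4, model_label = "Model 4 (SAR, residential)"))

  effects <- .stage("effects", list(
    model1 = average_effects(fits$model1, data),
    model2 = average_effects(fits$model2, split$residential),
    model3 = average_effects(fits$model3, data, w_all),
    model4 = average_effects(fits$model4, split$residential, w_res)
  ))

  mc_b <- mc
  mc_b$seed <- mc$seed + 500L
  fit3b <- .stage("sar_probit",
    fit_sar_probit(data, w_all, covs_all, prior = cfg$prior, config = mc_b,
                   model_label = "Model 3 (repeat run)"))
  convergence <- .stage("sar_probit", convergence_check(fits$model3, fit3b))

  nbs <- dplyr::bind_rows(
    dplyr::mutate(neighbor_stats(w_all), sample = "all", .before = 1),
    dplyr::mutate(neighbor_stats(w_res), sample = "residential", .before = 1)
  )
  tables <- report_tables(list(fits = fits, effects = effects))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tables$coefficients, file.path(cfg$out_dir, "coefficients.csv"))
    readr::write_csv(tables$effects, file.path(cfg$out_dir, "effects.csv"))
    readr::write_csv(convergence, file.path(cfg$out_dir, "convergence.csv"))
    jsonlite::write_json(nbs, file.path(cfg$out_dir, "neighbor_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    write_weights(w_all, file.path(cfg$out_dir, "weights_all"))
    writeLines(c(
      sprintf("sarprobit %s | R %s", utils::packageVersion("sarprobit"),
              getRversion()),
      sprintf("seed: %s", cfg$seed),
      sprintf("input: %s", if (is.null(cfg$input)) "simulated" else cfg$input),
      sprintf("n: %d (residential %d, absentee %d)", nrow(data),
              nrow(split$residential), nrow(split$absentee)),
      sprintf("mcmc: %d draws, %d burn-in, grid step %g, %d chain(s)",
              mc$n_draws, mc$burn_in, mc$rho_grid_step, mc$n_chains),
      sprintf("convergence pass: %s", attr(convergence, "pass"))
    ), file.path(cfg$out_dir, "run_log.txt"))
  }

  list(data = data, split = split,
       weights = list(all = w_all, residential = w_res),
       fits = fits, effects = effects, neighbor_stats = nbs,
       convergence = convergence, tables = tables)
}

#' Format fitted models as publication-layout tables
#'
#' `coefficients`: one row per term (spatial dependence first, then the
#' covariates), with coefficient and p-value columns per model.
#' `effects`: one row per covariate with a total-effect column per standard
#' model and direct/indirect/total columns per spatial model. Values are
#' rounded to 3 decimals, matching the precision such tables print.
#'
#' @param results list with `fits` (named list of `probit_fit`/`sar_fit`)
#'   and optionally `effects` (named list of `effects_tbl`, same names).
#' @return list of tibbles `coefficients` and `effects`.
#' @export
report_tables <- function(results) {
  fits <- results$fits
  if (is.null(fits) || length(fits) == 0) stop("no fitted models in results")
  terms <- unique(c("spatial_dependence",
                    unlist(lapply(fits, function(f) f$covariates))))
  coefs <- tibble::tibble(term = terms)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    td <- tidy(f)
    idx <- match(coefs$term, td$term)
    coefs[[paste0(nm, "_coef")]] <- round(td$estimate[idx], 3)
    coefs[[paste0(nm, "_p")]] <- round(td$p_value[idx], 3)
  }
  pct <- tibble::tibble(term = "pct_correct")
  for (nm in names(fits)) {
    pct[[paste0(nm, "_coef")]] <- round(fits[[nm]]$pct_correct, 1)
    pct[[paste0(nm, "_p")]] <- NA_real_
  }
  coefs <- dplyr::bind_rows(coefs, pct)

  eff_tbl <- NULL
  if (!is.null(results$effects)) {
    eff_terms <- unique(unlist(lapply(results$effects, function(e) e$term)))
    eff_tbl <- tibble::tibble(term = eff_terms)
    for (nm in names(results$effects)) {
      e <- results$effects[[nm]]
      idx <- match(eff_tbl$term, e$term)
      spatial <- !isTRUE(all(e$indirect == 0))
      if (spatial) {
        eff_tbl[[paste0(nm, "_direct")]] <- round(e$direct[idx], 3)
        eff_tbl[[paste0(nm, "_indirect")]] <- round(e$indirect[idx], 3)
      }
      eff_tbl[[paste0(nm, "_total")]] <- round(e$total[idx], 3)
    }
  }
  list(coefficients = coefs, effects = eff_tbl)
}
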