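#' Default mapping from source spreadsheet headers to canonical names
#'
#' Column matching is case-insensitive and ignores punctuation/whitespace.
#' Each element maps a canonical column to the header names it may carry in a
#' source file; the canonical name itself always matches. Override or extend
#' entries to adapt to a particular deposit's headers.
#'
#' @return named list: canonical name -> character vector of accepted aliases.
#' @export
default_col_map <- function() {
  list(
    id                  = c("id", "respondent", "obs"),
    wth                 = c("wth", "willingness_to_harvest", "willingnesstoharvest"),
    beauty              = c("beauty", "scenery"),
    privacy             = "privacy",
    sawlog              = c("sawlog", "timber_production"),
    past_harvest        = c("past_harvest", "pastharvest", "harvest_experience"),
    dist_service_center = c("dist_service_center", "distance_to_service_center", "service_center"),
    age55               = c("age55", "age", "age_55"),
    male                = c("male", "gender"),
    college             = c("college", "education"),
    income_ge_50k       = c("income_ge_50k", "income50k", "income_50k", "income"),
    income_unknown      = c("income_unknown", "unknown_income", "incomeunknown"),
    absentee            = "absentee",
    ge_500ac            = c("ge_500ac", "acres500", "ge500ac", "large_ownership"),
    sawtimber_volume    = c("sawtimber_volume", "sawtimber"),
    dist_mtnf           = c("dist_mtnf", "mtnf", "distance_to_mtnf"),
    market_access       = c("market_access", "market_accessibility"),
    market_access_sq    = c("market_access_sq", "market_access2", "market_accessibility_sq"),
    lon                 = c("lon", "longitude", "x"),
    lat                 = c("lat", "latitude", "y")
  )
}

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.match_columns <- function(headers, col_map) {
  normed <- .norm_header(headers)
  out <- character(0)
  for (canon in names(col_map)) {
    aliases <- .norm_header(unique(c(canon, col_map[[canon]])))
    hit <- which(normed %in% aliases)
    if (length(hit) > 0) out[canon] <- headers[hit[1]]
  }
  out
}

#' Read and validate an owner-level survey table
#'
#' Reads a CSV or XLSX file of one-row-per-owner survey records (binary
#' willingness-to-harvest outcome, the 16 model covariates, an absentee
#' indicator, and parcel longitude/latitude), maps source headers to
#' canonical names, and validates every row. Rows violating the coding
#' invariants are rejected, not imputed; the per-row report is attached as
#' `attr(x, "rejected")` and a count message is emitted.
#'
#' Distance covariates are stored in miles. Files recording kilometres can be
#' read with `distance_unit = "km"`; values (and the squared market-access
#' term) are converted on input.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, or `"xlsx"`. XLSX reading
#'   requires the readxl package.
#' @param col_map column alias map, see [default_col_map()].
#' @param distance_unit `"miles"` (default) or `"km"`.
#' @param quiet suppress the row-count message.
#' @return a validated survey tibble (see [validate_survey()]).
#' @export
read_survey <- function(path, format = c("auto", "csv", "xlsx"),
                        col_map = default_col_map(),
                        distance_unit = c("miles", "km"), quiet = FALSE) {
  format <- match.arg(format)
  distance_unit <- match.arg(distance_unit)
  if (!file.exists(path)) stop("survey file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the 'readxl' package")
      }
      as.data.frame(readxl::read_excel(path))
    }
  )
  if (nrow(raw) == 0) stop("survey file has no data rows: ", path)
  hits <- .match_columns(names(raw), col_map)
  required <- c("wth", .covariate_names[.covariate_names != "market_access_sq"])
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df <- raw[, unname(hits), drop = FALSE]
  names(df) <- names(hits)
  if (!"id" %in% names(df)) df$id <- as.character(seq_len(nrow(df)))
  df$id <- as.character(df$id)
  if (distance_unit == "km") {
    mi <- 1.609344
    for (cl in intersect(.distance_names, names(df))) df[[cl]] <- df[[cl]] / mi
    if ("market_access_sq" %in% names(df)) {
      df$market_access_sq <- df$market_access_sq / mi^2
    }
  }
  if (!"market_access_sq" %in% names(df)) {
    df$market_access_sq <- df$market_access^2
  }
  validate_survey(tibble::as_tibble(df), quiet = quiet)
}

#' Validate an owner table against the survey coding invariants
#'
#' Checks, per row: outcome and dummy covariates in \{0,1\}; the two income
#' indicators never both 1; distance covariates non-negative; the squared
#' market-access term equal to the square of market access (1e-6 relative
#' tolerance); finite coordinates when present; no missing required fields.
#' Ids must be unique across retained rows. Failing rows are dropped and
#' reported in `attr(x, "rejected")` (columns `id`, `row`, `reason`).
#'
#' @param df data frame with canonical column names.
#' @param quiet suppress the row-count message.
#' @return validated tibble with subclass `"survey_tbl"`.
#' @export
validate_survey <- function(df, quiet = FALSE) {
  df <- tibble::as_tibble(df)
  required <- c("wth", .covariate_names)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!"id" %in% names(df)) df$id <- as.character(seq_len(nrow(df)))
  df$id <- as.character(df$id)
  n <- nrow(df)
  if (n == 0) stop("survey table has zero rows")

  reasons <- vector("list", n)
  note <- function(rows, why) {
    for (r in which(rows)) reasons[[r]] <<- c(reasons[[r]], why)
  }
  num_required <- c("wth", .covariate_names)
  na_any <- Reduce(`|`, lapply(df[num_required], function(v) !is.finite(suppressWarnings(as.numeric(v)))))
  note(na_any, "missing or non-numeric required field")
  for (cl in c("wth", .dummy_names)) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    note(is.finite(v) & !(v %in% c(0, 1)), paste0(cl, " not in {0,1}"))
  }
  inc <- suppressWarnings(as.numeric(df$income_ge_50k) + as.numeric(df$income_unknown))
  note(is.finite(inc) & inc > 1, "income_ge_50k and income_unknown both 1")
  for (cl in .distance_names) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    note(is.finite(v) & v < 0, paste0(cl, " negative"))
  }
  ma <- suppressWarnings(as.numeric(df$market_access))
  msq <- suppressWarnings(as.numeric(df$market_access_sq))
  bad_sq <- is.finite(ma) & is.finite(msq) &
    abs(msq - ma^2) > 1e-6 * pmax(1, ma^2)
  note(bad_sq, "market_access_sq != market_access^2")
  if (all(c("lon", "lat") %in% names(df))) {
    note(!is.finite(suppressWarnings(as.numeric(df$lon))) |
           !is.finite(suppressWarnings(as.numeric(df$lat))), "non-finite coordinates")
  }

  bad <- !vapply(reasons, is.null, logical(1))
  rejected <- tibble::tibble(
    id = df$id[bad],
    row = which(bad),
    reason = vapply(reasons[bad], paste, character(1), collapse = "; ")
  )
  out <- df[!bad, , drop = FALSE]
  if (nrow(out) == 0) stop("zero valid rows after validation")
  if (anyDuplicated(out$id)) stop("record ids are not unique")
  for (cl in num_required) out[[cl]] <- as.numeric(out[[cl]])
  if (!quiet) {
    message(sprintf("survey table: %d valid rows (%d rejected)", nrow(out), sum(bad)))
  }
  attr(out, "rejected") <- rejected
  class(out) <- c("survey_tbl", class(out))
  out
}

#' Write a survey table to canonical CSV
#'
#' @param df survey tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(df, path) {
  keep <- intersect(c("id", "wth", .covariate_names, "lon", "lat"), names(df))
  utils::write.csv(as.data.frame(df)[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Split an owner table into residential and absentee subsamples
#'
#' Partitions by the absentee indicator. The residential table is the
#' estimation sample for the residential-only models, where the absentee
#' covariate (constant 0) is dropped from the design; [model_covariates()]
#' returns the matching covariate list.
#'
#' @param df survey tibble with an `absentee` column.
#' @return named list with tibbles `residential` and `absentee`.
#' @export
#' @examples
#' s <- simulate_survey(sim_config(n = 50, seed = 1))
#' lengths(lapply(split_residential(s), nrow))
split_residential <- function(df) {
  if (!"absentee" %in% names(df)) stop("absentee flag missing")
  if (anyNA(df$absentee)) stop("absentee flag missing on some records")
  list(
    residential = df[df$absentee == 0, , drop = FALSE],
    absentee = df[df$absentee == 1, , drop = FALSE]
  )
}

#' Descriptive statistics for an owner table
#'
#' Per-variable mean and standard deviation (for binary columns the mean is
#' the sample proportion). With `by_absentee = TRUE`, also reports
#' residential and absentee group means/SDs, the residential-minus-absentee
#' mean difference, and a flag for a two-sample Welch test significant at the
#' 1% level.
#'
#' @param df survey tibble.
#' @param by_absentee also summarize by residential/absentee group.
#' @param variables columns to summarize; defaults to the outcome plus all
#'   model covariates present.
#' @return tibble of summary rows.
#' @export
summarize_survey <- function(df, by_absentee = FALSE, variables = NULL) {
  if (nrow(df) == 0) stop("empty survey table")
  if (is.null(variables)) {
    variables <- intersect(c("wth", .covariate_names), names(df))
  }
  base <- tibble::tibble(
    variable = variables,
    mean = unname(vapply(variables, function(v) mean(df[[v]]), numeric(1))),
    sd = unname(vapply(variables, function(v) stats::sd(df[[v]]), numeric(1)))
  )
  if (!by_absentee) return(base)
  parts <- split_residential(df)
  res <- parts$residential
  abs_ <- parts$absentee
  grp_vars <- setdiff(variables, "absentee")
  grouped <- purrr::map_dfr(grp_vars, function(v) {
    x <- res[[v]]; y <- abs_[[v]]
    tt <- if (stats::sd(x) + stats::sd(y) > 0 && length(x) > 1 && length(y) > 1) {
      stats::t.test(x, y)
    } else NULL
    tibble::tibble(
      variable = v,
      mean_residential = mean(x), sd_residential = stats::sd(x),
      mean_absentee = mean(y), sd_absentee = stats::sd(y),
      diff = mean(x) - mean(y),
      p_value = if (is.null(tt)) NA_real_ else unname(tt$p.value),
      sig_1pct = if (is.null(tt)) NA else unname(tt$p.value) < 0.01
    )
  })
  dplyr::left_join(base, grouped, by = "variable")
}
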