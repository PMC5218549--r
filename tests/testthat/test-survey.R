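make_toy_survey <- function(n = 10, seed = 42) {
  simulate_survey(sim_config(n = max(n, 10), seed = seed))[seq_len(n), ]
}

test_that("canonical CSV round-trips all fields", {
  s <- simulate_survey(sim_config(n = 25, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(s, path)
  back <- read_survey(path, quiet = TRUE)
  for (cl in c("wth", model_covariates("all"), "lon", "lat")) {
    expect_equal(back[[cl]], s[[cl]], tolerance = 1e-12, label = cl)
  }
  expect_equal(back$id, s$id)
  # idempotence: a second round trip is exact
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_survey(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("rows violating the coding invariants are rejected with reasons", {
  s <- as.data.frame(make_toy_survey(8))
  s$beauty[1] <- 2                      # non-binary dummy
  s$income_ge_50k[2] <- 1; s$income_unknown[2] <- 1
  s$market_access[3] <- -4              # negative distance
  s$market_access_sq[4] <- s$market_access[4]^2 + 1
  s$wth[5] <- NA
  out <- validate_survey(s, quiet = TRUE)
  rej <- attr(out, "rejected")
  expect_equal(nrow(out), 3)
  expect_equal(sort(rej$row), 1:5)
  expect_match(rej$reason[rej$row == 1], "beauty")
  expect_match(rej$reason[rej$row == 2], "income")
  expect_match(rej$reason[rej$row == 3], "negative")
  expect_match(rej$reason[rej$row == 4], "market_access_sq")
  expect_match(rej$reason[rej$row == 5], "missing")
})

test_that("degenerate tables raise the documented errors", {
  s <- make_toy_survey(5)
  expect_error(validate_survey(s[0, ]), "zero rows")
  bad <- s; bad$wth <- NA
  expect_error(validate_survey(bad, quiet = TRUE), "zero valid rows")
  dup <- s; dup$id <- rep("a", 5)
  expect_error(validate_survey(dup, quiet = TRUE), "unique")
  expect_error(read_survey(tempfile()), "not found")
  headers_only <- withr::local_tempfile(fileext = ".csv")
  write_survey(s[0, ] |> tibble::as_tibble(), headers_only) |>
    suppressWarnings()
  expect_error(read_survey(headers_only), "no data rows")
  missing_col <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(s)[, setdiff(names(s), "sawlog")], missing_col,
                   row.names = FALSE)
  expect_error(read_survey(missing_col), "sawlog")
})

test_that("a generated CSV loads with zero rejects and headers map case-insensitively", {
  s <- simulate_survey(sim_config(n = 10, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(s)[, c("id", "wth", model_covariates("all"), "lon", "lat")]
  names(df)[names(df) == "wth"] <- "WTH"
  names(df)[names(df) == "male"] <- "Gender"
  names(df)[names(df) == "age55"] <- "Age"
  utils::write.csv(df, path, row.names = FALSE)
  out <- read_survey(path, quiet = TRUE)
  expect_equal(nrow(out), 10)
  expect_equal(nrow(attr(out, "rejected")), 0)
  expect_equal(out$male, s$male)
})

test_that("km distances convert to the internal miles representation", {
  s <- simulate_survey(sim_config(n = 12, seed = 4))
  df <- as.data.frame(s)
  mi <- 1.609344
  for (cl in c("dist_service_center", "dist_mtnf", "market_access")) {
    df[[cl]] <- df[[cl]] * mi
  }
  df$market_access_sq <- df$market_access^2
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, c("id", "wth", model_covariates("all"), "lon", "lat")],
                   path, row.names = FALSE)
  out <- read_survey(path, distance_unit = "km", quiet = TRUE)
  expect_equal(out$market_access, s$market_access, tolerance = 1e-9)
  expect_equal(out$market_access_sq, s$market_access^2, tolerance = 1e-6)
})

test_that("residential/absentee split partitions the table", {
  s <- make_toy_survey(9)
  s$absentee <- c(1, 0, 1, rep(0, 6))
  parts <- split_residential(s)
  expect_equal(nrow(parts$residential), 7)
  expect_equal(nrow(parts$absentee), 2)
  expect_equal(nrow(parts$residential) + nrow(parts$absentee), nrow(s))

  toy <- s[1:3, ]; toy$absentee <- c(1, 0, 1)
  sizes <- vapply(split_residential(toy), nrow, integer(1))
  expect_equal(unname(sizes), c(1, 2))

  allres <- s; allres$absentee <- 0
  expect_equal(nrow(split_residential(allres)$absentee), 0)
  noflag <- s; noflag$absentee <- NA
  expect_error(split_residential(noflag), "absentee")
  # residential model specification drops the absentee covariate
  expect_false("absentee" %in% model_covariates("residential"))
  expect_true("absentee" %in% model_covariates("all"))
})

test_that("summaries report means/SDs and grouped differences", {
  s <- make_toy_survey(60, seed = 7)
  sm <- summarize_survey(s)
  expect_equal(sm$mean[sm$variable == "wth"], mean(s$wth))
  # binary mean equals the sample proportion exactly
  expect_identical(sm$mean[sm$variable == "sawlog"], mean(s$sawlog == 1))
  const <- s; const$beauty <- 1
  smc <- summarize_survey(const, variables = "beauty")
  expect_equal(smc$mean, 1)
  expect_equal(smc$sd, 0)
  g <- summarize_survey(s, by_absentee = TRUE)
  parts <- split_residential(s)
  expect_equal(
    g$diff[g$variable == "privacy"],
    mean(parts$residential$privacy) - mean(parts$absentee$privacy)
  )
  expect_true(all(is.na(g$diff[g$variable == "absentee"])))
  expect_error(summarize_survey(s[0, ]), "empty")
})
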