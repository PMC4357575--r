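test_that("a cohort CSV round-trips exactly", {
  cohort <- make_cohort(n = 60, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_identical(names(back), names(cohort))
  for (nm in names(cohort)) {
    expect_identical(back[[nm]], cohort[[nm]], label = paste("column", nm))
  }
})

test_that("eligibility and level violations are reported with row context", {
  cohort <- make_cohort(n = 60, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- cohort
  bad$age[7] <- 54
  write_cohort(bad, path)
  expect_error(read_cohort(path), "row 7")
  # non-strict mode keeps the rows and attaches the report
  expect_warning(tab <- read_cohort(path, strict = FALSE), "violation")
  expect_equal(nrow(tab), nrow(cohort))
  expect_equal(attr(tab, "validation")$row, 7L)

  bad <- cohort
  bad$vit_worn_out[2] <- "sometimes"
  write_cohort(bad, path)
  err <- tryCatch(read_cohort(path), error = identity)
  expect_match(conditionMessage(err), "sometimes")
  expect_match(conditionMessage(err), "all of the time")  # names the level set

  bad <- cohort
  bad$extra_column <- 1
  write_cohort(bad, path)
  expect_error(read_cohort(path), "extra_column")
})

test_that("below-threshold missingness is filled deterministically by group statistics", {
  cohort <- make_cohort(n = 60, seed = 4)
  cohort$bmi[5] <- NA                      # 1/60 numeric
  cohort$drinks_per_week[c(2, 9)] <- NA    # 2/60 categorical
  filled <- apply_missing_policy(cohort, missing_policy(), seed = 1)
  expect_equal(filled$bmi[5], median(cohort$bmi[-5]))
  obs <- cohort$drinks_per_week[-c(2, 9)]
  expect_equal(filled$drinks_per_week[2],
               names(which.max(table(obs))))
  log <- imputation_log(filled)
  expect_setequal(log$column, c("bmi", "drinks_per_week"))
  expect_equal(sort(log$row[log$column == "drinks_per_week"]), c(2L, 9L))
  # observed cells untouched
  expect_identical(filled$bmi[-5], cohort$bmi[-5])
  # mean fill option
  filled2 <- apply_missing_policy(cohort, missing_policy(numeric_fill = "mean"))
  expect_equal(filled2$bmi[5], mean(cohort$bmi[-5]))
})

test_that("a clean table passes through unchanged with an empty log", {
  cohort <- make_cohort(n = 40, seed = 6)
  filled <- apply_missing_policy(cohort, missing_policy(), seed = 1)
  expect_equal(nrow(imputation_log(filled)), 0)
  attr(filled, "imputation_log") <- NULL
  expect_identical(filled, cohort)
})

test_that("at-or-above-threshold fills are stochastic, seeded and idempotent", {
  cohort <- make_cohort(n = 100, seed = 7)
  masked <- make_missing(cohort, rate = 0.3, columns = "walk20_days", seed = 2)
  f1 <- apply_missing_policy(masked, missing_policy(), seed = 11)
  f2 <- apply_missing_policy(masked, missing_policy(), seed = 11)
  expect_identical(f1$walk20_days, f2$walk20_days)
  expect_true(all(imputation_log(f1)$method == "empirical_draw"))
  # draws come from the observed empirical distribution
  expect_true(all(f1$walk20_days[is.na(masked$walk20_days)] %in%
                    masked$walk20_days[!is.na(masked$walk20_days)]))
  # idempotent on its own output
  f3 <- apply_missing_policy(f1, missing_policy(), seed = 99)
  expect_equal(nrow(imputation_log(f3)), 0)
  attr(f3, "imputation_log") <- NULL
  attr(f1, "imputation_log") <- NULL
  expect_identical(f3, f1)
})

test_that("a fully missing column cannot be imputed", {
  cohort <- make_cohort(n = 40, seed = 8)
  cohort$bmi <- NA_real_
  expect_error(apply_missing_policy(cohort), "100% missing")
})
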