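test_that("load_applications parses, recodes Round 3 and reports rejects", {
  apps <- make_apps(3, round = c("R1", "R3", "R2"),
                    withdrew = c(TRUE, FALSE, NA))
  path <- write_apps_csv(apps)
  got <- load_applications(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$round, c("R1", "R2", "R2"))
  expect_equal(got$stage2_total, got$cps_score + got$pd_score)
  expect_equal(nrow(attr(got, "rejects")), 0)

  # malformed numeric cell: row-indexed reject, not silently dropped
  raw <- utils::read.csv(path, colClasses = "character")
  raw$cps_score[2] <- "oops"
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(raw, bad, row.names = FALSE, na = "")
  got2 <- load_applications(bad)
  rej <- attr(got2, "rejects")
  expect_equal(nrow(got2), 2)
  expect_equal(rej$row, 2L)
  expect_equal(rej$column, "cps_score")

  # empty file with a valid header
  empty <- write_apps_csv(make_apps(0))
  got3 <- load_applications(empty)
  expect_equal(nrow(got3), 0)

  # missing mandatory column is a schema error naming the column
  raw$pd_score <- NULL
  utils::write.csv(raw, bad, row.names = FALSE, na = "")
  expect_error(load_applications(bad), "pd_score")
})

test_that("application round-trip through CSV is the identity", {
  fo <- full_obs_cohort(seed = 11, n_per_year = 60)
  apps <- fo$cohort$apps
  back <- load_applications(write_apps_csv(apps))
  attr(back, "rejects") <- NULL
  expect_equal(back, apps, tolerance = 1e-12)
})

test_that("link_and_filter applies the stated exclusions and counts add up", {
  apps <- make_apps(5, gmc_id = c(NA, "G1", "G2", "G3", "G4"),
                    passed_stage1 = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                    took_stage2 = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                    withdrew = FALSE, offer_accepted = FALSE)
  lc <- link_and_filter(apps)
  expect_s3_class(lc, "linked_cohort")
  expect_equal(nrow(lc$data), 2)
  expect_equal(unname(lc$exclusions),
               c(1L, 1L, 1L))
  expect_equal(sum(lc$exclusions) + nrow(lc$data), lc$n_raw)
})

test_that("performance links only to the successful application", {
  # same doctor: rejected 2011 application, accepted 2013 application
  apps <- make_apps(3, gmc_id = c("G1", "G1", "G2"),
                    year = c(2011L, 2013L, 2013L),
                    withdrew = FALSE,
                    offer_accepted = c(FALSE, TRUE, TRUE))
  perf <- data.frame(gmc_id = "G1", start_month = 163L,
                     ltft_months = 0, oop_months = 0, arcp4 = FALSE,
                     registration_month = 200L, censor_month = 210L)
  lc <- suppressWarnings(link_and_filter(apps, perf))
  expect_equal(lc$data$has_performance, c(FALSE, TRUE, FALSE))
  expect_equal(lc$data$fte_time_to_registration[2], 37)
  # linkage never invents data
  expect_true(is.na(lc$data$arcp4[1]))

  # duplicate performance identifiers are an error
  expect_error(link_and_filter(apps, rbind(perf, perf)), "duplicate")
  # a performance record matching no application is warned about and ignored
  perf2 <- perf; perf2$gmc_id <- "G9"
  w <- capture_warnings(link_and_filter(apps, perf2))
  expect_true(any(grepl("no included", w)))
})

test_that("records released from training have FTE time structurally absent", {
  apps <- make_apps(1, gmc_id = "G1", withdrew = FALSE, offer_accepted = TRUE)
  perf <- data.frame(gmc_id = "G1", start_month = 140L,
                     ltft_months = 3, oop_months = 0, arcp4 = TRUE,
                     registration_month = NA_integer_, censor_month = 190L)
  lc <- link_and_filter(apps, perf)
  expect_true(lc$data$arcp4[1])
  expect_true(is.na(lc$data$fte_time_to_registration[1]))
  expect_true(lc$miss[1, "fte_time_to_registration"])
})

test_that("accounting_summary computes max fillable and annual means", {
  apps <- make_apps(10, round = rep(c("R1", "R2"), c(7, 3)),
                    withdrew = rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 2),
                    offer_accepted = rep(c(TRUE, FALSE, TRUE, TRUE, TRUE), 2))
  # accepted offers without performance records warn (linkage open question)
  lc <- suppressWarnings(link_and_filter(apps))
  acc <- accounting_summary(lc, n_years = 2)
  expect_equal(acc$included, c(7, 3))
  expect_equal(acc$max_fillable, acc$included - acc$withdrew_or_declined)
  expect_equal(acc$max_fillable_annual * 2, acc$max_fillable)
  expect_error(accounting_summary(lc, n_years = 0), "positive")

  # empty cohort: all outputs zero
  acc0 <- accounting_summary(link_and_filter(make_apps(0)), n_years = 4)
  expect_true(all(acc0$included == 0) && all(acc0$max_fillable == 0))

  # missing flags need imputations
  apps$withdrew[1] <- NA
  expect_error(accounting_summary(suppressWarnings(link_and_filter(apps)),
                                  n_years = 2),
               "imputations")
})

test_that("date/month conversion is a month-resolution inverse pair", {
  m <- month_from_date(c("2011-08-15", "2000-01-01", NA))
  expect_equal(m, c(139L, 0L, NA_integer_))
  expect_equal(month_from_date(date_from_month(m)), m)
})
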