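test_that("pool_scalar matches hand arithmetic", {
  p <- pool_scalar(c(1, 2, 3, 4))
  expect_equal(p$mean, 2.5)
  expect_equal(p$sd, sd(c(1, 2, 3, 4)))   # 1.2910 with the n-1 denominator
  expect_equal(round(p$sd, 4), 1.291)
  expect_equal(pool_scalar(c(5, 5, 5))$sd, 0)
  expect_equal(pool_scalar(rep(861, 10))$mean, 861)
  expect_error(pool_scalar(7), "at least two")
})

test_that("configuration is validated", {
  expect_error(imputation_config(m = 1), "at least 2")
  expect_error(imputation_config(n_iterations = 0), "at least 1")
  expect_error(imputation_config(pmm_donors = 0), "at least 1")
  expect_error(imputation_config(variable_order = c("withdrew", "oop")),
               "permutation")
})

test_that("a cohort with no missing cells is returned unchanged", {
  fo <- full_obs_cohort(seed = 31, n_per_year = 150)
  imp <- impute_cohort(fo$linked, imputation_config(m = 3, n_iterations = 2,
                                                    seed = 1))
  for (dd in imp$datasets) expect_identical(dd, fo$linked$data)
})

test_that("MCAR marginal frequency is preserved", {
  fo <- full_obs_cohort(seed = 32, n_per_year = 1500)
  d <- fo$linked$data
  set.seed(42)
  d$ltft <- runif(nrow(d)) < 0.3          # independent of every predictor
  mask <- runif(nrow(d)) < 0.5
  d$ltft[mask] <- NA
  lc <- new_linked_cohort(d)
  imp <- impute_cohort(lc, imputation_config(m = 5, n_iterations = 5,
                                             seed = 2))
  freq <- mean(sapply(imp$datasets, function(dd) mean(dd$ltft[mask])))
  expect_lt(abs(freq - 0.3), 0.05)
})

test_that("imputation completes the cohort, preserves observed cells and
           respects the structural ARCP rule", {
  p <- small_params(seed = 33)
  coh <- generate_cohort(p)
  lc <- apply_historical_selection(coh, p)
  imp <- impute_cohort(lc, imputation_config(m = 4, n_iterations = 4,
                                             seed = 3))
  obs_fte <- !lc$miss[, "fte_time_to_registration"]
  for (dd in imp$datasets) {
    for (v in c("withdrew", "stage3_total", "offer_accepted",
                "ltft", "oop", "arcp4"))
      expect_false(anyNA(dd[[v]]))
    # observed cells identical across all datasets and equal to the input
    for (v in colnames(lc$miss)) {
      keep <- !lc$miss[, v]
      expect_identical(dd[[v]][keep], lc$data[[v]][keep])
    }
    # FTE time absent exactly where released from training
    expect_true(all(is.na(dd$fte_time_to_registration[dd$arcp4 & !obs_fte])))
    expect_false(anyNA(dd$fte_time_to_registration[!dd$arcp4]))
    # PMM donor property: imputed continuous values are observed values
    imp_s3 <- dd$stage3_total[lc$miss[, "stage3_total"]]
    expect_true(all(imp_s3 %in% lc$data$stage3_total[!lc$miss[, "stage3_total"]]))
    imp_fte <- dd$fte_time_to_registration[lc$miss[, "fte_time_to_registration"] &
                                             !dd$arcp4]
    expect_true(all(imp_fte %in%
                      lc$data$fte_time_to_registration[obs_fte]))
  }
  # convergence traces exist for every chained variable
  expect_true(all(dim(imp$trace$stage3_total) == c(4, 4)))
})

test_that("imputation is reproducible given cohort, config and seed", {
  p <- small_params(seed = 34)
  coh <- generate_cohort(p)
  lc <- apply_historical_selection(coh, p)
  cfg <- imputation_config(m = 2, n_iterations = 2, seed = 9)
  expect_identical(impute_cohort(lc, cfg)$datasets,
                   impute_cohort(lc, cfg)$datasets)
})

test_that("imputed Stage 3 scores beat an unconditional-draw baseline", {
  p <- generator_params(n_per_year = 2500, n_years = 2,
                        n_appointed_per_year = 1180, seed = 35)
  coh <- generate_cohort(p)
  lc <- apply_historical_selection(coh, p)
  imp <- impute_cohort(lc, imputation_config(m = 4, n_iterations = 5,
                                             seed = 4))
  mi <- lc$miss[, "stage3_total"]
  truth <- coh$truth$stage3_total[match(lc$data$gmc_id, coh$truth$gmc_id)]
  mae <- mean(sapply(imp$datasets, function(dd)
    mean(abs(dd$stage3_total[mi] - truth[mi]))))
  set.seed(5)
  donors <- lc$data$stage3_total[!mi]
  mae_base <- mean(abs(donors[sample.int(length(donors), sum(mi),
                                         replace = TRUE)] - truth[mi]))
  expect_lt(mae, mae_base)
})

test_that("a variable with no observed donors is a configuration error", {
  fo <- full_obs_cohort(seed = 36, n_per_year = 80)
  d <- fo$linked$data
  d$oop <- NA
  expect_error(impute_cohort(new_linked_cohort(d)), "no observed donors")
})
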