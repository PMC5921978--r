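# fixtures are built in code: small hand-rolled tables plus scaled-down
# synthetic cohorts

# a minimal valid applications data.frame
make_apps <- function(n = 3, gmc_id = sprintf("G%07d", seq_len(n)),
                      year = 2011L, round = "R1",
                      cps_score = 260, pd_score = 255,
                      stage3_total = NA_real_, stage3_competent = NA,
                      withdrew = NA, offer_accepted = NA,
                      passed_stage1 = TRUE, took_stage2 = TRUE,
                      gender = "F", ethnicity_bme = FALSE, uk_pmq = TRUE) {
  d <- data.frame(gmc_id = rep_len(gmc_id, n), year = rep_len(year, n),
                  round = rep_len(round, n),
                  cps_score = rep_len(cps_score, n),
                  pd_score = rep_len(pd_score, n),
                  stage3_total = rep_len(stage3_total, n),
                  stage3_competent = rep_len(stage3_competent, n),
                  withdrew = rep_len(withdrew, n),
                  offer_accepted = rep_len(offer_accepted, n),
                  passed_stage1 = rep_len(passed_stage1, n),
                  took_stage2 = rep_len(took_stage2, n),
                  gender = rep_len(gender, n),
                  ethnicity_bme = rep_len(ethnicity_bme, n),
                  uk_pmq = rep_len(uk_pmq, n), stringsAsFactors = FALSE)
  d$stage2_total <- d$cps_score + d$pd_score
  d
}

write_apps_csv <- function(apps, path = tempfile(fileext = ".csv")) {
  write_applications(apps, path)
  path
}

# desk-scale synthetic world: same proportions as the defaults, ~1/8 size
small_params <- function(seed = 7, n_appointed_per_year = 380, ...) {
  generator_params(n_per_year = 800, n_years = 2,
                   n_appointed_per_year = n_appointed_per_year,
                   seed = seed, ...)
}

# a fully observed linked cohort (everyone sits Stage 3, everyone appointed,
# nobody released, so FTE time is never structurally absent)
full_obs_cohort <- function(seed = 7, n_per_year = 400) {
  p <- generator_params(n_per_year = n_per_year, n_years = 2,
                        n_appointed_per_year = n_per_year,
                        historical_cut = -Inf,
                        competent_intercept = 50,
                        arcp4_intercept = -50,
                        p_withdraw = 0, p_decline = 0, seed = seed)
  coh <- generate_cohort(p)
  list(params = p, cohort = coh, linked = apply_historical_selection(coh, p))
}
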