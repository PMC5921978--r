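# Synthetic applicant cohorts with the statistical structure the analysis
# assumes: selection scores and training outcomes correlated through a latent
# aptitude, applicant decisions, and the selection-induced missingness of a
# historical cut-score process. Generated cohorts stand in for the
# confidential linked selection/performance data, which are not deposited.

#' Generator parameters
#'
#' Defaults describe a four-year application cohort matching the published
#' aggregate structure: about 6341 applications per year (18% in Round 2),
#' Stage 2 tests with mean 250 and SD 40 so the per-test cut of 181 sits
#' about 1.7 SD below the mean, roughly 20% of applications withdrawing or
#' declining offers, and around 3000 appointments per year. Outcome
#' parameters are calibrated so that randomly selected entrants obtain GP
#' Registration at 52% within 3 years FTE and 79% within 5 years.
#'
#' @param n_per_year applications per year.
#' @param n_years number of application years.
#' @param frac_round2 share of applications made in Round 2.
#' @param latent_sd SD of the latent aptitude `u`.
#' @param score_mean,score_sd location/scale of each Stage 2 test, points.
#' @param loading_stage2 correlation loading of each Stage 2 test on `u`.
#' @param stage3_mean,stage3_sd,loading_stage3 analogous for the Stage 3
#'   total score.
#' @param competent_intercept,competent_slope logistic coefficients on `u`
#'   for the categorical Stage 3 "demonstrated competency" outcome.
#' @param p_withdraw,p_decline probabilities of withdrawing before Stage 3 /
#'   declining an offer (independent of `u` by default).
#' @param withdraw_slope,decline_slope optional logit slopes on `u`.
#' @param ltft_rate,ltft_duration_mean,oop_rate,oop_duration_mean probability
#'   of any less-than-full-time / out-of-programme time and mean months when
#'   present (independent of `u`).
#' @param arcp4_intercept,arcp4_slope logistic coefficients for ARCP
#'   Outcome 4 (released from training): `plogis(intercept - slope * u)`.
#' @param ontime_intercept,ontime_slope logistic coefficients for completing
#'   in the minimum 36 FTE months with no extension.
#' @param delay_shape,delay_scale,delay_slope gamma-distributed extension
#'   beyond 36 FTE months, scale `delay_scale * exp(-delay_slope * u)`.
#' @param p_male,p_bme,p_uk_pmq demographic mix (no outcome effects by
#'   default; the published analysis reports none).
#' @param historical_cut per-test Stage 2 cut score of the historical
#'   process.
#' @param n_appointed_per_year historical appointments per year.
#' @param seed RNG seed.
#' @return a `generator_params` list.
#' @export
generator_params <- function(n_per_year = 6341L, n_years = 4L,
                             frac_round2 = 0.1806,
                             latent_sd = 1,
                             score_mean = 250, score_sd = 40,
                             loading_stage2 = 0.55,
                             stage3_mean = 200, stage3_sd = 25,
                             loading_stage3 = 0.6,
                             competent_intercept = 0.85,
                             competent_slope = 1.0,
                             p_withdraw = 0.12, p_decline = 0.09,
                             withdraw_slope = 0, decline_slope = 0,
                             ltft_rate = 0.25, ltft_duration_mean = 12,
                             oop_rate = 0.10, oop_duration_mean = 6,
                             arcp4_intercept = stats::qlogis(0.09),
                             arcp4_slope = 0.9,
                             ontime_intercept = -0.0113,
                             ontime_slope = 0.5,
                             delay_shape = 0.8, delay_scale = 19.82,
                             delay_slope = 0.3,
                             p_male = 0.5, p_bme = 0.45, p_uk_pmq = 0.65,
                             historical_cut = 181,
                             n_appointed_per_year = 3000L,
                             seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$frac_round2, p$p_withdraw, p$p_decline, p$ltft_rate,
             p$oop_rate, p$p_male, p$p_bme, p$p_uk_pmq)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$score_sd <= 0 || p$stage3_sd <= 0) stop("score SDs must be positive")
  if (p$loading_stage2 < 0 || p$loading_stage2 > 1 ||
      p$loading_stage3 < 0 || p$loading_stage3 > 1)
    stop("loadings must lie in [0, 1]")
  if (p$ltft_duration_mean < 0 || p$oop_duration_mean < 0 ||
      p$delay_shape <= 0 || p$delay_scale <= 0)
    stop("durations and delay parameters must be non-negative")
  if (p$n_per_year < 1 || p$n_years < 1) stop("cohort dimensions must be >= 1")
  structure(p, class = "generator_params")
}

#' Generate a complete applicant cohort and its truth table
#'
#' Draws a latent aptitude `u ~ N(0, latent_sd)` per application; each Stage
#' 2 test score is `score_mean + score_sd * (loading * u + sqrt(1 -
#' loading^2) * e)` with independent noise `e`, and the Stage 3 total is
#' built analogously. Training outcomes: release from training (ARCP
#' Outcome 4) follows a logistic model decreasing in `u`; conditional on not
#' being released, FTE time to registration is 36 months plus a
#' point-mass-at-zero / gamma extension whose probability and scale depend on
#' `u`; LTFT and OOP spells are drawn independently of `u`. Withdrawal and
#' offer-decline are independent of `u` at the defaults. Deterministic given
#' the seed.
#'
#' @param params a [generator_params()] object.
#' @return list with `apps` (complete application table, one row per
#'   application) and `truth` (complete outcome table with no missing values:
#'   the validation oracle). FTE time to registration is absent in the truth
#'   table exactly for released (ARCP Outcome 4) trainees.
#' @export
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  n <- p$n_per_year * p$n_years
  with_seed(p$seed, {
    u <- stats::rnorm(n, 0, p$latent_sd)
    us <- u / p$latent_sd   # standardised aptitude drives the logit models
    l2 <- p$loading_stage2; l3 <- p$loading_stage3
    cps <- p$score_mean + p$score_sd * (l2 * us + sqrt(1 - l2^2) * stats::rnorm(n))
    pd  <- p$score_mean + p$score_sd * (l2 * us + sqrt(1 - l2^2) * stats::rnorm(n))
    s3  <- p$stage3_mean + p$stage3_sd * (l3 * us + sqrt(1 - l3^2) * stats::rnorm(n))
    competent <- stats::runif(n) < stats::plogis(p$competent_intercept +
                                                   p$competent_slope * us)
    withdrew <- stats::runif(n) < stats::plogis(stats::qlogis(p$p_withdraw) +
                                                  p$withdraw_slope * us)
    decline <- stats::runif(n) < stats::plogis(stats::qlogis(p$p_decline) +
                                                 p$decline_slope * us)
    arcp4 <- stats::runif(n) < stats::plogis(p$arcp4_intercept -
                                               p$arcp4_slope * us)
    ontime <- stats::runif(n) < stats::plogis(p$ontime_intercept +
                                                p$ontime_slope * us)
    delay <- ifelse(ontime, 0,
                    stats::rgamma(n, shape = p$delay_shape,
                                  scale = p$delay_scale *
                                    exp(-p$delay_slope * us)))
    fte <- ifelse(arcp4, NA_real_, 36 + delay)
    ltft <- stats::runif(n) < p$ltft_rate
    oop <- stats::runif(n) < p$oop_rate
    ltft_months <- ifelse(ltft, 1 + stats::rpois(n, p$ltft_duration_mean - 1), 0)
    oop_months <- ifelse(oop, 1 + stats::rpois(n, p$oop_duration_mean - 1), 0)
    gender <- ifelse(stats::runif(n) < p$p_male, "M", "F")
    bme <- stats::runif(n) < p$p_bme
    ukpmq <- stats::runif(n) < p$p_uk_pmq

    year <- rep(seq_len(p$n_years) + 2010L, each = p$n_per_year)
    round <- ifelse(stats::runif(n) < p$frac_round2, "R2", "R1")

    apps <- data.frame(
      gmc_id = sprintf("G%07d", seq_len(n)),
      year = year, round = round,
      cps_score = cps, pd_score = pd, stage2_total = cps + pd,
      stage3_total = s3, stage3_competent = competent,
      withdrew = withdrew, offer_accepted = !decline,
      passed_stage1 = TRUE, took_stage2 = TRUE,
      gender = gender, ethnicity_bme = bme, uk_pmq = ukpmq,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      gmc_id = apps$gmc_id, u = u,
      stage3_total = s3, stage3_competent = competent,
      withdrew = withdrew, offer_accepted = !decline,
      ltft = ltft, oop = oop,
      ltft_months = ltft_months, oop_months = oop_months,
      arcp4 = arcp4, fte_time_to_registration = fte,
      stringsAsFactors = FALSE)
    list(apps = apps, truth = truth)
  })
}

#' Apply the historical selection process and its missingness
#'
#' Reproduces the observation pattern of a cut-score selection: Stage 3
#' scores and the competency outcome are observed only for applications with
#' both Stage 2 tests at or above `historical_cut` (only they sat Stage 3),
#' as is the withdrawal flag; offers cascade down the Stage 2 + Stage 3
#' ranking of qualifying applications until `n_appointed_per_year` accept
#' (so offer accept/decline is observed for everyone offered); and training
#' outcomes are observed only for appointed trainees. Because masking
#' depends only on always-observed scores, the missingness is missing-at-
#' random by construction. Performance records for appointed trainees are
#' built from the truth table (training starts each August; registration
#' dates back out the calendar time implied by the FTE duration and the
#' LTFT/OOP spells) and linked through [link_and_filter()].
#'
#' @param cohort a list from [generate_cohort()].
#' @param params the [generator_params()] used to generate it.
#' @return a `linked_cohort` with the historical missingness pattern.
#' @export
apply_historical_selection <- function(cohort, params) {
  apps <- cohort$apps; truth <- cohort$truth; p <- params
  n <- nrow(apps)
  sat_stage3 <- apps$cps_score >= p$historical_cut &
    apps$pd_score >= p$historical_cut
  qualifies <- sat_stage3 & truth$stage3_competent & !truth$withdrew

  offered <- logical(n)
  appointed <- logical(n)
  short <- 0L
  for (yr in unique(apps$year)) {
    pool <- which(qualifies & apps$year == yr)
    pool <- pool[order(-(apps$stage2_total[pool] + truth$stage3_total[pool]))]
    acc <- cumsum(truth$offer_accepted[pool])
    k <- match(p$n_appointed_per_year, acc)
    if (is.na(k)) { k <- length(pool); short <- short + 1L }
    off <- pool[seq_len(k)]
    offered[off] <- TRUE
    appointed[off] <- truth$offer_accepted[off]
  }
  if (short > 0L)
    warning("appointment target exceeded the qualifying pool in ", short,
            " year(s); appointed all qualifying applicants")

  masked <- apps
  masked$stage3_total[!sat_stage3] <- NA_real_
  masked$stage3_competent[!sat_stage3] <- NA
  masked$withdrew[!sat_stage3] <- NA
  masked$offer_accepted[!offered] <- NA

  ai <- which(appointed)
  start <- (apps$year[ai] - 2000L) * 12L + 7L   # training starts in August
  fte <- truth$fte_time_to_registration[ai]
  cal <- round(fte + truth$oop_months[ai] +
                 truth$ltft_months[ai] * (1 - 1 / 1.67))
  reg <- ifelse(truth$arcp4[ai], NA_integer_, start + cal)
  perf <- data.frame(
    gmc_id = apps$gmc_id[ai],
    start_month = start,
    ltft_months = truth$ltft_months[ai],
    oop_months = truth$oop_months[ai],
    arcp4 = truth$arcp4[ai],
    registration_month = reg,
    censor_month = max(c(start, reg), na.rm = TRUE) + 1L,
    stringsAsFactors = FALSE)
  link_and_filter(masked, perf)
}

#' Ground-truth registration count for a selected set
#'
#' Counts truth-table registrations within an FTE horizon for a set of
#' applications, ignoring the missingness pattern entirely; the oracle
#' against which imputation-based estimates are validated. Released (ARCP
#' Outcome 4) trainees never register.
#'
#' @param truth the truth table from [generate_cohort()].
#' @param selected integer row indices (or a `selected_set`).
#' @param horizon FTE months, e.g. 38 or 62; `Inf` counts everyone who ever
#'   registers.
#' @return integer count.
#' @export
oracle_outcomes <- function(truth, selected, horizon) {
  idx <- if (inherits(selected, "selected_set")) selected$idx else selected
  if (length(idx) && (min(idx) < 1 || max(idx) > nrow(truth)))
    stop("selected indices out of range")
  fte <- truth$fte_time_to_registration[idx]
  sum(!truth$arcp4[idx] & !is.na(fte) & fte <= horizon)
}
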