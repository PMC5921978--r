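# FTE-equivalent time to GP Registration, 3/5-year outcome counting, pooling
# of counts across imputations and the derived analytics (marginal cohorts,
# extension proportions, between-process comparisons).

#' FTE outcome thresholds
#'
#' Registration outcomes are assessed against full-time-equivalent (FTE)
#' training time: three years (36 months) and five years (60 months), each
#' plus a grace period of two months to allow for delays in processing
#' registration applications, i.e. 38 and 62 FTE months by default. Time
#' spent less-than-full-time is scaled down by `ltft_factor` (1.67,
#' equivalent to working at 60% FTE); time out of programme is subtracted
#' entirely. Thresholds are inclusive.
#'
#' @param base_3y,base_5y base thresholds, FTE months.
#' @param grace grace period, months, applied to both thresholds.
#' @param ltft_factor divisor applied to less-than-full-time months.
#' @return an `fte_thresholds` list.
#' @export
fte_thresholds <- function(base_3y = 36, base_5y = 60, grace = 2,
                           ltft_factor = 1.67) {
  stopifnot(grace >= 0, ltft_factor >= 1, base_3y > 0, base_5y >= base_3y)
  structure(list(base_3y = base_3y, base_5y = base_5y, grace = grace,
                 ltft_factor = ltft_factor), class = "fte_thresholds")
}

#' FTE-equivalent duration
#'
#' Converts a calendar duration to full-time-equivalent months: out-of-
#' programme months are subtracted, and less-than-full-time months are
#' divided by `ltft_factor` rather than counted in full:
#' `(calendar - oop - ltft) + ltft / ltft_factor`.
#'
#' @param calendar_months calendar months from training start to registration.
#' @param oop_months months out of programme.
#' @param ltft_months calendar months spent less than full time.
#' @param ltft_factor see [fte_thresholds()].
#' @param id optional record identifiers used in error messages.
#' @return FTE months (vectorised).
#' @examples
#' fte_time(36, 0, 0)          # 36: full time
#' fte_time(48, 12, 0)         # 36: a year OOP subtracted
#' fte_time(50, 0, 20)         # 30 + 20/1.67 = 41.98
#' @export
fte_time <- function(calendar_months, oop_months, ltft_months,
                     ltft_factor = 1.67, id = NULL) {
  bad <- which(oop_months < 0 | ltft_months < 0 |
                 oop_months + ltft_months > calendar_months)
  if (length(bad)) {
    lab <- if (is.null(id)) bad else id[bad]
    stop("OOP + LTFT months exceed calendar duration (or are negative) for ",
         "record(s): ", paste(utils::head(lab, 5), collapse = ", "))
  }
  (calendar_months - oop_months - ltft_months) + ltft_months / ltft_factor
}

#' Registration outcomes for a selected set
#'
#' Counts how many selected applications obtain (or are imputed to obtain)
#' GP Registration within the 3-year and 5-year FTE thresholds. A record
#' released from training (ARCP Outcome 4) counts toward neither horizon;
#' otherwise it counts when its FTE time to registration is at most
#' `base + grace` (inclusive).
#'
#' @param selected a `selected_set` from [select_trainees()], or an integer
#'   vector of row indices.
#' @param dataset a completed (no missing imputable values) cohort
#'   `data.frame`.
#' @param thresholds an [fte_thresholds()] object.
#' @return list with `n_filled`, `reg_3y`, `reg_5y`.
#' @export
registration_outcomes <- function(selected, dataset,
                                  thresholds = fte_thresholds()) {
  idx <- if (inherits(selected, "selected_set")) selected$idx else selected
  arcp4 <- dataset$arcp4[idx]
  fte <- dataset$fte_time_to_registration[idx]
  reg <- !arcp4 & !is.na(fte)
  list(n_filled = length(idx),
       reg_3y = sum(reg & fte <= thresholds$base_3y + thresholds$grace),
       reg_5y = sum(reg & fte <= thresholds$base_5y + thresholds$grace))
}

#' Pool a scalar estimate across imputations
#'
#' Pools one quantity computed on each of the M completed datasets: the
#' arithmetic mean, the standard deviation across imputations (in effect the
#' standard error of the estimate), and the empirical 2.5th/97.5th
#' percentiles as approximate 95% bounds.
#'
#' @param estimates numeric vector, one value per imputation (M >= 2).
#' @return list with `mean`, `sd`, `p2.5`, `p97.5`, `m`.
#' @export
pool_scalar <- function(estimates) {
  if (length(estimates) < 2)
    stop("pooling requires at least two imputations (SD undefined)")
  qs <- unname(stats::quantile(estimates, c(0.025, 0.975)))
  list(mean = mean(estimates), sd = stats::sd(estimates),
       p2.5 = qs[1], p97.5 = qs[2], m = length(estimates))
}

#' Build the pooled results table
#'
#' For every (selection process x annual recruitment target) combination,
#' runs the selection and outcome counting on each completed dataset of an
#' imputation set and pools the 3- and 5-year registration counts across
#' imputations. Counts are reported as annual means (totals divided by the
#' number of application years) for interpretation against annual targets.
#' A cell is flagged unfillable when the process cannot fill the target in
#' every dataset; unfillable cells carry no counts.
#'
#' @param imputations an [impute_cohort()] result.
#' @param rules list of [selection_rule()] objects.
#' @param targets annual recruitment targets (posts to fill per year).
#' @param thresholds an [fte_thresholds()] object.
#' @param n_years number of application years in the cohort (annualisation
#'   divisor and per-year target multiplier).
#' @param per_year if `TRUE` (default) each year's posts are filled
#'   independently; set `FALSE` to fill `n_years * target` posts from the
#'   pooled years (useful for small cohorts).
#' @param seed base seed; the selection seed is fixed per imputation as
#'   `seed + m`.
#' @return a `results_table` data.frame with columns `process`, `n_target`,
#'   `mean_3y`, `sd_3y`, `mean_5y`, `sd_5y`, `p2.5_5y`, `p97.5_5y`,
#'   `fillable`.
#' @export
build_results_table <- function(imputations, rules,
                                targets = c(1000, 1500, 2000, 2500,
                                            3000, 3500, 4000),
                                thresholds = fte_thresholds(),
                                n_years = NULL, per_year = TRUE, seed = 1L) {
  if (inherits(rules, "selection_rule")) rules <- list(rules)
  n_years <- n_years %||% attr(imputations, "n_years") %||%
    length(unique(imputations$datasets[[1]]$year))
  rows <- list()
  for (rule in rules) {
    for (tg in targets) {
      r3 <- r5 <- numeric(length(imputations$datasets))
      fillable <- TRUE
      for (m in seq_along(imputations$datasets)) {
        dd <- imputations$datasets[[m]]
        rule_m <- rule
        rule_m$seed <- seed + m
        sel <- select_trainees(rule_m, dd, n_target = tg,
                               per_year = per_year, n_years = n_years)
        if (sel$n_filled < sel$n_target_total) fillable <- FALSE
        oc <- registration_outcomes(sel, dd, thresholds)
        r3[m] <- oc$reg_3y / n_years
        r5[m] <- oc$reg_5y / n_years
      }
      if (fillable) {
        p3 <- pool_scalar(r3); p5 <- pool_scalar(r5)
        rows[[length(rows) + 1L]] <- data.frame(
          process = rule$kind, n_target = tg,
          mean_3y = p3$mean, sd_3y = p3$sd,
          mean_5y = p5$mean, sd_5y = p5$sd,
          p2.5_5y = p5$p2.5, p97.5_5y = p5$p97.5, fillable = TRUE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          process = rule$kind, n_target = tg,
          mean_3y = NA_real_, sd_3y = NA_real_,
          mean_5y = NA_real_, sd_5y = NA_real_,
          p2.5_5y = NA_real_, p97.5_5y = NA_real_, fillable = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("results_table", "data.frame"))
}

#' Load the packaged published results table
#'
#' Annual mean (SD) numbers of recruits achieving GP Registration within 3
#' and 5 years FTE, per selection process and recruitment target, pooled over
#' 10 imputations of the 2011-14 UK application cohort, as published.
#' Shipped as a plain-CSV fixture for the analytics functions; cells the
#' cut-score process cannot fill are marked unfillable.
#'
#' @return a `results_table` data.frame.
#' @export
load_published_results <- function() {
  path <- system.file("extdata", "table4.csv", package = "traineesim",
                      mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$fillable <- !is.na(out$mean_5y)
  structure(out, class = c("results_table", "data.frame"))
}

.cell <- function(table, process, n_target, allow_unfillable = FALSE) {
  i <- which(table$process == process & table$n_target == n_target)
  if (!length(i))
    stop("no cell for process ", process, " at target ", n_target)
  row <- table[i[1], ]
  if (!row$fillable && !allow_unfillable)
    stop("target ", n_target, " is not fillable under process ", process)
  row
}

#' Registration rate for a table cell
#'
#' `100 * pooled mean registrations / n_target`, rounded half-up to the
#' nearest whole percent for reporting. With `n_target = NULL` the per-target
#' percentages are averaged over all fillable targets (useful for random
#' selection, whose rate is constant in the target).
#'
#' @param table a `results_table`.
#' @param process process kind (see [selection_rule()]).
#' @param n_target annual recruitment target, or `NULL` to average.
#' @param horizon `"3y"` or `"5y"`.
#' @return integer percent.
#' @export
registration_rate <- function(table, process, n_target = NULL,
                              horizon = c("5y", "3y")) {
  horizon <- match.arg(horizon)
  col <- paste0("mean_", horizon)
  if (is.null(n_target)) {
    sub <- table[table$process == process & table$fillable, , drop = FALSE]
    if (!nrow(sub)) stop("no fillable cells for process ", process)
    pct <- mean(100 * sub[[col]] / sub$n_target)
  } else {
    row <- .cell(table, process, n_target)
    pct <- 100 * row[[col]] / n_target
  }
  round_half_up(pct)
}

#' Proportion of registrants requiring an extension
#'
#' Extensions are registrants needing more than the 3-year FTE threshold:
#' `100 * (reg_5y - reg_3y) / reg_5y`, rounded to the nearest whole percent.
#'
#' @inheritParams registration_rate
#' @return integer percent, or `NA` when the 5-year count is zero.
#' @export
extension_proportion <- function(table, process, n_target) {
  row <- .cell(table, process, n_target)
  if (row$mean_5y <= 0) return(NA_real_)
  round_half_up(100 * (row$mean_5y - row$mean_3y) / row$mean_5y)
}

#' Outcomes of a marginal cohort
#'
#' The marginal cohort between two recruitment targets (e.g. those ranked
#' 2501--3000) measures diminishing returns to selection: its registration
#' counts are the differences between the two cells.
#'
#' @param table a `results_table`.
#' @param process process kind.
#' @param n_low,n_high bracketing targets, `n_high > n_low`.
#' @return list with `registration_pct` (marginal 5-year registrations per
#'   marginal post, percent) and `extension_pct` (share of marginal 5-year
#'   registrants needing an extension, percent; `NA` if no marginal
#'   registrants), both rounded to whole percent.
#' @export
marginal_cohort_stats <- function(table, process, n_low, n_high) {
  if (n_high <= n_low) stop("n_high must exceed n_low")
  lo <- .cell(table, process, n_low)
  hi <- .cell(table, process, n_high)
  m5 <- hi$mean_5y - lo$mean_5y
  m3 <- hi$mean_3y - lo$mean_3y
  list(registration_pct = round_half_up(100 * m5 / (n_high - n_low)),
       extension_pct = if (m5 > 0) round_half_up(100 * (m5 - m3) / m5)
                       else NA_real_)
}

#' Compare two selection processes at a target
#'
#' Differences (a minus b) of the pooled 3- and 5-year registration counts
#' and of the implied extension counts (`reg_5y - reg_3y`), together with the
#' percentage change relative to process b.
#'
#' @param table a `results_table`.
#' @param process_a,process_b process kinds to compare.
#' @param n_target annual recruitment target.
#' @return list with `d_reg_3y`, `d_reg_5y`, `d_extensions` and
#'   `pct_reg_3y`, `pct_reg_5y`, `pct_extensions` (percent of process b's
#'   value, unrounded).
#' @export
compare_processes <- function(table, process_a, process_b, n_target) {
  a <- .cell(table, process_a, n_target)
  b <- .cell(table, process_b, n_target)
  ext_a <- a$mean_5y - a$mean_3y
  ext_b <- b$mean_5y - b$mean_3y
  list(d_reg_3y = a$mean_3y - b$mean_3y,
       d_reg_5y = a$mean_5y - b$mean_5y,
       d_extensions = ext_a - ext_b,
       pct_reg_3y = 100 * (a$mean_3y - b$mean_3y) / b$mean_3y,
       pct_reg_5y = 100 * (a$mean_5y - b$mean_5y) / b$mean_5y,
       pct_extensions = 100 * (ext_a - ext_b) / ext_b)
}

#' @export
print.results_table <- function(x, ...) {
  cat("Pooled registration outcomes (annual mean (SD) across imputations)\n")
  y <- as.data.frame(x)
  print(y, row.names = FALSE, digits = 4)
  invisible(x)
}
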