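# Application / performance tables, CSV interchange, GMC-number linkage and
# eligibility filtering. The unit of analysis is the *application* for GP
# training, not the doctor: one doctor may contribute several applications,
# and training-outcome data attach only to the accepted one.

# The seven variables subject to multiple imputation. stage3_competent is a
# dependent auxiliary (see fcs_imputation.R), not part of this official list.
IMPUTABLE_VARS <- c("withdrew", "stage3_total", "offer_accepted",
                    "ltft", "oop", "arcp4", "fte_time_to_registration")

# Predictors observed for every application; must be complete in a cohort.
ALWAYS_OBSERVED <- c("round", "cps_score", "pd_score", "gender",
                     "ethnicity_bme", "uk_pmq")

.APP_COLS <- c("gmc_id", "year", "round", "cps_score", "pd_score",
               "stage3_total", "stage3_competent", "withdrew",
               "offer_accepted", "passed_stage1", "took_stage2",
               "gender", "ethnicity_bme", "uk_pmq")
.APP_LGL <- c("stage3_competent", "withdrew", "offer_accepted",
              "passed_stage1", "took_stage2", "ethnicity_bme", "uk_pmq")
.APP_NUM <- c("year", "cps_score", "pd_score", "stage3_total")

.PERF_COLS <- c("gmc_id", "start_date", "ltft_months", "oop_months",
                "arcp4", "registration_date", "censor_date")

#' Read an applications table
#'
#' Expects a UTF-8, comma-separated file with a header row; empty cells are
#' missing. One row per application with columns `gmc_id`, `year`, `round`
#' (`R1`/`R2`/`R3`; `R3` is recoded to `R2` on load), the two Stage 2 test
#' scores `cps_score` and `pd_score`, `stage3_total`, `stage3_competent`,
#' the applicant decisions `withdrew` and `offer_accepted`, the eligibility
#' flags `passed_stage1` and `took_stage2`, and the demographics `gender`
#' (`F`/`M`), `ethnicity_bme`, `uk_pmq`. Logical columns accept
#' `TRUE`/`FALSE`/`1`/`0`.
#'
#' Rows with unparseable cells are not loaded and not silently dropped: they
#' are collected into a rejects report attached as `attr(x, "rejects")`
#' (columns `row`, `column`, `value`, `reason`).
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of applications with a derived `stage2_total`
#'   column (`cps_score + pd_score`) and a `rejects` attribute.
#' @seealso [write_applications()], [link_and_filter()]
#' @export
load_applications <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, na.strings = NULL)
  missing_cols <- setdiff(.APP_COLS, names(raw))
  if (length(missing_cols))
    stop("applications file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  rejects <- list()
  bad_rows <- logical(n)
  note <- function(rows, col, vals, why) {
    if (length(rows)) {
      rejects[[length(rejects) + 1L]] <<-
        data.frame(row = rows, column = col, value = vals, reason = why)
      bad_rows[rows] <<- TRUE
    }
  }

  out <- data.frame(gmc_id = trimws(raw$gmc_id), stringsAsFactors = FALSE)
  out$gmc_id[!nzchar(out$gmc_id)] <- NA_character_
  for (cc in .APP_NUM) {
    v <- .parse_num(raw[[cc]])
    note(attr(v, "bad"), cc, raw[[cc]][attr(v, "bad")], "not numeric")
    attr(v, "bad") <- NULL
    out[[cc]] <- v
  }
  for (cc in .APP_LGL) {
    v <- .parse_lgl(raw[[cc]])
    note(attr(v, "bad"), cc, raw[[cc]][attr(v, "bad")], "not logical")
    attr(v, "bad") <- NULL
    out[[cc]] <- v
  }
  rnd <- trimws(raw$round)
  rnd[rnd == "R3"] <- "R2"          # late Round 3 recruitment counted as Round 2
  bad_round <- which(!rnd %in% c("R1", "R2"))
  note(bad_round, "round", raw$round[bad_round], "round must be R1, R2 or R3")
  out$round <- rnd
  gen <- trimws(raw$gender)
  bad_gen <- which(!gen %in% c("F", "M"))
  note(bad_gen, "gender", raw$gender[bad_gen], "gender must be F or M")
  out$gender <- gen

  if ("stage2_total" %in% names(raw)) {
    s2 <- .parse_num(raw$stage2_total)
    incon <- which(!is.na(s2) & !is.na(out$cps_score) & !is.na(out$pd_score) &
                     abs(s2 - (out$cps_score + out$pd_score)) > 1e-8)
    note(incon, "stage2_total", raw$stage2_total[incon],
         "stage2_total != cps_score + pd_score")
  }
  out$stage2_total <- out$cps_score + out$pd_score
  s3incon <- which(is.na(out$stage3_total) & !is.na(out$stage3_competent))
  note(s3incon, "stage3_competent", raw$stage3_competent[s3incon],
       "stage3_competent present without stage3_total")

  out <- out[, c("gmc_id", "year", "round", "cps_score", "pd_score",
                 "stage2_total", "stage3_total", "stage3_competent",
                 "withdrew", "offer_accepted", "passed_stage1", "took_stage2",
                 "gender", "ethnicity_bme", "uk_pmq")]
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(row = integer(), column = character(),
               value = character(), reason = character())
  out <- out[!bad_rows, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write an applications table
#'
#' Inverse of [load_applications()]: `load_applications(write_applications(x))`
#' reproduces `x` for valid records.
#'
#' @param apps applications `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_applications <- function(apps, path) {
  cols <- setdiff(names(apps), "stage2_total")
  utils::write.csv(apps[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a training-performance table
#'
#' One row per appointed trainee: `gmc_id`, `start_date` (ISO-8601, training
#' commencement), calendar months spent less-than-full-time (`ltft_months`)
#' and out-of-programme (`oop_months`), the ARCP Outcome 4 flag `arcp4`
#' (released from training), `registration_date` (GP Registration, empty if
#' not obtained) and `censor_date` (data cut-off). Dates are converted to
#' integer months since 2000-01.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with `*_month` columns.
#' @export
load_performance <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, na.strings = NULL)
  missing_cols <- setdiff(.PERF_COLS, names(raw))
  if (length(missing_cols))
    stop("performance file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(gmc_id = trimws(raw$gmc_id), stringsAsFactors = FALSE)
  out$start_month <- month_from_date(raw$start_date)
  out$ltft_months <- .parse_num(raw$ltft_months)
  out$oop_months <- .parse_num(raw$oop_months)
  out$arcp4 <- .parse_lgl(raw$arcp4)
  out$registration_month <- month_from_date(raw$registration_date)
  out$censor_month <- month_from_date(raw$censor_date)
  for (cc in c("ltft_months", "oop_months", "arcp4")) attr(out[[cc]], "bad") <- NULL
  bad <- which(!is.na(out$registration_month) &
                 out$registration_month < out$start_month)
  if (length(bad))
    stop("registration before training start for record(s): ",
         paste(out$gmc_id[bad], collapse = ", "))
  bad <- which(!is.na(out$arcp4) & out$arcp4 & !is.na(out$registration_month))
  if (length(bad))
    stop("ARCP Outcome 4 (released) with a registration date for record(s): ",
         paste(out$gmc_id[bad], collapse = ", "))
  out
}

#' Write a training-performance table
#' @param perf performance `data.frame` with `*_month` columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_performance <- function(perf, path) {
  out <- data.frame(gmc_id = perf$gmc_id,
                    start_date = date_from_month(perf$start_month),
                    ltft_months = perf$ltft_months,
                    oop_months = perf$oop_months,
                    arcp4 = perf$arcp4,
                    registration_date = date_from_month(perf$registration_month),
                    censor_date = date_from_month(perf$censor_month))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Link applications to training performance and apply eligibility filters
#'
#' Excludes applications with a missing GMC number, those failing the Stage 1
#' eligibility check, and those withdrawing before taking the Stage 2 tests,
#' so that every retained application has a Stage 2 score. Performance is
#' attached by exact `gmc_id` match, and where a doctor made several
#' applications, only to the successful one (observed `offer_accepted`
#' `TRUE`). FTE-equivalent time to registration is derived for linked records
#' (see [fte_time()]); records released from training (ARCP Outcome 4) have
#' it structurally absent.
#'
#' @param apps applications `data.frame` from [load_applications()].
#' @param perf optional performance `data.frame` from [load_performance()].
#' @param thresholds an [fte_thresholds()] object (supplies the LTFT factor).
#' @return a `linked_cohort`: list with `data` (one row per retained
#'   application, with performance columns where linked), `miss` (logical
#'   matrix over the seven imputable variables), `exclusions` (named counts)
#'   and `n_raw`.
#' @export
link_and_filter <- function(apps, perf = NULL, thresholds = fte_thresholds()) {
  n_raw <- nrow(apps)
  excl <- c(missing_gmc = sum(is.na(apps$gmc_id)))
  keep <- !is.na(apps$gmc_id)
  excl["failed_stage1"] <- sum(keep & !apps$passed_stage1)
  keep <- keep & apps$passed_stage1
  excl["no_stage2"] <- sum(keep & !apps$took_stage2)
  keep <- keep & apps$took_stage2
  d <- apps[keep, , drop = FALSE]
  rownames(d) <- NULL

  for (v in ALWAYS_OBSERVED)
    if (anyNA(d[[v]]))
      stop("always-observed predictor '", v, "' has missing values")

  nk <- nrow(d)
  d$has_performance <- rep(FALSE, nk)
  d$start_month <- rep(NA_integer_, nk)
  d$ltft_months <- rep(NA_real_, nk)
  d$oop_months <- rep(NA_real_, nk)
  d$ltft <- rep(NA, nk)
  d$oop <- rep(NA, nk)
  d$arcp4 <- rep(NA, nk)
  d$registration_month <- rep(NA_integer_, nk)
  d$censor_month <- rep(NA_integer_, nk)
  d$fte_time_to_registration <- rep(NA_real_, nk)

  if (!is.null(perf) && nrow(perf)) {
    dup <- perf$gmc_id[duplicated(perf$gmc_id)]
    if (length(dup))
      stop("duplicate gmc_id in performance data: ",
           paste(unique(dup), collapse = ", "))
    # attach only to the accepted application of each doctor
    target <- which(!is.na(d$offer_accepted) & d$offer_accepted)
    idx <- target[match(perf$gmc_id, d$gmc_id[target])]
    unmatched <- is.na(idx)
    if (any(unmatched))
      warning(sum(unmatched), " performance record(s) match no included ",
              "accepted application; ignored")
    pi <- which(!unmatched)
    ai <- idx[pi]
    d$has_performance[ai] <- TRUE
    d$start_month[ai] <- perf$start_month[pi]
    d$ltft_months[ai] <- perf$ltft_months[pi]
    d$oop_months[ai] <- perf$oop_months[pi]
    d$arcp4[ai] <- perf$arcp4[pi]
    d$registration_month[ai] <- perf$registration_month[pi]
    d$censor_month[ai] <- perf$censor_month[pi]
    d$ltft[ai] <- perf$ltft_months[pi] > 0
    d$oop[ai] <- perf$oop_months[pi] > 0

    reg <- ai[!is.na(d$registration_month[ai]) &
                (is.na(d$arcp4[ai]) | !d$arcp4[ai])]
    if (length(reg)) {
      cal <- d$registration_month[reg] - d$start_month[reg]
      d$fte_time_to_registration[reg] <-
        fte_time(cal, d$oop_months[reg], d$ltft_months[reg],
                 ltft_factor = thresholds$ltft_factor, id = d$gmc_id[reg])
    }
    d$fte_time_to_registration[!is.na(d$arcp4) & d$arcp4] <- NA_real_
  }

  orphan <- which(!is.na(d$offer_accepted) & d$offer_accepted &
                    !d$has_performance)
  if (length(orphan))
    warning(length(orphan), " application(s) with an accepted offer have no ",
            "performance record; training outcomes left missing")

  new_linked_cohort(d, exclusions = excl, n_raw = n_raw)
}

#' Construct a linked cohort from an already-filtered table
#'
#' Low-level constructor used by [link_and_filter()] and the synthetic
#' generator. Builds the missingness mask over the seven imputable variables
#' from the `NA` pattern of `data`.
#'
#' @param data a `data.frame` carrying application and (where linked)
#'   performance columns.
#' @param exclusions named integer vector of exclusion counts.
#' @param n_raw raw row count before filtering.
#' @return a `linked_cohort` object.
#' @export
new_linked_cohort <- function(data, exclusions = c(missing_gmc = 0L,
                                                   failed_stage1 = 0L,
                                                   no_stage2 = 0L),
                              n_raw = nrow(data)) {
  stopifnot(all(IMPUTABLE_VARS %in% names(data)))
  miss <- sapply(data[IMPUTABLE_VARS], is.na)
  if (nrow(data) == 1L) miss <- matrix(miss, nrow = 1,
                                       dimnames = list(NULL, IMPUTABLE_VARS))
  if (nrow(data) == 0L) miss <- matrix(logical(), nrow = 0, ncol = 7,
                                       dimnames = list(NULL, IMPUTABLE_VARS))
  structure(list(data = data, miss = miss,
                 exclusions = exclusions, n_raw = n_raw),
            class = "linked_cohort")
}

#' @export
print.linked_cohort <- function(x, ...) {
  cat("Linked GP-training cohort: ", nrow(x$data), " applications (",
      x$n_raw, " raw rows; excluded: ",
      paste(names(x$exclusions), x$exclusions, sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat("  with performance data:", sum(x$data$has_performance), "\n")
  mr <- round(100 * colMeans(x$miss), 1)
  cat("  missingness (%):\n")
  print(mr)
  invisible(x)
}

#' @export
dim.linked_cohort <- function(x) dim(x$data)

#' Application accounting summary
#'
#' Per-round counts of applications included in the analysis, of those that
#' withdrew before Stage 3 or declined a post offer, and of the maximum
#' number of posts that could have been filled (included minus withdrawals
#' and declines), plus annual means. Where the withdrawal/decline flags are
#' partly missing, counts are averaged over a set of imputed datasets.
#'
#' @param cohort a `linked_cohort`.
#' @param imputations an [impute_cohort()] result; required when
#'   `withdrew`/`offer_accepted` contain missing values.
#' @param n_years number of application years covered.
#' @return an `accounting_summary` object.
#' @export
accounting_summary <- function(cohort, imputations = NULL, n_years) {
  if (n_years <= 0) stop("n_years must be positive")
  d <- cohort$data
  wd_count <- function(dd, r) {
    sub <- dd[dd$round == r, , drop = FALSE]
    sum(sub$withdrew | !sub$offer_accepted)
  }
  inc <- c(R1 = sum(d$round == "R1"), R2 = sum(d$round == "R2"))
  if (anyNA(d$withdrew) || anyNA(d$offer_accepted)) {
    if (is.null(imputations))
      stop("withdrawal/decline flags have missing values; supply imputations")
    wd <- rowMeans(sapply(imputations$datasets, function(dd)
      c(wd_count(dd, "R1"), wd_count(dd, "R2"))))
  } else {
    wd <- c(wd_count(d, "R1"), wd_count(d, "R2"))
  }
  accounting_from_counts(inc[["R1"]], wd[[1]], inc[["R2"]], wd[[2]], n_years)
}

#' Accounting summary from aggregate counts
#'
#' The arithmetic behind [accounting_summary()], exposed so published
#' aggregate counts can be tabulated directly: maximum fillable posts equal
#' included applications minus withdrawals and declines, and annual means
#' are totals divided by the number of years.
#'
#' @param included_r1,included_r2 applications included, per round.
#' @param withdrew_or_declined_r1,withdrew_or_declined_r2 withdrawn-before-
#'   Stage-3 or declined-offer counts, per round.
#' @param n_years number of application years.
#' @return an `accounting_summary`: data.frame with one row per round and
#'   columns `included`, `withdrew_or_declined`, `max_fillable` and their
#'   `*_annual` means.
#' @export
accounting_from_counts <- function(included_r1, withdrew_or_declined_r1,
                                   included_r2, withdrew_or_declined_r2,
                                   n_years) {
  if (n_years <= 0) stop("n_years must be positive")
  inc <- c(included_r1, included_r2)
  wd <- c(withdrew_or_declined_r1, withdrew_or_declined_r2)
  out <- data.frame(round = c("R1", "R2"),
                    included = inc,
                    withdrew_or_declined = wd,
                    max_fillable = inc - wd,
                    included_annual = inc / n_years,
                    withdrew_or_declined_annual = wd / n_years,
                    max_fillable_annual = (inc - wd) / n_years)
  structure(out, class = c("accounting_summary", "data.frame"),
            n_years = n_years)
}

#' @export
print.accounting_summary <- function(x, ...) {
  cat("Application accounting over", attr(x, "n_years"), "years\n")
  y <- x
  class(y) <- "data.frame"
  y[5:7] <- lapply(y[5:7], function(v) round_half_up(v))
  print(y, row.names = FALSE)
  invisible(x)
}
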