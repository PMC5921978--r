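# The four counterfactual selection processes: random selection from Round 1,
# the 2015 cut-score + Selection Centre process (Rounds 1 then 2), and pure
# rankings on Stage 2 or Stage 3 scores.

PROCESS_KINDS <- c("RANDOM", "PROCESS_2015", "STAGE2_ONLY", "STAGE3_ONLY")

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Define a selection process
#'
#' @param kind one of `"RANDOM"` (uniform draw from the Round 1 pool),
#'   `"PROCESS_2015"` (a cut score on each Stage 2 test plus the categorical
#'   Stage 3 "demonstrated competency for training" outcome, filling Round 1
#'   then Round 2), `"STAGE2_ONLY"` or `"STAGE3_ONLY"` (rank Round 1
#'   applications on the total Stage 2 / Stage 3 score, no cut score).
#' @param cut_score per-test Stage 2 cut score, used by `PROCESS_2015` only.
#' @param seed seed for random selection and for tie-breaking in ranked
#'   processes (ties are broken by a seeded uniform draw so that results are
#'   reproducible and selections nest across targets).
#' @param rank_by within-pool ordering for `PROCESS_2015` when demand exceeds
#'   supply: `"combined"` (Stage 2 + Stage 3 totals, default) or `"stage2"`.
#' @return a `selection_rule` list.
#' @export
selection_rule <- function(kind = PROCESS_KINDS, cut_score = 181, seed = 1L,
                           rank_by = c("combined", "stage2")) {
  kind <- match.arg(kind)
  rank_by <- match.arg(rank_by)
  if (kind == "PROCESS_2015" && cut_score <= 0)
    stop("cut_score must be positive for PROCESS_2015")
  structure(list(kind = kind, cut_score = cut_score, seed = as.integer(seed),
                 rank_by = rank_by), class = "selection_rule")
}

#' Eligible applications of a round
#'
#' Applications that withdrew from the selection process or declined a post
#' offer are excluded from every modelled process; the remaining applications
#' of the requested round form the pool.
#'
#' @param dataset a completed cohort `data.frame` (no missing
#'   `withdrew`/`offer_accepted`).
#' @param round `"R1"` or `"R2"`.
#' @return integer row indices.
#' @export
eligible_pool <- function(dataset, round = "R1") {
  if (anyNA(dataset$withdrew) || anyNA(dataset$offer_accepted))
    stop("withdrew/offer_accepted must be complete; impute first")
  which(dataset$round == round & !dataset$withdrew & dataset$offer_accepted)
}

# descending-score order with a seeded uniform tie-break
.ranked <- function(idx, score, seed) {
  tie <- with_seed(seed, stats::runif(length(score)))
  idx[order(-score, tie)]
}

.select_one_year <- function(rule, dataset, rows, n_target) {
  r1 <- rows[dataset$round[rows] == "R1" & !dataset$withdrew[rows] &
               dataset$offer_accepted[rows]]
  switch(rule$kind,
    RANDOM = {
      k <- min(n_target, length(r1))
      with_seed(rule$seed, r1[sample.int(length(r1), k)])
    },
    STAGE2_ONLY = utils::head(
      .ranked(r1, dataset$stage2_total[r1], rule$seed), n_target),
    STAGE3_ONLY = utils::head(
      .ranked(r1, dataset$stage3_total[r1], rule$seed), n_target),
    PROCESS_2015 = {
      r2 <- rows[dataset$round[rows] == "R2" & !dataset$withdrew[rows] &
                   dataset$offer_accepted[rows]]
      qual <- function(i) i[dataset$cps_score[i] >= rule$cut_score &
                              dataset$pd_score[i] >= rule$cut_score &
                              dataset$stage3_competent[i]]
      score <- function(i) if (rule$rank_by == "combined")
        dataset$stage2_total[i] + dataset$stage3_total[i] else
          dataset$stage2_total[i]
      q1 <- qual(r1); q2 <- qual(r2)
      sel <- utils::head(.ranked(q1, score(q1), rule$seed), n_target)
      if (length(sel) < n_target)   # Round 2 fills what Round 1 could not
        sel <- c(sel, utils::head(.ranked(q2, score(q2), rule$seed + 1L),
                                  n_target - length(sel)))
      sel
    })
}

#' Fill training posts under a selection process
#'
#' Fills up to `n_target` posts per application year (or `n_years * n_target`
#' posts from the pooled years when `per_year = FALSE`) from a completed
#' cohort. `n_filled` below the total target signals a target the process
#' cannot fill.
#'
#' @param rule a [selection_rule()].
#' @param dataset a completed cohort `data.frame`.
#' @param n_target annual number of posts to fill (>= 0).
#' @param per_year fill each application year independently (default) or
#'   treat all years as one pool.
#' @param n_years number of years; defaults to the distinct years present.
#' @return a `selected_set`: list with `idx` (selected row indices),
#'   `n_target_total`, `n_filled`, `kind`.
#' @export
select_trainees <- function(rule, dataset, n_target, per_year = TRUE,
                            n_years = NULL) {
  if (n_target < 0) stop("n_target must be non-negative")
  n_years <- n_years %||% length(unique(dataset$year))
  if (per_year) {
    idx <- integer()
    for (yr in sort(unique(dataset$year))) {
      rows <- which(dataset$year == yr)
      rule_y <- rule
      rule_y$seed <- rule$seed + (yr %% 1000L) * 7L  # independent draws per year
      idx <- c(idx, .select_one_year(rule_y, dataset, rows, n_target))
    }
    total <- n_target * n_years
  } else {
    idx <- .select_one_year(rule, dataset, seq_len(nrow(dataset)),
                            n_target * n_years)
    total <- n_target * n_years
  }
  structure(list(idx = idx, n_target_total = total, n_filled = length(idx),
                 kind = rule$kind), class = "selected_set")
}

#' Largest achievable fill for a process
#'
#' For processes without a cut score this is the size of the Round 1 eligible
#' pool; for the 2015 process it is the number of Round 1 + Round 2
#' applications passing both Stage 2 cut scores and judged competent at
#' Stage 3. Equals `select_trainees(rule, dataset, Inf)$n_filled`.
#'
#' @param rule a [selection_rule()].
#' @param dataset a completed cohort `data.frame`.
#' @return total count across all years.
#' @export
max_fill <- function(rule, dataset) {
  if (rule$kind == "PROCESS_2015") {
    pool <- c(eligible_pool(dataset, "R1"), eligible_pool(dataset, "R2"))
    sum(dataset$cps_score[pool] >= rule$cut_score &
          dataset$pd_score[pool] >= rule$cut_score &
          dataset$stage3_competent[pool])
  } else {
    length(eligible_pool(dataset, "R1"))
  }
}

#' @export
print.selected_set <- function(x, ...) {
  cat("Selection (", x$kind, "): filled ", x$n_filled, " of ",
      x$n_target_total, " posts\n", sep = "")
  invisible(x)
}
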