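# Fully-conditional-specification (chained equations) multiple imputation.
#
# Each variable with missing values is taken in turn as the dependent
# variable with all others as predictors: binary variables through logistic
# regression with coefficient draws from the asymptotic posterior, continuous
# variables through Bayesian linear regression followed by predictive mean
# matching (type-1 matching), so every imputed continuous value is an
# observed donor value and durations stay within the observed support.
# Because selection restricts the range of scores among those with observed
# outcomes, the conditional models extrapolate from the always-observed
# predictors under the missing-at-random assumption; no explicit truncation
# correction is applied.

#' Imputation configuration
#'
#' @param m number of imputations (>= 2).
#' @param n_iterations chained-equation cycles before each imputation is
#'   drawn (>= 1). Convergence traces are returned so this can be raised if
#'   the per-cycle means have not settled.
#' @param pmm_donors donor-pool size for predictive mean matching (>= 1).
#' @param seed integer seed; imputation `m` uses `seed + m`.
#' @param variable_order order in which the seven imputable variables are
#'   visited within a cycle; defaults to the causal sequence of the training
#'   pathway. The categorical Stage 3 competency outcome is completed as a
#'   dependent auxiliary immediately after the Stage 3 total score.
#' @return an `imputation_config` list.
#' @export
imputation_config <- function(m = 10L, n_iterations = 10L, pmm_donors = 5L,
                              seed = 1L, variable_order = IMPUTABLE_VARS) {
  if (m < 2) stop("m must be at least 2")
  if (n_iterations < 1) stop("n_iterations must be at least 1")
  if (pmm_donors < 1) stop("pmm_donors must be at least 1")
  if (!setequal(variable_order, IMPUTABLE_VARS))
    stop("variable_order must be a permutation of the seven imputable variables")
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 pmm_donors = as.integer(pmm_donors), seed = as.integer(seed),
                 variable_order = variable_order),
            class = "imputation_config")
}

# ridge-stabilised IRLS logistic fit; returns coefficients and posterior
# covariance. lambda > 0 is the fallback for separation / singular fits.
.fit_logistic <- function(X, y, lambda = 0) {
  p <- ncol(X)
  beta <- numeric(p)
  ok <- FALSE
  for (it in 1:30) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    A <- crossprod(X, w * X)
    if (lambda > 0) A <- A + diag(lambda, p)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta_new <- drop(chol2inv(ch) %*% crossprod(X, w * (eta + (y - mu) / w)))
    if (!all(is.finite(beta_new))) return(NULL)
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; ok <- TRUE; break }
    beta <- beta_new
  }
  if (!ok || max(abs(beta)) > 25) return(NULL)
  list(beta = beta, V = chol2inv(ch))
}

# columns that are constant on the fitting rows carry no information and
# make the normal equations singular (e.g. offer_accepted is TRUE for every
# record with observed training outcomes); drop them from both matrices
.drop_constant <- function(X_obs, X_mis) {
  keep <- c(TRUE, apply(X_obs[, -1, drop = FALSE], 2,
                        function(x) stats::var(x) > 0))
  list(obs = X_obs[, keep, drop = FALSE], mis = X_mis[, keep, drop = FALSE])
}

# draw imputations for a binary variable: posterior coefficient draw, then
# Bernoulli draws at the predicted probabilities
.draw_binary <- function(X_obs, y_obs, X_mis, events, var) {
  Xs <- .drop_constant(X_obs, X_mis)
  X_obs <- Xs$obs; X_mis <- Xs$mis
  fit <- .fit_logistic(X_obs, y_obs)
  if (is.null(fit)) {
    fit <- .fit_logistic(X_obs, y_obs, lambda = 0.1)
    events$log(paste0("ridge fallback for logistic model of ", var))
    if (is.null(fit)) stop("logistic model for ", var,
                           " could not be fitted even with ridge penalty")
  }
  beta <- fit$beta + drop(stats::rnorm(length(fit$beta)) %*% chol(fit$V))
  p <- stats::plogis(drop(X_mis %*% beta))
  stats::runif(length(p)) < p
}

# predictive mean matching: for each missing case, pick one of the `donors`
# observed cases with closest predicted mean and take its observed value.
.pmm_match <- function(yhat_obs, y_obs, yhat_mis, donors) {
  n_obs <- length(y_obs)
  donors <- min(donors, n_obs)
  ord <- order(yhat_obs)
  yh <- yhat_obs[ord]
  yo <- y_obs[ord]
  pos <- findInterval(yhat_mis, yh)
  # the `donors` nearest sorted neighbours lie within this window
  cand <- outer(pos, seq.int(-donors + 1L, donors), "+")
  cand[cand < 1L] <- 1L
  cand[cand > n_obs] <- n_obs
  D <- abs(matrix(yh[cand], nrow(cand)) - yhat_mis)
  pick <- sample.int(donors, length(yhat_mis), replace = TRUE)
  out <- numeric(length(yhat_mis))
  left <- seq_along(yhat_mis)
  for (s in seq_len(donors)) {       # s-th pass extracts the s-th nearest
    j <- max.col(-D[left, , drop = FALSE], ties.method = "first")
    hit <- pick[left] == s
    out[left[hit]] <- yo[cand[cbind(left[hit], j[hit])]]
    D[cbind(left[!hit], j[!hit])] <- Inf
    left <- left[!hit]
    if (!length(left)) break
  }
  out
}

# Bayesian linear regression + PMM draw
.draw_pmm <- function(X_obs, y_obs, X_mis, donors, events, var) {
  Xs <- .drop_constant(X_obs, X_mis)
  X_obs <- Xs$obs; X_mis <- Xs$mis
  p <- ncol(X_obs)
  A <- crossprod(X_obs) + diag(1e-8 * nrow(X_obs), p)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    A <- A + diag(0.1, p)
    ch <- chol(A)
    events$log(paste0("ridge fallback for linear model of ", var))
  }
  Ainv <- chol2inv(ch)
  beta_hat <- drop(Ainv %*% crossprod(X_obs, y_obs))
  res <- y_obs - drop(X_obs %*% beta_hat)
  df <- max(nrow(X_obs) - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_draw <- beta_hat +
    drop(stats::rnorm(p) %*% chol(sigma2 * Ainv))
  .pmm_match(drop(X_obs %*% beta_hat), y_obs, drop(X_mis %*% beta_draw),
             donors)
}

# design matrix of always-observed predictors + current values of the other
# chained variables (FTE time is excluded as a predictor because it is
# structurally absent for released trainees). Continuous predictors are
# standardised so logistic coefficients are O(1) and the normal equations
# well conditioned.
.design <- function(d, current, exclude) {
  z <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mean(x)) / s
  }
  cols <- list(intercept = rep(1, nrow(d)),
               round_r2 = as.numeric(d$round == "R2"),
               cps = z(d$cps_score), pd = z(d$pd_score),
               male = as.numeric(d$gender == "M"),
               bme = as.numeric(d$ethnicity_bme),
               ukpmq = as.numeric(d$uk_pmq))
  for (v in c("withdrew", "stage3_total", "stage3_competent",
              "offer_accepted", "ltft", "oop", "arcp4")) {
    if (v %in% exclude) next
    x <- as.numeric(current[[v]])
    cols[[v]] <- if (v == "stage3_total") z(x) else x
  }
  do.call(cbind, cols)
}

#' Multiply impute a linked cohort
#'
#' Runs fully-conditional-specification imputation of the seven imputable
#' variables (withdrawal, Stage 3 total score, offer accept/decline, LTFT and
#' OOP indicators, ARCP Outcome 4, and FTE-equivalent time to registration),
#' plus the categorical Stage 3 competency outcome as a dependent auxiliary.
#' Missing cells are initialised by random draws from the observed margins,
#' then each variable is re-imputed from its conditional model for
#' `n_iterations` cycles per imputation. Structural rule: FTE time to
#' registration is imputed only where ARCP Outcome 4 (observed or currently
#' imputed) is false, and is structurally absent where it is true — released
#' trainees never register. Records imputed to have LTFT/OOP time receive
#' durations hot-decked from the observed duration distributions.
#'
#' @param cohort a `linked_cohort`.
#' @param config an [imputation_config()].
#' @return an `imputation_set`: list with `datasets` (M completed data
#'   frames; observed cells identical to the input in every one), `config`,
#'   `trace` (per-variable mean of imputed cells per cycle, an M x cycles
#'   matrix each) and `events` (model-fallback log).
#' @export
impute_cohort <- function(cohort, config = imputation_config()) {
  stopifnot(inherits(cohort, "linked_cohort"))
  d <- cohort$data
  miss <- cohort$miss
  n <- nrow(d)
  for (v in ALWAYS_OBSERVED)
    if (anyNA(d[[v]])) stop("always-observed predictor '", v, "' is incomplete")

  chain <- config$variable_order
  chain <- append(chain, "stage3_competent",
                  after = match("stage3_total", chain))
  miss_aux <- is.na(d$stage3_competent)
  miss_of <- function(v) if (v == "stage3_competent") miss_aux else miss[, v]
  binary <- c("withdrew", "stage3_competent", "offer_accepted",
              "ltft", "oop", "arcp4")

  for (v in chain) {
    if (all(miss_of(v)))
      stop("variable '", v, "' is entirely missing: no observed donors")
  }

  events_log <- character()
  events <- list(log = function(msg) events_log <<- c(events_log, msg))

  trace <- lapply(stats::setNames(chain, chain), function(v)
    matrix(NA_real_, config$m, config$n_iterations))
  datasets <- vector("list", config$m)

  for (im in seq_len(config$m)) {
    cur <- d
    with_seed(config$seed + im, {
      # initialise from observed margins
      for (v in chain) {
        mi <- miss_of(v)
        if (any(mi)) {
          donors <- d[[v]][!mi]
          cur[[v]][mi] <- donors[sample.int(length(donors), sum(mi),
                                            replace = TRUE)]
        }
      }
      # structural absence only ever applies to cells that were not observed
      fte_mi <- miss[, "fte_time_to_registration"]
      cur$fte_time_to_registration[cur$arcp4 & fte_mi] <- NA_real_

      for (it in seq_len(config$n_iterations)) {
        for (v in chain) {
          mi <- miss_of(v)
          if (!any(mi)) next
          if (v == "fte_time_to_registration") {
            fit_rows <- which(!mi & !cur$arcp4)
            imp_rows <- which(mi & !cur$arcp4)
            cur$fte_time_to_registration[mi] <- NA_real_
            if (length(imp_rows)) {
              X <- .design(cur, cur, exclude = c(v, "arcp4"))
              cur[[v]][imp_rows] <- .draw_pmm(
                X[fit_rows, , drop = FALSE], cur[[v]][fit_rows],
                X[imp_rows, , drop = FALSE], config$pmm_donors, events, v)
            }
            if (length(imp_rows))
              trace[[v]][im, it] <- mean(cur[[v]][imp_rows])
          } else {
            X <- .design(cur, cur, exclude = v)
            if (v %in% binary) {
              cur[[v]][mi] <- .draw_binary(
                X[!mi, , drop = FALSE], as.numeric(cur[[v]][!mi]),
                X[mi, , drop = FALSE], events, v)
            } else {
              cur[[v]][mi] <- .draw_pmm(
                X[!mi, , drop = FALSE], cur[[v]][!mi],
                X[mi, , drop = FALSE], config$pmm_donors, events, v)
            }
            if (v == "arcp4")   # released trainees never register
              cur$fte_time_to_registration[cur$arcp4 & fte_mi] <- NA_real_
            trace[[v]][im, it] <- mean(as.numeric(cur[[v]][mi]))
          }
        }
      }

      # hot-deck durations for imputed LTFT/OOP indicators
      for (vv in c("ltft", "oop")) {
        mcol <- paste0(vv, "_months")
        fix <- miss[, vv]
        cur[[mcol]][fix & !cur[[vv]]] <- 0
        pos <- which(fix & cur[[vv]])
        donors <- d[[mcol]][!miss[, vv] & !is.na(d[[mcol]]) & d[[mcol]] > 0]
        if (length(pos)) {
          if (!length(donors)) donors <- 1
          cur[[mcol]][pos] <- donors[sample.int(length(donors), length(pos),
                                                replace = TRUE)]
        }
      }
    })
    datasets[[im]] <- cur
  }

  structure(list(datasets = datasets, config = config, trace = trace,
                 events = events_log),
            class = "imputation_set",
            n_years = length(unique(d$year)))
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$config$m, "completed datasets,",
      x$config$n_iterations, "cycles each\n")
  if (length(x$events))
    cat("  model fallbacks:", length(x$events), "\n")
  invisible(x)
}
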