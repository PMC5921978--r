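#' @keywords internal
"_PACKAGE"

# Months are counted from January 2000 (month 0) throughout the internal model;
# outcomes in this problem are only meaningful at month resolution.
.EPOCH_YEAR <- 2000L

#' Convert ISO-8601 dates to months since epoch
#'
#' Dates are carried internally as integer months since January 2000; loaders
#' accept ISO-8601 dates (`YYYY-MM-DD`) and truncate to month resolution.
#'
#' @param x character vector of ISO-8601 dates (or `NA`).
#' @return integer vector of months since 2000-01 (`NA` preserved).
#' @export
month_from_date <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    d <- as.Date(x[ok])
    if (anyNA(d)) stop("unparseable ISO-8601 date(s): ",
                       paste(utils::head(x[ok][is.na(d)], 5), collapse = ", "))
    lt <- as.POSIXlt(d)
    out[ok] <- (lt$year + 1900L - .EPOCH_YEAR) * 12L + lt$mon
  }
  out
}

#' Convert months since epoch back to an ISO-8601 date (first of month)
#' @param m integer months since 2000-01.
#' @return character vector of `YYYY-MM-01` dates.
#' @export
date_from_month <- function(m) {
  out <- rep(NA_character_, length(m))
  ok <- !is.na(m)
  yr <- .EPOCH_YEAR + floor(m[ok] / 12)
  mo <- m[ok] - (yr - .EPOCH_YEAR) * 12 + 1
  out[ok] <- sprintf("%04d-%02d-01", yr, mo)
  out
}

# round-half-up to match how whole-percent figures are usually reported;
# base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse "TRUE"/"FALSE"/"1"/"0"/"" from character CSV cells
.parse_lgl <- function(x) {
  out <- rep(NA, length(x))
  x <- trimws(x)
  out[x %in% c("TRUE", "true", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "false", "F", "0")] <- FALSE
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

.parse_num <- function(x) {
  x <- trimws(x)
  x[!nzchar(x)] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  attr(out, "bad") <- which(!is.na(x) & is.na(out))
  out
}
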