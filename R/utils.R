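# Shared helpers: date handling and rounding conventions.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; FAERS summary tables use
#' commercial rounding (0.5 always up). Used for all printed percentages.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
#' @examples round_half_up(65.395, 2) # 65.40, where round() gives 65.39
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize a FAERS date field to integer YYYYMMDD
#'
#' Blank, garbled, or out-of-range values become 0. Partial dates (YYYY or
#' YYYYMM) are padded with 01 for the missing month/day; use
#' [faers_date_precision()] to recover how much of the date was stated.
#' Years outside 1960-2099 and impossible calendar days are treated as
#' garbled. The function is idempotent: feeding its own output back returns
#' the same values.
#'
#' @param x character (or numeric) vector of raw date fields
#' @return integer vector, 0 where the date is missing or invalid
#' @export
faers_date_normalize <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  out <- integer(length(x))
  digits <- grepl("^[0-9]+$", x)
  n <- nchar(x)
  pad <- ifelse(digits & n == 4L, paste0(x, "0101"),
         ifelse(digits & n == 6L, paste0(x, "01"),
         ifelse(digits & n == 8L, x, "")))
  ok <- nzchar(pad)
  if (any(ok)) {
    yr <- as.integer(substr(pad[ok], 1, 4))
    dt <- as.Date(pad[ok], format = "%Y%m%d")
    valid <- !is.na(dt) & yr >= 1960L & yr <= 2099L
    out[ok][valid] <- as.integer(pad[ok][valid])
  }
  out
}

#' Report the stated precision of a raw FAERS date field
#'
#' @param x character vector of raw date fields
#' @return character vector in `c("day", "month", "year", "none")`
#' @export
faers_date_precision <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  n <- nchar(x)
  digits <- grepl("^[0-9]+$", x)
  norm <- faers_date_normalize(x)
  out <- rep("none", length(x))
  out[digits & n == 4L & norm > 0L] <- "year"
  out[digits & n == 6L & norm > 0L] <- "month"
  out[digits & n == 8L & norm > 0L] <- "day"
  out
}

# integer YYYYMMDD -> Date (NA for 0)
yyyymmdd_to_date <- function(x) {
  x <- as.integer(x)
  x[x <= 0L] <- NA_integer_
  as.Date(sprintf("%08d", x), format = "%Y%m%d")
}

# percentage of a count over a base, printed-table rounding; 0 when base == 0
count_pct <- function(count, base) {
  if (base <= 0) return(rep(0, length(count)))
  round_half_up(100 * count / base, 2)
}
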