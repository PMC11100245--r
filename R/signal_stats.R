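# The four disproportionality statistics with confidence intervals and
# signal thresholds.
#
# All four work off the 2x2 cells (a, b, c, d), N = a + b + c + d:
#   ROR  = ad / bc,          ln-scale SE = sqrt(1/a + 1/b + 1/c + 1/d)
#   PRR  = (a/(a+b)) / (c/(c+d)),
#          ln-scale SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))
#   IC   = log2( a N / ((a+b)(a+c)) ), reported via its posterior moments
#          E(IC), V(IC) under the BCPNN Dirichlet priors; IC025 = E - 2 SD
#   EBGM = a N / ((a+c)(a+b)) (observed/expected reporting ratio), with a
#          log-scale CI using the same SE as the ROR
# Conventional thresholds: a >= 3 with the ROR/PRR CI lower bound > 1,
# IC025 > 0, EBGM05 > 2.

.not_evaluable <- function(what) {
  stop(structure(class = c("faers_not_evaluable", "error", "condition"),
                 list(message = paste0(what, " not evaluable (zero cell)"),
                      call = sys.call(-1))))
}

.cells <- function(a, b, c, d) {
  if (inherits(a, "contingency_table")) {
    list(a = a$a, b = a$b, c = a$c, d = a$d)
  } else if (is.list(a) && all(c("a", "b", "c", "d") %in% names(a))) {
    a[c("a", "b", "c", "d")]
  } else {
    list(a = a, b = b, c = c, d = d)
  }
}

.ror_vec <- function(a, b, c, d) {
  est <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = est, ror_lo = est * exp(-1.96 * se), ror_hi = est * exp(1.96 * se))
}

.prr_vec <- function(a, b, c, d) {
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(prr = est, prr_lo = est * exp(-1.96 * se), prr_hi = est * exp(1.96 * se))
}

.chi2_vec <- function(a, b, c, d, yates = FALSE) {
  # doubles: the denominator overflows 32-bit integers even at modest N
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(num - N / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- N * num^2 / denom
  out[denom == 0] <- 0
  out
}

.bcpnn_vec <- function(a, b, c, d, priors) {
  N <- a + b + c + d
  al <- priors$alpha; be <- priors$beta
  al1 <- priors$alpha1; be1 <- priors$beta1; g11 <- priors$gamma11
  g <- g11 * (N + al) * (N + be) / ((a + b + al1) * (a + c + be1))
  e_ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + g) * (a + b + al1) * (a + c + be1)))
  v_ic <- (1 / log(2)^2) * (
    (N - a + g - g11) / ((a + g11) * (1 + N + g)) +
      (N - (a + b) + al - al1) / ((a + b + al1) * (1 + N + al)) +
      (N - (a + c) + be - be1) / ((a + c + be1) * (1 + N + be)))
  list(ic = e_ic, v_ic = v_ic, ic025 = e_ic - 2 * sqrt(v_ic))
}

.ebgm_vec <- function(a, b, c, d) {
  N <- a + b + c + d
  est <- a * N / ((a + c) * (a + b))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ebgm = est, ebgm_lo = est * exp(-1.96 * se),
       ebgm_hi = est * exp(1.96 * se))
}

#' BCPNN prior parameters
#'
#' Dirichlet prior pseudo-counts for the information component's posterior
#' moments. The defaults `(alpha, beta, alpha1, beta1, gamma11) =
#' (2, 2, 1, 1, 1)` are the standard choice and reproduce published IC
#' columns; `gamma` itself is derived from the margins, not configured.
#'
#' @param alpha,beta,alpha1,beta1,gamma11 positive reals
#' @return a `bcpnn_priors` list
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1,
                         gamma11 = 1) {
  vals <- c(alpha, beta, alpha1, beta1, gamma11)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all BCPNN priors must be positive", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, alpha1 = alpha1,
                 beta1 = beta1, gamma11 = gamma11), class = "bcpnn_priors")
}

#' Reporting odds ratio with 95% CI
#'
#' @param a a `contingency_table`, or the `a` cell when `b`, `c`, `d` are
#'   given
#' @param b,c,d remaining cells
#' @return named list `ror`, `ror_lo`, `ror_hi`
#' @export
#' @examples
#' ror(contingency_cells(3, 7, 30, 960))
ror <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .cells(a, b, c, d)
  if (any(unlist(x) <= 0)) .not_evaluable("ROR")
  .ror_vec(x$a, x$b, x$c, x$d)
}

#' Proportional reporting ratio with 95% CI
#'
#' @inheritParams ror
#' @return named list `prr`, `prr_lo`, `prr_hi`
#' @export
prr <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .cells(a, b, c, d)
  if (any(x$a <= 0) || any(x$c <= 0)) .not_evaluable("PRR")
  .prr_vec(x$a, x$b, x$c, x$d)
}

#' Pearson chi-squared on the 2x2 table
#'
#' @inheritParams ror
#' @param yates apply the Yates continuity correction (`|ad - bc|` reduced
#'   by `N/2`, floored at zero, before squaring); default off
#' @return the chi-squared statistic (0 when a margin is zero)
#' @export
chi_square <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  x <- .cells(a, b, c, d)
  .chi2_vec(x$a, x$b, x$c, x$d, yates = yates)
}

#' BCPNN information component
#'
#' Posterior expectation and variance of the information component
#' `IC = log2 p(x, y) / (p(x) p(y))` under the BCPNN priors, and the
#' conventional lower bound `IC025 = E(IC) - 2 sqrt(V(IC))`. Defined for
#' every table (including `a = 0`) thanks to the prior pseudo-counts.
#'
#' @inheritParams ror
#' @param priors a [bcpnn_priors()] list
#' @return named list `ic` (the posterior expectation `E(IC)`), `v_ic`,
#'   `ic025`
#' @export
bcpnn_ic <- function(a, b = NULL, c = NULL, d = NULL,
                     priors = bcpnn_priors()) {
  x <- .cells(a, b, c, d)
  if (sum(unlist(x)) <= 0) stop("empty table", call. = FALSE)
  .bcpnn_vec(x$a, x$b, x$c, x$d, priors)
}

#' Empirical Bayes geometric mean (observed/expected form) with 95% CI
#'
#' Implements the observed-over-expected reporting ratio
#' `EBGM = a N / ((a + c)(a + b))` with a log-scale CI; this is the
#' quantity printed in typical FAERS signal tables (EBGM05 = lower bound).
#' It is not the full DuMouchel Gamma-Poisson-shrinker posterior mean; see
#' the methods vignette for why that form is used here.
#'
#' @inheritParams ror
#' @return named list `ebgm`, `ebgm_lo`, `ebgm_hi` (`ebgm_lo`/`ebgm_hi`
#'   are `NA` when a cell is zero but the margins allow a point value)
#' @export
ebgm <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- .cells(a, b, c, d)
  if (any(x$a <= 0) || any((x$a + x$b) <= 0) || any((x$a + x$c) <= 0)) {
    .not_evaluable("EBGM")
  }
  out <- .ebgm_vec(x$a, x$b, x$c, x$d)
  if (any(unlist(x) <= 0)) out$ebgm_lo <- out$ebgm_hi <- NA_real_
  out
}

#' Batch signal estimates for a set of 2x2 tables
#'
#' Vectorized evaluation of all four statistics over a table of cells, as
#' produced by [all_tables()]. Tables with a zero cell get `NA` for the
#' statistics that are not evaluable there (no continuity correction is
#' applied anywhere) and `evaluable = FALSE`.
#'
#' @param tables data.frame/data.table with columns `a`, `b`, `c`, `d`
#'   (other columns such as `event` are carried through)
#' @param priors a [bcpnn_priors()] list
#' @param yates logical, passed to the chi-squared
#' @return data.table: input columns plus `ror`, `ror_lo`, `ror_hi`, `prr`,
#'   `prr_lo`, `prr_hi`, `chi2`, `ic`, `v_ic`, `ic025`, `ebgm`, `ebgm_lo`,
#'   `ebgm_hi`, `evaluable`
#' @export
signal_estimates <- function(tables, priors = bcpnn_priors(), yates = FALSE) {
  dt <- as.data.table(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(dt)))
  a <- as.numeric(dt$a); b <- as.numeric(dt$b)
  c <- as.numeric(dt$c); d <- as.numeric(dt$d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  na <- rep(NA_real_, nrow(dt))
  r <- list(ror = na, ror_lo = na, ror_hi = na)
  p <- list(prr = na, prr_lo = na, prr_hi = na)
  e <- list(ebgm = na, ebgm_lo = na, ebgm_hi = na)
  if (any(ok)) {
    rr <- .ror_vec(a[ok], b[ok], c[ok], d[ok])
    pp <- .prr_vec(a[ok], b[ok], c[ok], d[ok])
    ee <- .ebgm_vec(a[ok], b[ok], c[ok], d[ok])
    for (nm in names(rr)) r[[nm]][ok] <- rr[[nm]]
    for (nm in names(pp)) p[[nm]][ok] <- pp[[nm]]
    for (nm in names(ee)) e[[nm]][ok] <- ee[[nm]]
  }
  bc <- .bcpnn_vec(a, b, c, d, priors)
  out <- cbind(dt,
               as.data.table(r), as.data.table(p),
               chi2 = .chi2_vec(a, b, c, d, yates = yates),
               as.data.table(bc), as.data.table(e),
               evaluable = ok)
  out[]
}

#' Apply the signal thresholds
#'
#' Flags each pair against the conventional thresholds: ROR and PRR pass
#' when `a >= 3` and the 95% CI lower bound exceeds 1; BCPNN passes when
#' `IC025 > 0`; EBGM passes when `EBGM05 > 2`. `NA` statistics never pass.
#' The combined flag follows `rule`: `"all"` (every method), `"any"`, or a
#' character subset of `c("ror", "prr", "bcpnn", "ebgm")` that must all
#' pass.
#'
#' @param estimates output of [signal_estimates()]
#' @param rule `"all"`, `"any"`, or a subset of method names
#' @param min_a minimum case count for the ROR/PRR thresholds (default 3)
#' @return `estimates` plus logical columns `pass_ror`, `pass_prr`,
#'   `pass_bcpnn`, `pass_ebgm`, `combined`
#' @export
evaluate_signal <- function(estimates, rule = "all", min_a = 3L) {
  dt <- as.data.table(estimates)
  f <- function(x) !is.na(x) & x
  dt[, pass_ror := f(a >= min_a & ror_lo > 1)]
  dt[, pass_prr := f(a >= min_a & prr_lo > 1)]
  dt[, pass_bcpnn := f(ic025 > 0)]
  dt[, pass_ebgm := f(ebgm_lo > 2)]
  flags <- c("ror", "prr", "bcpnn", "ebgm")
  if (identical(rule, "all")) {
    use <- flags
  } else if (identical(rule, "any")) {
    dt[, combined := pass_ror | pass_prr | pass_bcpnn | pass_ebgm]
    return(dt[])
  } else {
    use <- match.arg(rule, flags, several.ok = TRUE)
  }
  cols <- paste0("pass_", use)
  dt[, combined := Reduce(`&`, .SD), .SDcols = cols]
  dt[]
}
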