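# Reconstructing full-database statistics from published summary rows.
#
# Published FAERS signal tables print, per event, the case count a and the
# rounded statistics (ROR, PRR, chi2, IC, EBGM) but not the global
# denominators: T = total target-drug pairs (a + b) and N = total pairs.
# Two printed numbers pin them down:
#   * eliminating c between the ROR and PRR formulas gives, per row,
#       T = a (R - 1/PRR) / (R - 1),   R = ROR / PRR,
#     which does not involve N at all;
#   * EBGM = PRR * N / (N + T (PRR - 1)) is N-sensitive for rows where
#     PRR and EBGM visibly differ (small-a rows with large PRR).
# A least-squares fit over a few calibration rows recovers (T, N); every
# other printed statistic is then predicted from (a, PRR, T, N) alone.

#' Published per-event summary rows shipped with the package
#'
#' The transcribed signal-table rows (event label, case count, and the
#' printed ROR/PRR/chi-squared/IC/EBGM values with CI bounds) for the
#' vilazodone analysis the package reproduces at desk scale.
#'
#' @param path optional path to an alternative CSV with the same columns
#' @return data.table with columns `source_table`, `soc`, `pt`, `a`,
#'   `ror`, `ror_lo`, `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chi2`, `ic`,
#'   `ic025`, `ebgm`, `ebgm05`
#' @export
printed_pt_rows <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "printed_pt_rows.csv",
                        package = "faersignal", mustWork = TRUE)
  }
  fread(path, colClasses = list(character = c("source_table", "soc", "pt")))
}

#' Target-drug pair total implied by one printed row
#'
#' Closed form for `T = a + b` from a row's case count and printed ROR and
#' PRR, obtained by eliminating the background cell `c` between the two
#' formulas. Requires `ROR != PRR`; `R = ROR / PRR <= 1` is inconsistent
#' with a positive background and raises an error.
#'
#' @param a case count
#' @param ror,prr printed values
#' @return the implied `T` (a real; printed rounding makes it approximate)
#' @export
#' @examples
#' t_from_row(633, 4.19, 4.05) # about 1.44e4
t_from_row <- function(a, ror, prr) {
  R <- ror / prr
  if (any(R <= 1)) {
    stop("inconsistent row: ROR <= PRR implies no positive background",
         call. = FALSE)
  }
  a * (R - 1 / prr) / (R - 1)
}

#' Rebuild a 2x2 table from (a, PRR) and global denominators
#'
#' Inverts the cell identities: `b = T - a`, `c = a (N - T) / (T PRR)`,
#' `d = N - T - c`. Cells are real-valued (the printed inputs are rounded).
#'
#' @param a case count
#' @param prr printed PRR
#' @param T,N global pair denominators (see [fit_globals()])
#' @return a `contingency_table`
#' @export
reconstruct_table <- function(a, prr, T, N) {
  b <- T - a
  c_ <- a * (N - T) / (T * prr)
  d <- N - T - c_
  if (b <= 0 || c_ <= 0 || d <= 0) {
    stop("inconsistent inputs: reconstructed cell(s) non-positive",
         call. = FALSE)
  }
  contingency_cells(a, b, c_, d)
}

# predicted ROR from (a, prr, T): the N-free closed form
.pred_ror <- function(a, prr, T) prr * (T - a / prr) / (T - a)
# predicted EBGM from (a, prr, T, N)
.pred_ebgm <- function(prr, T, N) prr * N / (N + T * (prr - 1))

#' Fit the global pair denominators (T, N) to printed rows
#'
#' Least squares on the squared relative error of the predicted ROR and
#' EBGM against the printed values, over the calibration rows. At least two
#' rows are needed, one of which must have a printed EBGM visibly below its
#' PRR (otherwise N is unidentified). The default calibration set
#' (Diarrhoea, Nausea, Sleep paralysis) deliberately excludes the rows used
#' as reproduction targets.
#'
#' @param rows data.table as from [printed_pt_rows()]
#' @param calibration PT labels of the rows to fit on
#' @return a `faers_globals` list: `T`, `N`, `residual`, `calibration`
#' @export
fit_globals <- function(rows,
                        calibration = c("Diarrhoea", "Nausea",
                                        "Sleep paralysis")) {
  rows <- as.data.table(rows)
  cal <- unique(rows[pt %in% calibration, .(pt, a, ror, prr, ebgm)])
  if (nrow(cal) < 2L) {
    stop("need at least two calibration rows to identify (T, N)",
         call. = FALSE)
  }
  obj <- function(p) {
    T <- exp(p[1]); N <- exp(p[2])
    if (N <= T || T <= max(cal$a)) return(1e6)
    sum((.pred_ror(cal$a, cal$prr, T) / cal$ror - 1)^2 +
          (.pred_ebgm(cal$prr, T, N) / cal$ebgm - 1)^2)
  }
  T0 <- mean(t_from_row(cal$a, cal$ror, cal$prr))
  sensitive <- cal$prr - cal$ebgm > 0.5
  N0 <- if (any(sensitive)) {
    i <- which(sensitive)[which.min(cal$a[sensitive])]
    cal$ebgm[i] * T0 * (cal$prr[i] - 1) / (cal$prr[i] - cal$ebgm[i])
  } else {
    3000 * T0
  }
  fit <- optim(log(c(T0, N0)), obj,
               control = list(reltol = 1e-14, maxit = 10000L))
  fit <- optim(fit$par, obj, control = list(reltol = 1e-14, maxit = 10000L))
  if (!fit$convergence %in% c(0L, 10L) || !is.finite(fit$value)) {
    stop("global denominator fit did not converge; residual ", fit$value,
         call. = FALSE)
  }
  structure(list(T = exp(fit$par[1]), N = exp(fit$par[2]),
                 residual = fit$value, calibration = cal$pt),
            class = "faers_globals")
}

#' @export
print.faers_globals <- function(x, ...) {
  cat(sprintf(
    "<faers_globals>: T = %.0f target pairs, N = %.3e total pairs\n",
    x$T, x$N))
  cat("  residual ", format(x$residual, digits = 3), ", calibrated on: ",
      paste(x$calibration, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict every statistic for a printed row
#'
#' Reconstructs the 2x2 table from `(a, prr)` and fitted globals, then
#' evaluates the full set of signal statistics.
#'
#' @param a case count
#' @param prr printed PRR
#' @param globals a `faers_globals` from [fit_globals()]
#' @param priors BCPNN priors
#' @param yates chi-squared variant
#' @return one-row data.table of [signal_estimates()] output
#' @export
predict_row <- function(a, prr, globals, priors = bcpnn_priors(),
                        yates = FALSE) {
  stopifnot(inherits(globals, "faers_globals"))
  tab <- reconstruct_table(a, prr, globals$T, globals$N)
  signal_estimates(data.table(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
                   priors = priors, yates = yates)
}

#' Compare predictions against every printed row
#'
#' Runs [predict_row()] for each row and reports the relative (ROR,
#' chi-squared, EBGM) or absolute (IC, IC025) deviation from the printed
#' value, with pass flags at the rounding-propagation tolerances (2%
#' relative, 0.05 absolute for IC).
#'
#' @param rows printed rows, default [printed_pt_rows()]
#' @param globals fitted globals, default [fit_globals()] on `rows`
#' @param rel_tol,ic_tol tolerances for the pass flags
#' @return data.table with one row per printed row: predicted values,
#'   deviations, and `pass_*` flags
#' @export
validate_printed_rows <- function(rows = printed_pt_rows(),
                                  globals = fit_globals(rows),
                                  rel_tol = 0.02, ic_tol = 0.05) {
  rows <- unique(as.data.table(rows), by = "pt")
  pred <- rbindlist(lapply(seq_len(nrow(rows)), function(i) {
    predict_row(rows$a[i], rows$prr[i], globals)
  }))
  out <- data.table(
    pt = rows$pt, a = rows$a,
    ror_printed = rows$ror, ror_pred = pred$ror,
    chi2_printed = rows$chi2, chi2_pred = pred$chi2,
    ic_printed = rows$ic, ic_pred = pred$ic,
    ebgm_printed = rows$ebgm, ebgm_pred = pred$ebgm
  )
  out[, `:=`(
    pass_ror = abs(ror_pred / ror_printed - 1) <= rel_tol,
    pass_chi2 = abs(chi2_pred / chi2_printed - 1) <= rel_tol,
    pass_ic = abs(ic_pred - ic_printed) <= ic_tol,
    pass_ebgm = abs(ebgm_pred / ebgm_printed - 1) <= rel_tol
  )]
  out[]
}
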