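# Drug-event 2x2 contingency tables at PT and SOC level.
#
# The counting unit is the report x event pair, not the raw report: each
# surviving report contributes one pair per distinct PT (or distinct mapped
# primary SOC), flagged by whether the report names the target drug. The
# 2x2 cells for an event are then
#   a = target reports with the event        b = target pairs without it
#   c = background reports with the event    d = remaining background pairs
# with a + b + c + d = N, the total pair count.

#' Build the report-by-event pair universe
#'
#' @param bundle a deduplicated `faers_bundle`
#' @param cohort character vector of target-drug `primaryid`s (from
#'   [select_target_reports()])
#' @param vocabulary a `vocabulary_map`; required when `level = "soc"`,
#'   where each PT is replaced by its primary SOC (unmapped PTs are
#'   excluded and counted)
#' @param level `"pt"` or `"soc"`
#' @return a `pair_universe`: list with `level`, `pairs` (data.table of
#'   `primaryid`, `event`, `target`), `T` (target pair count), `N` (total
#'   pair count), and `n_unmapped`
#' @export
build_pairs <- function(bundle, cohort, vocabulary = NULL,
                        level = c("pt", "soc")) {
  stopifnot(inherits(bundle, "faers_bundle"))
  level <- match.arg(tolower(level[1]), c("pt", "soc"))
  reac <- bundle$reactions[, .(primaryid, event = pt)]
  n_unmapped <- 0L
  if (level == "soc") {
    if (is.null(vocabulary)) {
      stop("SOC-level pairs need a PT/SOC vocabulary", call. = FALSE)
    }
    soc <- map_pt_to_soc(vocabulary, reac$event)$soc_name
    n_unmapped <- sum(is.na(soc))
    if (n_unmapped > 0L) {
      message("faersignal: ", n_unmapped,
              " reaction mention(s) with unmapped PT excluded at SOC level")
    }
    reac <- reac[!is.na(soc)][, event := soc[!is.na(soc)]]
  }
  pairs <- unique(reac)
  pairs[, target := primaryid %chin% cohort]
  structure(list(level = level, pairs = pairs,
                 T = sum(pairs$target), N = nrow(pairs),
                 n_unmapped = n_unmapped),
            class = "pair_universe")
}

#' @export
print.pair_universe <- function(x, ...) {
  cat("<pair_universe ", x$level, ">: N = ", x$N, " pairs (", x$T,
      " on the target drug), ", length(unique(x$pairs$event)),
      " distinct events\n", sep = "")
  invisible(x)
}

#' Construct a 2x2 table from explicit cells
#'
#' @param a,b,c,d non-negative cell counts (reconstructed tables may carry
#'   non-integer cells)
#' @return a `contingency_table` with fields `a`, `b`, `c`, `d`, `N`
#' @export
contingency_cells <- function(a, b, c, d) {
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

#' 2x2 table for one event label
#'
#' @param universe a `pair_universe`
#' @param event_label event (PT or SOC) label; an absent label yields
#'   `a = c = 0`
#' @return a `contingency_table`
#' @export
contingency_table <- function(universe, event_label) {
  stopifnot(inherits(universe, "pair_universe"))
  ev <- universe$pairs[event == event_label]
  a <- sum(ev$target)
  c_ <- nrow(ev) - a
  contingency_cells(a, universe$T - a, c_, universe$N - universe$T - c_)
}

#' All 2x2 tables above a report-count floor
#'
#' One row per event label with `a >= min_a`, ordered by `a` descending and
#' label ascending. The conventional floor `min_a = 3` mirrors the "at
#' least three case reports" signal precondition.
#'
#' @param universe a `pair_universe`
#' @param min_a minimum `a` cell (default 3)
#' @return data.table with columns `event`, `a`, `b`, `c`, `d`, `N`
#' @export
all_tables <- function(universe, min_a = 3L) {
  stopifnot(inherits(universe, "pair_universe"), min_a >= 0)
  tab <- universe$pairs[, .(a = sum(target), n_event = .N), by = event]
  tab[, `:=`(b = universe$T - a, c = n_event - a)]
  tab[, d := universe$N - universe$T - c]
  tab[, n_event := NULL]
  tab[, N := universe$N]
  tab <- tab[a >= min_a]
  setorderv(tab, c("a", "event"), order = c(-1L, 1L))
  tab[]
}
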