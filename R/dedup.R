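# FDA-recommended deduplication of case versions and deleted-case removal.
#
# A FAERS case (CASEID) can appear as several report versions (PRIMARYID).
# The recommended rule keeps, per case, the version with the largest FDA
# receipt date, breaking ties by the largest PRIMARYID. Deleted-case lists
# are applied afterwards.

# comparable rank for primaryid: numeric when every id parses as an integer
# (doubles are exact far beyond FAERS id widths), else zero-padded strings
.pid_rank <- function(primaryid) {
  if (all(grepl("^[0-9]+$", primaryid))) {
    as.numeric(primaryid)
  } else {
    w <- max(nchar(primaryid))
    formatC(primaryid, width = w, flag = "0")
  }
}

#' Deduplicate FAERS case versions
#'
#' Keeps exactly one DEMO record per `caseid`: the one with the largest
#' `fda_dt`, then (among ties) the largest `primaryid`. The result is
#' sorted by `caseid`, so the output is independent of input order. The
#' operation is idempotent.
#'
#' @param demo data.table of DEMO records (from [parse_quarter()]); needs
#'   columns `primaryid`, `caseid`, `fda_dt`
#' @return filtered DEMO data.table with attribute `dedup` holding
#'   `list(n_in, n_out, versions_collapsed)`
#' @export
deduplicate <- function(demo) {
  demo <- as.data.table(demo)
  n_in <- nrow(demo)
  if (n_in == 0L) {
    out <- copy(demo)
  } else {
    stopifnot(!anyDuplicated(demo$primaryid)) # one row per report version
    d <- copy(demo)[, pid_rank := .pid_rank(primaryid)]
    setorderv(d, c("caseid", "fda_dt", "pid_rank"))
    out <- d[d[, .I[.N], by = caseid]$V1]
    out[, pid_rank := NULL]
  }
  setattr(out, "dedup", list(n_in = n_in, n_out = nrow(out),
                             versions_collapsed = n_in - nrow(out)))
  out[]
}

#' Remove deleted cases
#'
#' Drops every record whose `caseid` appears in a deleted-case list. Run
#' after [deduplicate()], matching the order of the source procedure.
#'
#' @param demo deduplicated DEMO data.table
#' @param deleted_caseids character vector of case ids (union over quarters)
#' @return filtered data.table with attribute `n_removed`
#' @export
remove_deleted <- function(demo, deleted_caseids) {
  demo <- as.data.table(demo)
  keep <- !(demo$caseid %chin% as.character(deleted_caseids))
  out <- demo[keep]
  setattr(out, "n_removed", sum(!keep))
  out[]
}

#' Restrict mention tables to surviving reports
#'
#' After deduplication and deleted-case removal, drops drug, reaction,
#' outcome, and therapy mentions whose `primaryid` no longer has a DEMO
#' record.
#'
#' @param bundle a `faers_bundle`
#' @param surviving_keys character vector of surviving `primaryid`s
#' @return the bundle with all five tables filtered to those keys
#' @export
filter_mentions <- function(bundle, surviving_keys) {
  stopifnot(inherits(bundle, "faers_bundle"))
  bundle$demo <- bundle$demo[primaryid %chin% surviving_keys]
  for (nm in c("drugs", "reactions", "outcomes", "therapies")) {
    bundle[[nm]] <- bundle[[nm]][primaryid %chin% surviving_keys]
  }
  bundle
}

#' Deduplicate a whole bundle
#'
#' Convenience wrapper: [deduplicate()], then [remove_deleted()], then
#' [filter_mentions()]. The summary is stored as `bundle$dedup_summary`.
#'
#' @param bundle a `faers_bundle`
#' @param deleted_caseids character vector of deleted case ids
#' @return the deduplicated bundle
#' @export
dedup_bundle <- function(bundle, deleted_caseids = character()) {
  stopifnot(inherits(bundle, "faers_bundle"))
  demo <- deduplicate(bundle$demo)
  dd <- attr(demo, "dedup")
  demo <- remove_deleted(demo, deleted_caseids)
  nrem <- attr(demo, "n_removed")
  bundle <- filter_mentions(bundle, demo$primaryid)
  bundle$demo <- demo
  bundle$dedup_summary <- data.table(
    input_reports = dd$n_in,
    versions_collapsed = dd$versions_collapsed,
    deleted_removed = nrem,
    output_reports = nrow(demo)
  )
  bundle
}
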