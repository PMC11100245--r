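# Target-drug cohort selection and the descriptive report profile.

.age_factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                 DY = 1 / 365.25, HR = 1 / 8766)
.reporter_labels <- c(CN = "Consumer", PH = "Pharmacist", MD = "Physician",
                      OT = "Other Health Professionals",
                      HP = "Other Health Professionals", LW = "Lawyer")
.outcome_labels <- c(DE = "Death", DS = "Disability",
                     HO = "Hospitalization-Initial or Prolonged",
                     LT = "Life-Threatening", CA = "Congenital Anomaly",
                     RI = "Required Intervention", OT = "Other")
.age_breaks <- c(-Inf, 18, 45, 65, 75, Inf)
.age_labels <- c("<18", "18-45", "45-65", "65-75", ">=75")
.onset_breaks <- c(-1, 30, 60, 90, 120, 150, 180, 360, Inf)
.onset_labels <- c("0-30", "31-60", "61-90", "91-120", "121-150",
                   "151-180", "181-360", ">360")

#' Describe the drug of interest
#'
#' A query holds the match strings (generic name plus brand synonyms), the
#' FAERS role codes that qualify a mention (primary suspect `PS`, secondary
#' suspect `SS`, concomitant `C`, interacting `I`), and which free-text
#' fields to search. Matching is case-insensitive substring matching, the
#' practical choice for FAERS's free-text drug names.
#'
#' @param names character vector of match strings (non-empty)
#' @param roles subset of `c("PS", "SS", "C", "I")`
#' @param match_fields subset of `c("drugname", "active_ingredient")`
#' @return a `drug_query` object
#' @export
#' @examples
#' drug_query(c("vilazodone", "viibryd"), roles = "PS")
drug_query <- function(names, roles = "PS",
                       match_fields = c("drugname", "active_ingredient")) {
  names <- toupper(trimws(as.character(names)))
  names <- names[nzchar(names)]
  roles <- toupper(roles)
  match_fields <- match.arg(match_fields, several.ok = TRUE)
  if (!length(names)) stop("drug query needs at least one name", call. = FALSE)
  if (!length(roles) || !all(roles %in% .role_codes)) {
    stop("roles must be a non-empty subset of PS, SS, C, I", call. = FALSE)
  }
  structure(list(names = unique(names), roles = unique(roles),
                 match_fields = match_fields), class = "drug_query")
}

# logical vector over drug-mention rows
.match_mentions <- function(drugs, query) {
  hit <- rep(FALSE, nrow(drugs))
  for (f in query$match_fields) {
    field <- drugs[[f]]
    field[is.na(field)] <- ""
    for (nm in query$names) hit <- hit | grepl(nm, field, fixed = TRUE)
  }
  hit & (drugs$role %chin% query$roles)
}

#' Select the reports naming the target drug
#'
#' A report enters the cohort iff it has at least one drug mention whose
#' role is in `query$roles` and whose drugname or active ingredient
#' contains one of the query names (case-insensitive substring).
#'
#' @param bundle a deduplicated `faers_bundle`
#' @param query a [drug_query()]
#' @return sorted character vector of cohort `primaryid`s
#' @export
select_target_reports <- function(bundle, query) {
  stopifnot(inherits(bundle, "faers_bundle"), inherits(query, "drug_query"))
  hit <- .match_mentions(bundle$drugs, query)
  sort(unique(bundle$drugs$primaryid[hit]))
}

# age in years from value + unit; NA when either is missing
.age_years <- function(age_value, age_unit) {
  f <- .age_factor[age_unit]
  out <- age_value * as.numeric(f)
  out[is.na(age_unit) | is.na(age_value)] <- NA_real_
  out
}

.tally <- function(labels, levels, base, category) {
  if (!length(levels)) {
    return(data.table(category = character(), level = character(),
                      count = integer(), percentage = numeric()))
  }
  labels <- as.character(labels)
  labels[is.na(labels)] <- "Unknown"
  cnt <- table(factor(labels, levels = levels))
  data.table(category = category, level = levels,
             count = as.integer(cnt[levels]),
             percentage = count_pct(as.integer(cnt[levels]), base))
}

#' Time from therapy start to adverse event, binned
#'
#' For each cohort report, onset days = event date minus the earliest
#' therapy start date among therapy records linked (via `dsg_drug_seq`) to
#' a drug mention matching the query. Negative or undated spans fall in
#' `"Unknown"`. Bins are closed as conventionally printed: `[0,30]`,
#' `[31,60]`, ..., `[181,360]`, `>360`.
#'
#' @param bundle a deduplicated `faers_bundle`
#' @param cohort character vector of cohort `primaryid`s
#' @param query the [drug_query()] used to select the cohort
#' @return data.table with columns `category`, `level`, `count`,
#'   `percentage` (percent of the cohort)
#' @export
onset_days <- function(bundle, cohort, query) {
  stopifnot(inherits(bundle, "faers_bundle"))
  days <- compute_onset_days(bundle, cohort, query)
  lab <- cut(days, breaks = .onset_breaks, labels = .onset_labels)
  .tally(lab, c(.onset_labels, "Unknown"), length(cohort), "onset_days")
}

#' @rdname onset_days
#' @return `compute_onset_days()`: named numeric vector of onset days per
#'   cohort report (`NA` where undefined)
#' @export
compute_onset_days <- function(bundle, cohort, query) {
  hit <- .match_mentions(bundle$drugs, query)
  target <- bundle$drugs[hit & primaryid %chin% cohort,
                         .(primaryid, drug_seq)]
  ther <- bundle$therapies[start_dt > 0L]
  linked <- ther[target, on = c(primaryid = "primaryid",
                                dsg_drug_seq = "drug_seq"), nomatch = NULL]
  if (!nrow(linked)) {
    return(setNames(rep(NA_real_, length(cohort)), cohort))
  }
  first_start <- linked[, .(start_dt = min(start_dt)), by = primaryid]
  demo <- bundle$demo[primaryid %chin% cohort,
                      .(primaryid, event_dt)][first_start, on = "primaryid"]
  days <- as.numeric(yyyymmdd_to_date(demo$event_dt) -
                       yyyymmdd_to_date(demo$start_dt))
  days[!is.na(days) & days < 0] <- NA_real_
  out <- setNames(rep(NA_real_, length(cohort)), cohort)
  out[demo$primaryid] <- days
  out
}

#' Descriptive profile of a report cohort
#'
#' Tabulates the cohort by sex, age group, reporter occupation, reporter
#' country, report year, serious-outcome codes, and (when `query` is given)
#' time to onset. Ages are converted to years using the FAERS unit codes
#' (`YR`, `DEC`, `MON`, `WK`, `DY`, `HR`); age groups are left-closed,
#' right-open at the joints (`[18,45)`, `[45,65)`, `[65,75)`, `[75,Inf)`),
#' which keeps the printed-style bins disjoint. Percentages are
#' `100 * count / cohort size`, rounded half-up to two decimals. Within
#' each category except outcomes, counts (including `Unknown`) sum to the
#' cohort size; a report can carry several outcome codes, each counted once
#' per report.
#'
#' @param bundle a deduplicated `faers_bundle`
#' @param cohort character vector of cohort `primaryid`s
#' @param query optional [drug_query()]; when supplied, onset-day bins are
#'   appended (they need the drug-therapy linkage)
#' @return data.table with columns `category`, `level`, `count`, `percentage`
#' @export
profile_cohort <- function(bundle, cohort, query = NULL) {
  stopifnot(inherits(bundle, "faers_bundle"))
  cohort <- as.character(cohort)
  demo <- bundle$demo[primaryid %chin% cohort]
  n <- length(cohort)

  sex_lab <- c(F = "Female", M = "Male", UNK = "Unknown")[demo$sex]
  age <- .age_years(demo$age_value, demo$age_unit)
  age_lab <- as.character(cut(age, breaks = .age_breaks, labels = .age_labels,
                              right = FALSE))
  rep_lab <- .reporter_labels[demo$reporter_occupation]
  country <- demo$reporter_country
  country[is.na(country)] <- "Not Specified"
  country_levels <- names(sort(table(country), decreasing = TRUE))
  year_lab <- ifelse(demo$report_year > 0L, as.character(demo$report_year),
                     NA_character_)
  year_levels <- sort(unique(year_lab[!is.na(year_lab)]))

  out <- rbindlist(list(
    .tally(sex_lab, c("Female", "Male", "Unknown"), n, "sex"),
    .tally(age_lab, c(.age_labels, "Unknown"), n, "age"),
    .tally(rep_lab, c(unique(unname(.reporter_labels)), "Unknown"), n,
           "reporter"),
    .tally(country, country_levels, n, "country"),
    .tally(year_lab, c(year_levels, "Unknown"), n, "report_year")
  ))

  oc <- unique(bundle$outcomes[primaryid %chin% cohort])
  oc_counts <- vapply(names(.outcome_labels),
                      function(code) sum(oc$outcome_code == code), 0L)
  out <- rbind(out, data.table(category = "outcome",
                               level = unname(.outcome_labels),
                               count = unname(oc_counts),
                               percentage = count_pct(unname(oc_counts), n)))
  if (!is.null(query)) out <- rbind(out, onset_days(bundle, cohort, query))
  out[]
}
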