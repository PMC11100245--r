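# Reading and normalizing FAERS quarterly ASCII extracts.
#
# The quarterly packages ship five '$'-delimited tables per quarter (DEMO,
# DRUG, REAC, OUTC, THER) plus, since 2019Q1, a deleted-case list. Two
# header dialects exist: the modern one keyed by PRIMARYID/CASEID and the
# legacy (pre-2012Q3) one keyed by ISR/CASE. Both are normalized to one
# canonical record layout here.

# canonical column -> accepted header aliases, per table
.demo_aliases <- list(
  primaryid = c("PRIMARYID", "ISR"),
  caseid = c("CASEID", "CASE"),
  fda_dt = "FDA_DT",
  event_dt = "EVENT_DT",
  sex = c("SEX", "GNDR_COD"),
  age_value = "AGE",
  age_unit = "AGE_COD",
  reporter_occupation = "OCCP_COD",
  reporter_country = "REPORTER_COUNTRY",
  occr_country = "OCCR_COUNTRY"
)
.drug_aliases <- list(
  primaryid = c("PRIMARYID", "ISR"),
  caseid = c("CASEID", "CASE"),
  drug_seq = c("DRUG_SEQ", "DRUGSEQ"),
  role = "ROLE_COD",
  drugname = "DRUGNAME",
  active_ingredient = "PROD_AI"
)
.reac_aliases <- list(
  primaryid = c("PRIMARYID", "ISR"),
  caseid = c("CASEID", "CASE"),
  pt = "PT"
)
.outc_aliases <- list(
  primaryid = c("PRIMARYID", "ISR"),
  caseid = c("CASEID", "CASE"),
  outcome_code = c("OUTC_COD", "OUTC_CODE")
)
.ther_aliases <- list(
  primaryid = c("PRIMARYID", "ISR"),
  caseid = c("CASEID", "CASE"),
  dsg_drug_seq = c("DSG_DRUG_SEQ", "DRUG_SEQ"),
  start_dt = "START_DT"
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.age_units <- c("YR", "DEC", "MON", "WK", "DY", "HR")
.occupation_codes <- c("CN", "MD", "PH", "OT", "LW", "HP")

# read one $-delimited table, resolve header aliases, return DT of character
# columns named canonically (missing columns become NA)
read_faers_table <- function(path, aliases, what) {
  if (!file.exists(path)) {
    stop("FAERS ", what, " file not found: ", path, call. = FALSE)
  }
  dt <- fread(path, sep = "$", header = TRUE, quote = "",
              colClasses = "character", fill = TRUE,
              blank.lines.skip = TRUE, strip.white = TRUE,
              keepLeadingZeros = TRUE, na.strings = NULL)
  setnames(dt, toupper(trimws(names(dt))))
  if (!any(.demo_aliases$primaryid %in% names(dt))) {
    stop("unrecognized dialect in ", path,
         ": header has neither PRIMARYID nor ISR", call. = FALSE)
  }
  out <- data.table(.rows = seq_len(nrow(dt)))
  for (canon in names(aliases)) {
    hit <- intersect(aliases[[canon]], names(dt))
    if (length(hit)) {
      set(out, j = canon, value = dt[[hit[1]]])
    } else {
      set(out, j = canon, value = rep(NA_character_, nrow(dt)))
    }
  }
  out[, .rows := NULL]
  out
}

# drop rows with a blank/invalid report key; returns list(dt, skipped)
.drop_malformed <- function(dt, what) {
  bad <- is.na(dt$primaryid) | !grepl("^[0-9]+$", trimws(dt$primaryid))
  if (any(bad)) {
    message("faersignal: skipped ", sum(bad), " malformed ", what,
            " row(s) (missing/non-numeric report key)")
  }
  list(dt = dt[!bad], skipped = sum(bad))
}

.norm_code <- function(x, valid, unknown = NA_character_) {
  x <- toupper(trimws(x))
  x[is.na(x) | x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %chin% valid)
  x[bad] <- unknown
  list(x = x, coerced = sum(bad))
}

#' Parse one FAERS quarter into a typed bundle
#'
#' Reads the five `$`-delimited ASCII tables of a FAERS quarterly package
#' and returns normalized, typed records. Both the modern
#' (`PRIMARYID`/`CASEID`) and the legacy (`ISR`/`CASE`) header dialects are
#' accepted; legacy keys are mapped onto the modern names. Dates are
#' normalized to integer `YYYYMMDD` with 0 for blank or garbled values
#' (partial dates padded, see [faers_date_normalize()]); sex, drug role,
#' and outcome codes are upper-cased and checked against the FAERS code
#' lists. Drug/reaction/outcome/therapy rows whose report key does not
#' appear in DEMO ("orphans") are counted and dropped.
#'
#' @param demo_path,drug_path,reac_path,outc_path,ther_path paths to the
#'   quarter's DEMO, DRUG, REAC, OUTC, and THER files
#' @param quarter_label label such as `"2013Q2"`, kept for logging
#' @return a `faers_bundle`: a list with data.tables `demo`, `drugs`,
#'   `reactions`, `outcomes`, `therapies`, the `quarter_label`, and a `log`
#'   list of row-accounting counters (rows in, records out, skipped,
#'   orphans, coerced codes per table)
#' @export
parse_quarter <- function(demo_path, drug_path, reac_path, outc_path,
                          ther_path, quarter_label = "") {
  log <- list()

  raw <- read_faers_table(demo_path, .demo_aliases, "DEMO")
  log$demo_rows_in <- nrow(raw)
  m <- .drop_malformed(raw, "DEMO"); demo <- m$dt
  log$demo_skipped <- m$skipped
  sex <- .norm_code(demo$sex, c("F", "M"), unknown = "UNK")
  occ <- .norm_code(demo$reporter_occupation, .occupation_codes)
  age <- suppressWarnings(as.numeric(demo$age_value))
  age[!is.na(age) & age < 0] <- NA_real_
  country <- toupper(trimws(demo$reporter_country))
  occr <- toupper(trimws(demo$occr_country))
  country[is.na(country) | country == ""] <-
    occr[is.na(country) | country == ""]
  country[is.na(country) | country == ""] <- NA_character_
  fda_dt <- faers_date_normalize(demo$fda_dt)
  demo <- data.table(
    primaryid = trimws(demo$primaryid),
    caseid = trimws(demo$caseid),
    fda_dt = fda_dt,
    event_dt = faers_date_normalize(demo$event_dt),
    event_dt_precision = faers_date_precision(demo$event_dt),
    sex = { x <- sex$x; x[is.na(x)] <- "UNK"; x },
    age_value = age,
    age_unit = .norm_code(demo$age_unit, .age_units)$x,
    reporter_occupation = occ$x,
    reporter_country = country,
    report_year = fda_dt %/% 10000L
  )
  demo[is.na(caseid) | caseid == "", caseid := primaryid]
  log$demo_codes_coerced <- sex$coerced + occ$coerced
  log$demo_records <- nrow(demo)

  raw <- read_faers_table(drug_path, .drug_aliases, "DRUG")
  log$drug_rows_in <- nrow(raw)
  m <- .drop_malformed(raw, "DRUG"); drugs <- m$dt
  role <- .norm_code(drugs$role, .role_codes)
  bad_role <- is.na(role$x)
  if (any(bad_role)) {
    message("faersignal: skipped ", sum(bad_role),
            " DRUG row(s) with missing/unknown role code")
  }
  drugs <- data.table(
    primaryid = trimws(drugs$primaryid),
    drug_seq = suppressWarnings(as.integer(drugs$drug_seq)),
    role = role$x,
    drugname = toupper(trimws(drugs$drugname)),
    active_ingredient = toupper(trimws(drugs$active_ingredient))
  )[!bad_role]
  log$drug_skipped <- m$skipped + sum(bad_role)

  raw <- read_faers_table(reac_path, .reac_aliases, "REAC")
  log$reac_rows_in <- nrow(raw)
  m <- .drop_malformed(raw, "REAC"); reac <- m$dt
  pt <- toupper(gsub("[[:space:]]+", " ", trimws(reac$pt)))
  blank_pt <- is.na(pt) | pt == ""
  if (any(blank_pt)) {
    message("faersignal: skipped ", sum(blank_pt), " REAC row(s) with blank PT")
  }
  reactions <- data.table(primaryid = trimws(reac$primaryid),
                          pt = pt)[!blank_pt]
  log$reac_skipped <- m$skipped + sum(blank_pt)

  raw <- read_faers_table(outc_path, .outc_aliases, "OUTC")
  log$outc_rows_in <- nrow(raw)
  m <- .drop_malformed(raw, "OUTC"); outc <- m$dt
  oc <- .norm_code(outc$outcome_code, .outcome_codes)
  bad_oc <- is.na(oc$x)
  if (any(bad_oc)) {
    message("faersignal: skipped ", sum(bad_oc),
            " OUTC row(s) with missing/unknown outcome code")
  }
  outcomes <- data.table(primaryid = trimws(outc$primaryid),
                         outcome_code = oc$x)[!bad_oc]
  log$outc_skipped <- m$skipped + sum(bad_oc)

  raw <- read_faers_table(ther_path, .ther_aliases, "THER")
  log$ther_rows_in <- nrow(raw)
  m <- .drop_malformed(raw, "THER"); ther <- m$dt
  therapies <- data.table(
    primaryid = trimws(ther$primaryid),
    dsg_drug_seq = suppressWarnings(as.integer(ther$dsg_drug_seq)),
    start_dt = faers_date_normalize(ther$start_dt)
  )
  log$ther_skipped <- m$skipped

  # orphan mentions: counted, logged, dropped
  keys <- demo$primaryid
  for (nm in c("drugs", "reactions", "outcomes", "therapies")) {
    tab <- get(nm)
    orphan <- !(tab$primaryid %chin% keys)
    log[[paste0(nm, "_orphans")]] <- sum(orphan)
    if (any(orphan)) {
      message("faersignal: dropped ", sum(orphan), " orphan ", nm,
              " mention(s) with no DEMO record")
      assign(nm, tab[!orphan])
    }
  }

  structure(
    list(demo = demo, drugs = drugs, reactions = reactions,
         outcomes = outcomes, therapies = therapies,
         quarter_label = quarter_label, log = log),
    class = "faers_bundle"
  )
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle ", if (nzchar(x$quarter_label)) x$quarter_label else "?",
      ">: ", nrow(x$demo), " reports, ", nrow(x$drugs), " drug mentions, ",
      nrow(x$reactions), " reactions, ", nrow(x$outcomes), " outcomes, ",
      nrow(x$therapies), " therapy records\n", sep = "")
  invisible(x)
}

#' Combine several quarter bundles into one
#'
#' @param bundles list of `faers_bundle` objects
#' @param quarter_label label for the combined bundle
#' @return a single `faers_bundle` with row-bound record tables
#' @export
bind_bundles <- function(bundles, quarter_label = "combined") {
  stopifnot(length(bundles) >= 1L,
            all(vapply(bundles, inherits, TRUE, "faers_bundle")))
  pick <- function(nm) rbindlist(lapply(bundles, `[[`, nm))
  structure(
    list(demo = pick("demo"), drugs = pick("drugs"),
         reactions = pick("reactions"), outcomes = pick("outcomes"),
         therapies = pick("therapies"), quarter_label = quarter_label,
         log = list(quarters = vapply(bundles, `[[`, "", "quarter_label"))),
    class = "faers_bundle"
  )
}

#' Write a bundle back to the FAERS ASCII dialect
#'
#' Inverse of [parse_quarter()]; used by the synthetic generator and by
#' round-trip tests. Dates equal to 0 are written as blanks, mirroring the
#' source files.
#'
#' @param bundle a `faers_bundle`
#' @param dir output directory (created if needed)
#' @param dialect `"modern"` writes PRIMARYID/CASEID headers, `"legacy"`
#'   writes ISR/CASE
#' @return named character vector of the five file paths, invisibly
#' @export
write_quarter <- function(bundle, dir, dialect = c("modern", "legacy")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key_cols <- if (dialect == "modern") c("PRIMARYID", "CASEID") else
    c("ISR", "CASE")
  blank0 <- function(x) fifelse(x == 0L, "", as.character(x))

  demo <- bundle$demo
  ddt <- data.table(
    K1 = demo$primaryid, K2 = demo$caseid,
    FDA_DT = blank0(demo$fda_dt),
    EVENT_DT = fifelse(
      demo$event_dt == 0L, "",
      fifelse(demo$event_dt_precision == "year",
              substr(as.character(demo$event_dt), 1, 4),
              fifelse(demo$event_dt_precision == "month",
                      substr(as.character(demo$event_dt), 1, 6),
                      as.character(demo$event_dt)))),
    SEX = fifelse(demo$sex == "UNK", "", demo$sex),
    AGE = fifelse(is.na(demo$age_value), "", as.character(demo$age_value)),
    AGE_COD = fifelse(is.na(demo$age_unit), "", demo$age_unit),
    OCCP_COD = fifelse(is.na(demo$reporter_occupation), "",
                       demo$reporter_occupation),
    REPORTER_COUNTRY = fifelse(is.na(demo$reporter_country), "",
                               demo$reporter_country)
  )
  setnames(ddt, c("K1", "K2"), key_cols)

  drg <- data.table(K1 = bundle$drugs$primaryid,
                    DRUG_SEQ = bundle$drugs$drug_seq,
                    ROLE_COD = bundle$drugs$role,
                    DRUGNAME = bundle$drugs$drugname,
                    PROD_AI = fifelse(is.na(bundle$drugs$active_ingredient),
                                      "", bundle$drugs$active_ingredient))
  setnames(drg, "K1", key_cols[1])
  rea <- data.table(K1 = bundle$reactions$primaryid, PT = bundle$reactions$pt)
  setnames(rea, "K1", key_cols[1])
  out <- data.table(K1 = bundle$outcomes$primaryid,
                    OUTC_COD = bundle$outcomes$outcome_code)
  setnames(out, "K1", key_cols[1])
  the <- data.table(K1 = bundle$therapies$primaryid,
                    DSG_DRUG_SEQ = bundle$therapies$dsg_drug_seq,
                    START_DT = blank0(bundle$therapies$start_dt))
  setnames(the, "K1", key_cols[1])

  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"),
             outc = file.path(dir, "OUTC.txt"),
             ther = file.path(dir, "THER.txt"))
  fwrite(ddt, paths["demo"], sep = "$", quote = FALSE, eol = "\n")
  fwrite(drg, paths["drug"], sep = "$", quote = FALSE, eol = "\n")
  fwrite(rea, paths["reac"], sep = "$", quote = FALSE, eol = "\n")
  fwrite(out, paths["outc"], sep = "$", quote = FALSE, eol = "\n")
  fwrite(the, paths["ther"], sep = "$", quote = FALSE, eol = "\n")
  invisible(paths)
}

#' Read a deleted-case list
#'
#' Quarterly packages since 2019Q1 include a list of case identifiers whose
#' reports were deleted; these cases are removed after deduplication. The
#' file holds one CASEID per line; a non-numeric first line is treated as a
#' header and skipped.
#'
#' @param path path to the list file
#' @return character vector of distinct case ids (possibly empty)
#' @export
parse_deleted_list <- function(path) {
  if (!file.exists(path)) {
    stop("deleted-case list not found: ", path, call. = FALSE)
  }
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (length(x) && !grepl("^[0-9]+$", x[1])) x <- x[-1]
  unique(x)
}

#' Load a PT to primary-SOC mapping table
#'
#' MedDRA itself is licensed and cannot ship with the package; the caller
#' supplies a CSV with columns `pt`, `soc_name`, `soc_code` giving each
#' Preferred Term's primary System Organ Class. Lookups are case-insensitive;
#' a PT mapped to two different SOCs is a fatal error.
#'
#' @param path path to the CSV
#' @return a `vocabulary_map` object; query it with [map_pt_to_soc()]
#' @export
load_pt_soc_map <- function(path) {
  if (!file.exists(path)) stop("PT/SOC map not found: ", path, call. = FALSE)
  dt <- fread(path, colClasses = list(character = c("pt", "soc_name")))
  need <- c("pt", "soc_name", "soc_code")
  if (!all(need %in% names(dt))) {
    stop("PT/SOC map must have columns pt, soc_name, soc_code", call. = FALSE)
  }
  dt <- dt[, .(pt = toupper(gsub("[[:space:]]+", " ", trimws(pt))),
               soc_name = trimws(soc_name),
               soc_code = as.integer(soc_code))]
  dt <- unique(dt)
  dup <- dt[, .N, by = pt][N > 1L, pt]
  if (length(dup)) {
    stop("conflicting SOC assignments for PT(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(table = dt), class = "vocabulary_map")
}

#' Map Preferred Terms to their primary SOC
#'
#' @param vocab a `vocabulary_map` from [load_pt_soc_map()]
#' @param pts character vector of PT strings (any case)
#' @return data.table with columns `pt`, `soc_name`, `soc_code`; unmapped
#'   PTs get `NA` in both SOC columns
#' @export
map_pt_to_soc <- function(vocab, pts) {
  stopifnot(inherits(vocab, "vocabulary_map"))
  q <- data.table(pt = toupper(gsub("[[:space:]]+", " ", trimws(pts))))
  vocab$table[q, on = "pt"]
}

#' @export
print.vocabulary_map <- function(x, ...) {
  cat("<vocabulary_map>: ", nrow(x$table), " PTs across ",
      length(unique(x$table$soc_name)), " SOCs\n", sep = "")
  invisible(x)
}
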