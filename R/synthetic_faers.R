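# Synthetic FAERS quarters with known signal structure.
#
# The generative model is deliberately simple and fully stated:
#   * each report includes each configured drug independently with its
#     marginal probability (so drug-event pair algebra is exact);
#   * given the report's drug set, each PT is an independent Bernoulli with
#     probability baseline * lambda, where lambda is the largest reporting
#     rate ratio among the report's drugs holding a signal pair for that PT
#     (1 when none); lambda * baseline must not exceed 1;
#   * demographics are drawn from configurable marginals whose defaults are
#     the published vilazodone cohort profile;
#   * a fraction of cases get an extra report version with a strictly later
#     FDA date (so the deduplication rule has a unique right answer), and a
#     fraction of case ids go on the deleted list.
# Files are written in the exact dialect parse_quarter() consumes.

.default_drugs <- function() {
  data.table(
    name = c("VILAZODONE HYDROCHLORIDE", "SERTRALINE", "FLUOXETINE",
             "ESCITALOPRAM", "DULOXETINE", "BUPROPION", "QUETIAPINE",
             "IBUPROFEN", "METFORMIN", "LISINOPRIL", "ATORVASTATIN",
             "OMEPRAZOLE", "ASPIRIN"),
    marginal = c(0.010, 0.050, 0.045, 0.040, 0.035, 0.030, 0.025,
                 0.080, 0.070, 0.060, 0.065, 0.055, 0.075),
    synonyms = c("VIIBRYD;VILAZODONE", "ZOLOFT", "PROZAC", "LEXAPRO",
                 "CYMBALTA", "WELLBUTRIN", "SEROQUEL", "ADVIL", "",
                 "", "LIPITOR", "PRILOSEC", "")
  )
}

.default_pts <- function() {
  data.table(
    pt = c("NAUSEA", "DIARRHOEA", "VOMITING", "HEADACHE", "DIZZINESS",
           "SOMNOLENCE", "TREMOR", "INSOMNIA", "ANXIETY", "DEPRESSION",
           "AGITATION", "HALLUCINATION", "SUICIDAL IDEATION",
           "ABNORMAL DREAMS", "NIGHTMARE", "SLEEP PARALYSIS", "FATIGUE",
           "FEELING ABNORMAL", "CRYING", "RASH", "HYPERHIDROSIS",
           "PALPITATIONS", "WEIGHT INCREASED", "VISION BLURRED",
           "SEXUAL DYSFUNCTION"),
    soc_name = c("Gastrointestinal disorders", "Gastrointestinal disorders",
                 "Gastrointestinal disorders", "Nervous system disorders",
                 "Nervous system disorders", "Nervous system disorders",
                 "Nervous system disorders", "Psychiatric disorders",
                 "Psychiatric disorders", "Psychiatric disorders",
                 "Psychiatric disorders", "Psychiatric disorders",
                 "Psychiatric disorders", "Psychiatric disorders",
                 "Psychiatric disorders", "Nervous system disorders",
                 "General disorders and administration site conditions",
                 "General disorders and administration site conditions",
                 "General disorders and administration site conditions",
                 "Skin and subcutaneous tissue disorders",
                 "Skin and subcutaneous tissue disorders",
                 "Cardiac disorders", "Investigations", "Eye disorders",
                 "Reproductive system and breast disorders"),
    soc_code = c(10017947L, 10017947L, 10017947L, 10029205L, 10029205L,
                 10029205L, 10029205L, 10037175L, 10037175L, 10037175L,
                 10037175L, 10037175L, 10037175L, 10037175L, 10037175L,
                 10029205L, 10018065L, 10018065L, 10018065L, 10040785L,
                 10040785L, 10007541L, 10022891L, 10015919L, 10038604L),
    baseline = c(0.050, 0.040, 0.030, 0.060, 0.035, 0.020, 0.015, 0.030,
                 0.025, 0.020, 0.010, 0.005, 0.008, 0.003, 0.004, 0.0008,
                 0.050, 0.010, 0.004, 0.030, 0.010, 0.015, 0.020, 0.010,
                 0.002)
  )
}

.default_demographics <- function() {
  list(
    sex = c(F = 0.6540, M = 0.2765, UNK = 0.0696),
    age = c("<18" = 0.0571, "18-45" = 0.1749, "45-65" = 0.1981,
            "65-75" = 0.0610, ">=75" = 0.0303, Unknown = 0.4785),
    reporter = c(CN = 0.5978, PH = 0.0458, MD = 0.2255, OT = 0.0871,
                 LW = 0.0002, Unknown = 0.0437),
    country = c(US = 0.9836, "Not Specified" = 0.0121, CA = 0.0020,
                IN = 0.0017, DE = 0.0002),
    year = c("2011" = 0.0811, "2012" = 0.1120, "2013" = 0.2817,
             "2014" = 0.0586, "2015" = 0.0106, "2016" = 0.0540,
             "2017" = 0.0638, "2018" = 0.0381, "2019" = 0.0707,
             "2020" = 0.0860, "2021" = 0.0625, "2022" = 0.0476,
             "2023" = 0.0333),
    outcome = c(DE = 0.0149, DS = 0.0106, HO = 0.0554, LT = 0.0087,
                CA = 0, RI = 0, OT = 0)
  )
}

#' Configure the synthetic FAERS generator
#'
#' Defaults emulate the reproduced vilazodone study's world: a target
#' antidepressant with a 1% reporting share plus a dozen background drugs,
#' 25 PTs across 9 SOCs with realistic baseline reporting probabilities,
#' four elevated target-drug signal pairs, 10% duplicate case versions, 2%
#' deleted cases, and demographic marginals equal to the published cohort
#' profile (65.4% female, 47.85% missing age, 59.78% consumer reports,
#' 98.4% US, reporting years 2011-2023). See the methods vignette for the
#' reasoning behind each default.
#'
#' @param n_reports number of distinct cases to simulate
#' @param drugs data.frame with columns `name`, `marginal` (per-report
#'   inclusion probability in (0,1)), `synonyms` (`;`-separated brand
#'   names, possibly empty)
#' @param pts data.frame with columns `pt`, `soc_name`, `soc_code`,
#'   `baseline` (per-report reporting probability in (0,1))
#' @param signal_pairs data.frame with columns `drug`, `pt`, `lambda`
#'   (reporting rate ratio >= 1); `lambda * baseline` must stay <= 1
#' @param duplicate_fraction fraction of cases receiving an extra report
#'   version (in `[0, 1)`)
#' @param deleted_fraction fraction of case ids put on the deleted list
#' @param demographics list of named probability vectors `sex`, `age`,
#'   `reporter`, `country`, `year`, `outcome` (defaults: published profile)
#' @param event_dt_missing fraction of reports with no event date
#' @param therapy_start_missing fraction of therapy records with no start
#'   date
#' @param onset_mean_days mean of the geometric onset-day distribution
#' @param seed integer seed; identical configs generate byte-identical files
#' @return a validated `synth_config` list
#' @export
synth_config <- function(n_reports = 10000L,
                         drugs = .default_drugs(),
                         pts = .default_pts(),
                         signal_pairs = data.table(
                           drug = rep("VILAZODONE HYDROCHLORIDE", 4L),
                           pt = c("INSOMNIA", "ABNORMAL DREAMS",
                                  "SUICIDAL IDEATION", "SLEEP PARALYSIS"),
                           lambda = c(8, 25, 12, 50)),
                         duplicate_fraction = 0.10,
                         deleted_fraction = 0.02,
                         demographics = .default_demographics(),
                         event_dt_missing = 0.20,
                         therapy_start_missing = 0.55,
                         onset_mean_days = 25,
                         seed = 1L) {
  drugs <- as.data.table(drugs)
  pts <- as.data.table(pts)
  signal_pairs <- as.data.table(signal_pairs)
  drugs[, name := toupper(name)]
  pts[, pt := toupper(pt)]
  if (nrow(signal_pairs)) {
    signal_pairs[, `:=`(drug = toupper(drug), pt = toupper(pt))]
  }
  stopifnot(n_reports >= 1L,
            all(drugs$marginal > 0 & drugs$marginal < 1),
            all(pts$baseline > 0 & pts$baseline < 1),
            !anyDuplicated(drugs$name), !anyDuplicated(pts$pt),
            duplicate_fraction >= 0, duplicate_fraction < 1,
            deleted_fraction >= 0, deleted_fraction < 1)
  if (nrow(signal_pairs)) {
    if (any(signal_pairs$lambda < 1)) {
      stop("signal-pair lambda must be >= 1", call. = FALSE)
    }
    if (!all(signal_pairs$drug %in% drugs$name) ||
        !all(signal_pairs$pt %in% pts$pt)) {
      stop("signal pairs must reference configured drugs and PTs",
           call. = FALSE)
    }
    base <- pts$baseline[match(signal_pairs$pt, pts$pt)]
    over <- signal_pairs$lambda * base > 1
    if (any(over)) {
      stop("lambda too large for baseline: ",
           paste(signal_pairs$pt[over], collapse = ", "), call. = FALSE)
    }
  }
  for (nm in names(.default_demographics())) {
    p <- demographics[[nm]]
    if (nm != "outcome" && (is.null(p) || any(p < 0) || sum(p) <= 0)) {
      stop("demographics$", nm, " must be a non-negative probability vector",
           call. = FALSE)
    }
  }
  structure(list(n_reports = as.integer(n_reports), drugs = drugs, pts = pts,
                 signal_pairs = signal_pairs,
                 duplicate_fraction = duplicate_fraction,
                 deleted_fraction = deleted_fraction,
                 demographics = demographics,
                 event_dt_missing = event_dt_missing,
                 therapy_start_missing = therapy_start_missing,
                 onset_mean_days = onset_mean_days,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# per-report lambda multiplier for one pt, given the 0/1 drug presence matrix
.pt_lambda <- function(config, present, pt_name) {
  lam <- rep(1, nrow(present))
  sp <- config$signal_pairs
  if (nrow(sp)) {
    for (k in which(sp$pt == pt_name)) {
      j <- match(sp$drug[k], config$drugs$name)
      lam <- pmax(lam, ifelse(present[, j] == 1L, sp$lambda[k], 1))
    }
  }
  lam
}

.sample_marginal <- function(p, n) {
  sample(names(p), n, replace = TRUE, prob = p / sum(p))
}

#' Generate a synthetic FAERS quarter
#'
#' Draws reports from the generative model in `config`, injects duplicate
#' case versions and a deleted-case list, and writes the `$`-delimited
#' DEMO/DRUG/REAC/OUTC/THER files plus `DELETED.txt`, a `pt_soc_map.csv`
#' vocabulary derived from the config, and `truth.json` recording the
#' design (signal pairs, duplicated and deleted case ids). Deterministic:
#' the same config (including its seed) yields byte-identical files.
#'
#' @param config a [synth_config()]
#' @param dir output directory (created if needed)
#' @param dialect FAERS header dialect to write (see [write_quarter()])
#' @return invisibly, `list(files, truth)`; `files` includes the five
#'   quarterly tables, the deleted list, and the vocabulary
#' @export
synth_generate <- function(config, dir, dialect = "modern") {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_reports
  dem <- config$demographics

  caseid <- as.character(1000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  year <- as.integer(.sample_marginal(dem$year, n))
  fda_date <- as.Date(sprintf("%d-%02d-%02d", year,
                              sample(1:12, n, TRUE), sample(1:28, n, TRUE)))
  event_date <- fda_date - sample(0:60, n, TRUE)
  event_missing <- runif(n) < config$event_dt_missing
  event_dt <- as.integer(format(event_date, "%Y%m%d"))
  event_dt[event_missing] <- 0L

  sex <- .sample_marginal(dem$sex, n)
  age_bin <- .sample_marginal(dem$age, n)
  age_lo <- c("<18" = 1, "18-45" = 18, "45-65" = 45, "65-75" = 65,
              ">=75" = 75)[age_bin]
  age_hi <- c("<18" = 17, "18-45" = 44, "45-65" = 64, "65-75" = 74,
              ">=75" = 95)[age_bin]
  age_value <- rep(NA_real_, n)
  known <- !is.na(age_lo)
  age_value[known] <- floor(runif(sum(known), age_lo[known],
                                  age_hi[known] + 1))
  reporter <- .sample_marginal(dem$reporter, n)
  reporter[reporter == "Unknown"] <- NA_character_
  country <- .sample_marginal(dem$country, n)
  country[country == "Not Specified"] <- NA_character_

  demo <- data.table(
    primaryid = primaryid, caseid = caseid,
    fda_dt = as.integer(format(fda_date, "%Y%m%d")),
    event_dt = event_dt,
    event_dt_precision = ifelse(event_dt == 0L, "none", "day"),
    sex = sex, age_value = age_value,
    age_unit = ifelse(is.na(age_value), NA_character_, "YR"),
    reporter_occupation = reporter, reporter_country = country,
    report_year = year
  )

  # drug presence: independent Bernoulli per (report, drug)
  nd <- nrow(config$drugs)
  present <- matrix(0L, n, nd)
  for (j in seq_len(nd)) {
    present[, j] <- rbinom(n, 1L, config$drugs$marginal[j])
  }
  mention_idx <- which(present == 1L, arr.ind = TRUE)
  mentions <- data.table(report = mention_idx[, 1], drug = mention_idx[, 2],
                         prio = runif(nrow(mention_idx)))
  setorderv(mentions, c("report", "prio"))
  mentions[, drug_seq := seq_len(.N), by = report]
  mentions[, role := fifelse(drug_seq == 1L, "PS",
                             sample(c("SS", "C"), .N, TRUE,
                                    prob = c(0.6, 0.4)))]
  dn_pool <- mapply(function(nm, sy) c(nm, Filter(nzchar, strsplit(
    sy, ";", fixed = TRUE)[[1]])), config$drugs$name, config$drugs$synonyms,
    SIMPLIFY = FALSE)
  mentions[, drugname := vapply(drug, function(j) {
    opts <- dn_pool[[j]]
    opts[sample.int(length(opts), 1L)]
  }, "")]
  drugs <- data.table(primaryid = primaryid[mentions$report],
                      drug_seq = mentions$drug_seq,
                      role = mentions$role,
                      drugname = mentions$drugname,
                      active_ingredient = config$drugs$name[mentions$drug])

  # reactions: independent Bernoulli per (report, pt), lambda-scaled
  reac_list <- vector("list", nrow(config$pts))
  for (j in seq_len(nrow(config$pts))) {
    p <- pmin(1, config$pts$baseline[j] *
                .pt_lambda(config, present, config$pts$pt[j]))
    hit <- which(rbinom(n, 1L, p) == 1L)
    if (length(hit)) {
      reac_list[[j]] <- data.table(primaryid = primaryid[hit],
                                   pt = config$pts$pt[j])
    }
  }
  reactions <- rbindlist(reac_list)
  if (is.null(reactions) || !nrow(reactions)) {
    reactions <- data.table(primaryid = character(), pt = character())
  }

  # outcomes: independent Bernoulli per code
  outc_list <- list()
  for (code in names(dem$outcome)) {
    p <- dem$outcome[[code]]
    if (p > 0) {
      hit <- which(rbinom(n, 1L, p) == 1L)
      if (length(hit)) {
        outc_list[[code]] <- data.table(primaryid = primaryid[hit],
                                        outcome_code = code)
      }
    }
  }
  outcomes <- if (length(outc_list)) rbindlist(outc_list) else
    data.table(primaryid = character(), outcome_code = character())

  # therapy start dates, linked to drug mentions via drug_seq
  base_date <- fifelse(demo$event_dt[mentions$report] > 0L,
                       event_date[mentions$report],
                       fda_date[mentions$report])
  onset <- rgeom(nrow(mentions), 1 / (config$onset_mean_days + 1))
  start_missing <- runif(nrow(mentions)) < config$therapy_start_missing
  start_dt <- as.integer(format(base_date - onset, "%Y%m%d"))
  start_dt[start_missing] <- 0L
  therapies <- data.table(primaryid = primaryid[mentions$report],
                          dsg_drug_seq = mentions$drug_seq,
                          start_dt = start_dt)

  # duplicate case versions: same case, later FDA date, new primaryid
  n_dup <- floor(config$duplicate_fraction * n)
  dup_case <- character()
  if (n_dup > 0) {
    dup_idx <- sort(sample.int(n, n_dup))
    dup_case <- caseid[dup_idx]
    dup_pid <- paste0(dup_case, "2")
    dup_demo <- copy(demo[dup_idx])
    dup_demo[, `:=`(primaryid = dup_pid,
                    fda_dt = as.integer(format(
                      fda_date[dup_idx] + sample(1:30, n_dup, TRUE),
                      "%Y%m%d")))]
    dup_demo[, report_year := fda_dt %/% 10000L]
    demo <- rbind(demo, dup_demo)
    remap <- function(tab) {
      extra <- tab[primaryid %chin% paste0(dup_case, "1")]
      if (nrow(extra)) {
        extra[, primaryid := paste0(substr(
          primaryid, 1L, nchar(primaryid) - 1L), "2")]
      }
      rbind(tab, extra)
    }
    drugs <- remap(drugs); reactions <- remap(reactions)
    outcomes <- remap(outcomes); therapies <- remap(therapies)
  }

  n_del <- floor(config$deleted_fraction * n)
  del_case <- if (n_del > 0) sort(sample(caseid, n_del)) else character()

  bundle <- structure(
    list(demo = demo, drugs = drugs, reactions = reactions,
         outcomes = outcomes, therapies = therapies,
         quarter_label = "synthetic", log = list()),
    class = "faers_bundle")
  files <- write_quarter(bundle, dir, dialect = dialect)
  del_path <- file.path(dir, "DELETED.txt")
  writeLines(c("CASEID", del_case), del_path)
  vocab_path <- file.path(dir, "pt_soc_map.csv")
  fwrite(config$pts[, .(pt, soc_name, soc_code)], vocab_path)
  truth <- list(n_reports = n,
                signal_pairs = as.data.frame(config$signal_pairs),
                duplicated_caseids = dup_case,
                deleted_caseids = del_case,
                seed = config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(files = c(files, deleted = del_path, vocab = vocab_path),
                 truth = truth))
}

# P(pt_j drawn) under the model, optionally conditioning on one drug's
# presence; exact under drug independence (enumerates the pt's signal drugs)
.pt_prob <- function(config, j, cond_drug = NA_integer_,
                     cond_present = NA) {
  base <- config$pts$baseline[j]
  sp <- config$signal_pairs
  ks <- if (nrow(sp)) which(sp$pt == config$pts$pt[j]) else integer()
  if (!length(ks)) return(base)
  dj <- match(sp$drug[ks], config$drugs$name)
  lam <- sp$lambda[ks]
  pd <- config$drugs$marginal[dj]
  total <- 0
  for (mask in 0:(2^length(ks) - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_along(ks) - 1L)))
    prob <- 1
    skip <- FALSE
    for (i in seq_along(ks)) {
      if (!is.na(cond_drug) && dj[i] == cond_drug) {
        if (inset[i] != cond_present) { skip <- TRUE; break }
      } else {
        prob <- prob * if (inset[i]) pd[i] else 1 - pd[i]
      }
    }
    if (skip) next
    lmax <- if (any(inset)) max(lam[inset]) else 1
    total <- total + prob * min(1, base * lmax)
  }
  total
}

#' Model-implied EBGM for a drug-event pair
#'
#' Closed-form expectation of the observed/expected reporting ratio under
#' the generative model, computed from the configured marginals (ratio of
#' expected cells; exact under drug independence). For a signal pair with
#' rate ratio `lambda` this approaches `lambda` as the drug marginal and
#' the pair's share of all pairs shrink; for a null pair of a drug with no
#' signal pairs it is exactly 1. Used as the reference value in
#' parameter-recovery tests.
#'
#' @param config a [synth_config()]
#' @param drug drug name (as configured)
#' @param pt PT name (as configured)
#' @return the model-implied EBGM (a real)
#' @export
expected_ebgm <- function(config, drug, pt) {
  stopifnot(inherits(config, "synth_config"))
  drug <- toupper(drug); pt <- toupper(pt)
  dj <- match(drug, config$drugs$name)
  j <- match(pt, config$pts$pt)
  if (is.na(dj) || is.na(j)) stop("pair not in vocabulary", call. = FALSE)
  pd <- config$drugs$marginal[dj]
  q1 <- .pt_prob(config, j, dj, TRUE)
  q0 <- .pt_prob(config, j, dj, FALSE)
  qs1 <- vapply(seq_len(nrow(config$pts)),
                function(k) .pt_prob(config, k, dj, TRUE), 0)
  qs0 <- vapply(seq_len(nrow(config$pts)),
                function(k) .pt_prob(config, k, dj, FALSE), 0)
  e_a <- pd * q1
  e_ac <- pd * q1 + (1 - pd) * q0
  e_ab <- pd * sum(qs1)
  e_n <- pd * sum(qs1) + (1 - pd) * sum(qs0)
  e_a * e_n / (e_ac * e_ab)
}
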