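# Fixture builders and the independent statistic oracle used across tests.

# write a $-delimited file from a header and row vectors
write_dollar <- function(path, header, rows = character()) {
  writeLines(c(paste(header, collapse = "$"), rows), path)
  path
}

# a tiny hand-written modern-dialect quarter: 5 reports, 2 on the target
# drug (VILAZODONE), one duplicate case version, known PTs and therapy rows
write_tiny_quarter <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  demo <- write_dollar(
    file.path(dir, "DEMO.txt"),
    c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "SEX", "AGE", "AGE_COD",
      "OCCP_COD", "REPORTER_COUNTRY"),
    c("1001$100$20200115$20200101$F$34$YR$CN$US",
      "2001$200$20200210$$M$204$MON$MD$US",
      "3001$300$20200301$202002$F$68$YR$$CA",
      "4001$400$20200315$20200310$UNKSEX$45$YR$OT$US",
      "4002$400$20200320$20200310$F$45$YR$OT$US",   # later version of case 400
      "5001$500$20200401$20200325$M$$$$US"))
  drug <- write_dollar(
    file.path(dir, "DRUG.txt"),
    c("PRIMARYID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME", "PROD_AI"),
    c("1001$1$PS$VIIBRYD 20MG$VILAZODONE HYDROCHLORIDE",
      "1001$2$C$IBUPROFEN$IBUPROFEN",
      "2001$1$PS$SERTRALINE$SERTRALINE HYDROCHLORIDE",
      "3001$1$SS$VILAZODONE HYDROCHLORIDE$VILAZODONE HYDROCHLORIDE",
      "4002$1$PS$VILAZODONE$VILAZODONE HYDROCHLORIDE",
      "5001$1$PS$METFORMIN$METFORMIN",
      "9999$1$PS$ORPHAN DRUG$ORPHAN"))                # orphan mention
  reac <- write_dollar(
    file.path(dir, "REAC.txt"),
    c("PRIMARYID", "PT"),
    c("1001$Nausea", "1001$Insomnia", "1001$nausea",  # dup PT, case-insensitive
      "2001$Nausea", "3001$Insomnia", "3001$Diarrhoea",
      "4002$Headache", "5001$Diarrhoea"))
  outc <- write_dollar(
    file.path(dir, "OUTC.txt"),
    c("PRIMARYID", "OUTC_COD"),
    c("1001$HO", "3001$DE", "3001$HO", "5001$OT"))
  ther <- write_dollar(
    file.path(dir, "THER.txt"),
    c("PRIMARYID", "DSG_DRUG_SEQ", "START_DT"),
    c("1001$1$20191215", "2001$1$20200101", "3001$1$20200115",
      "4002$1$20200301", "5001$1$"))
  list(demo = demo, drug = drug, reac = reac, outc = outc, ther = ther,
       dir = dir)
}

parse_tiny <- function(dir = tempfile("tinyq")) {
  f <- write_tiny_quarter(dir)
  suppressMessages(
    parse_quarter(f$demo, f$drug, f$reac, f$outc, f$ther, "2020Q1"))
}

# random demo table for dedup property tests: cases with 1..4 versions
random_demo <- function(n_cases, seed) {
  set.seed(seed)
  versions <- sample(1:4, n_cases, replace = TRUE)
  case <- rep(sprintf("%05d", seq_len(n_cases)), versions)
  dt <- data.table::data.table(
    caseid = case,
    primaryid = paste0(case, unlist(lapply(versions, seq_len))),
    fda_dt = 20200000L + sample(101:930, length(case), replace = TRUE)
  )
  dt[sample(nrow(dt))]
}

# ---- independent statistic oracle -----------------------------------------
# Deliberately naive scalar transcriptions of the four formulas, kept apart
# from the package's vectorized implementations; chi-squared goes through
# stats::chisq.test.
oracle_stats <- function(a, b, c, d, alpha = 2, beta = 2, alpha1 = 1,
                         beta1 = 1, gamma11 = 1) {
  N <- a + b + c + d
  ror <- (a / c) / (b / d)
  se_ror <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  m <- matrix(as.numeric(c(a, b, c, d)), 2, 2, byrow = TRUE)
  chi2_plain <- unname(suppressWarnings(
    stats::chisq.test(m, correct = FALSE)$statistic))
  chi2_yates <- unname(suppressWarnings(
    stats::chisq.test(m, correct = TRUE)$statistic))
  gam <- gamma11 * (N + alpha) * (N + beta) /
    ((a + b + alpha1) * (a + c + beta1))
  e_ic <- log((a + gamma11) * (N + alpha) * (N + beta) /
                ((N + gam) * (a + b + alpha1) * (a + c + beta1)), base = 2)
  v_ic <- (1 / (log(2)^2)) *
    ((N - a + gam - gamma11) / ((a + gamma11) * (1 + N + gam)) +
       (N - (a + b) + alpha - alpha1) / ((a + b + alpha1) * (1 + N + alpha)) +
       (N - (a + c) + beta - beta1) / ((a + c + beta1) * (1 + N + beta)))
  ebgm <- a * N / ((a + c) * (a + b))
  list(
    ror = ror, ror_lo = exp(log(ror) - 1.96 * se_ror),
    ror_hi = exp(log(ror) + 1.96 * se_ror),
    prr = prr, prr_lo = exp(log(prr) - 1.96 * se_prr),
    prr_hi = exp(log(prr) + 1.96 * se_prr),
    chi2_plain = chi2_plain, chi2_yates = chi2_yates,
    ic = e_ic, v_ic = v_ic, ic025 = e_ic - 2 * sqrt(v_ic),
    ebgm = ebgm, ebgm_lo = exp(log(ebgm) - 1.96 * se_ror),
    ebgm_hi = exp(log(ebgm) + 1.96 * se_ror)
  )
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

# drug set with a very rare target, for "EBGM ~ lambda" limit checks
.rare_drug_set <- function() {
  data.frame(
    name = c("TARGET", "SERTRALINE", "IBUPROFEN", "METFORMIN"),
    marginal = c(0.001, 0.05, 0.08, 0.07),
    synonyms = c("", "ZOLOFT", "ADVIL", ""))
}
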