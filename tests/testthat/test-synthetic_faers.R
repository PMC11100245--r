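small_cfg <- function(...) {
  synth_config(n_reports = 2000L, seed = 11L, ...)
}

read_synth <- function(dir) {
  suppressMessages(parse_quarter(
    file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
    file.path(dir, "REAC.txt"), file.path(dir, "OUTC.txt"),
    file.path(dir, "THER.txt"), "synth"))
}

test_that("identical config and seed give byte-identical files", {
  d1 <- tempfile(); d2 <- tempfile()
  synth_generate(small_cfg(), d1)
  synth_generate(small_cfg(), d2)
  for (f in c("DEMO.txt", "DRUG.txt", "REAC.txt", "OUTC.txt", "THER.txt",
              "DELETED.txt", "pt_soc_map.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- tempfile()
  synth_generate(synth_config(n_reports = 2000L, seed = 12L), d3)
  expect_false(identical(readLines(file.path(d1, "DEMO.txt")),
                         readLines(file.path(d3, "DEMO.txt"))))
})

test_that("config validation enforces the generative-model constraints", {
  expect_error(synth_config(signal_pairs = data.frame(
    drug = "VILAZODONE HYDROCHLORIDE", pt = "NAUSEA", lambda = 30)),
    "lambda too large")
  expect_error(synth_config(signal_pairs = data.frame(
    drug = "VILAZODONE HYDROCHLORIDE", pt = "NAUSEA", lambda = 0.5)),
    ">= 1")
  expect_error(synth_config(signal_pairs = data.frame(
    drug = "NOT A DRUG", pt = "NAUSEA", lambda = 2)), "must reference")
  expect_error(synth_config(duplicate_fraction = 1), "duplicate_fraction")
})

test_that("duplicates and deletions are emitted and fully reversed by dedup", {
  cfg <- synth_config(n_reports = 1000L, duplicate_fraction = 0.2,
                      deleted_fraction = 0.05, seed = 3L)
  dir <- tempfile()
  out <- synth_generate(cfg, dir)
  b <- read_synth(dir)
  expect_equal(nrow(b$demo), 1200L)  # 1000 cases + 200 duplicate versions
  deleted <- parse_deleted_list(file.path(dir, "DELETED.txt"))
  expect_equal(sort(deleted), sort(out$truth$deleted_caseids))
  b2 <- dedup_bundle(b, deleted)
  expect_equal(nrow(b2$demo), 1000L - length(deleted))
  expect_equal(anyDuplicated(b2$demo$caseid), 0L)
  # the kept version of a duplicated case is the later one (version suffix 2)
  dup <- out$truth$duplicated_caseids
  dup_alive <- setdiff(dup, deleted)
  kept <- b2$demo[b2$demo$caseid %in% dup_alive]
  expect_true(all(substr(kept$primaryid, nchar(kept$primaryid),
                         nchar(kept$primaryid)) == "2"))
})

test_that("a lambda pair's case count lands near its design expectation", {
  cfg <- synth_config(
    n_reports = 50000L,
    signal_pairs = data.frame(drug = "VILAZODONE HYDROCHLORIDE",
                              pt = "NIGHTMARE", lambda = 10),
    duplicate_fraction = 0, deleted_fraction = 0, seed = 21L)
  dir <- tempfile()
  synth_generate(cfg, dir)
  b <- read_synth(dir)
  cohort <- select_target_reports(
    b, drug_query("vilazodone", roles = c("PS", "SS", "C", "I")))
  a_obs <- nrow(b$reactions[b$reactions$primaryid %in% cohort &
                              b$reactions$pt == "NIGHTMARE", ])
  a_exp <- 50000 * 0.01 * 0.004 * 10  # n * p_drug * baseline * lambda = 20
  expect_lt(abs(a_obs - a_exp), 3 * sqrt(a_exp) + 1)
})

test_that("expected_ebgm reflects the model algebra", {
  # null pair of a drug with no signal pairs -> exactly 1
  cfg0 <- small_cfg(signal_pairs = data.frame(drug = character(),
                                              pt = character(),
                                              lambda = numeric()))
  expect_equal(expected_ebgm(cfg0, "SERTRALINE", "NAUSEA"), 1)

  # a rare drug and rare event -> close to lambda: both distortions (the
  # drug's own share of event pairs and the inflated target pair total)
  # scale with p_drug and (lambda - 1) * baseline respectively
  cfg1 <- synth_config(
    n_reports = 1000L, drugs = .rare_drug_set(),
    signal_pairs = data.frame(drug = "TARGET", pt = "SLEEP PARALYSIS",
                              lambda = 5),
    seed = 1L)
  expect_rel(expected_ebgm(cfg1, "TARGET", "SLEEP PARALYSIS"), 5, 0.02)

  # with the default config the elevated pair total (a+b) depresses the
  # ratio below lambda; the exact value is what the pipeline should hit
  e <- expected_ebgm(synth_config(), "VILAZODONE HYDROCHLORIDE", "INSOMNIA")
  expect_gt(e, 1); expect_lt(e, 8)

  expect_error(expected_ebgm(small_cfg(), "NOPE", "NAUSEA"), "vocabulary")
})

test_that("null configuration centres empirical EBGM at 1", {
  cfg <- synth_config(
    n_reports = 20000L,
    signal_pairs = data.frame(drug = character(), pt = character(),
                              lambda = numeric()),
    duplicate_fraction = 0, deleted_fraction = 0, seed = 9L)
  dir <- tempfile()
  synth_generate(cfg, dir)
  b <- read_synth(dir)
  cohort <- select_target_reports(
    b, drug_query("SERTRALINE", roles = c("PS", "SS", "C", "I")))
  u <- build_pairs(b, cohort, level = "pt")
  est <- signal_estimates(all_tables(u, min_a = 5L))
  med <- stats::median(est$ebgm, na.rm = TRUE)
  expect_gt(med, 0.8); expect_lt(med, 1.25)
})
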