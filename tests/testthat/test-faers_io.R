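test_that("parse_quarter types and normalizes a hand-written quarter", {
  b <- parse_tiny()

  # 6 demo rows in, all keyed; orphan drug mention dropped
  expect_equal(nrow(b$demo), 6L)
  expect_equal(b$log$demo_rows_in, 6L)
  expect_equal(b$log$drugs_orphans, 1L)
  expect_false("9999" %in% b$drugs$primaryid)

  d <- b$demo[b$demo$primaryid == "2001"]
  expect_equal(d$event_dt, 0L)              # blank date -> 0
  expect_equal(d$age_value, 204)
  expect_equal(d$age_unit, "MON")
  expect_equal(d$report_year, 2020L)

  # partial date padded, precision recorded
  d3 <- b$demo[b$demo$primaryid == "3001"]
  expect_equal(d3$event_dt, 20200201L)
  expect_equal(d3$event_dt_precision, "month")

  # unknown sex code coerced to UNK
  expect_equal(b$demo[b$demo$primaryid == "4001"]$sex, "UNK")

  # PTs case-normalized; codes uppercased
  expect_true(all(b$reactions$pt == toupper(b$reactions$pt)))
  expect_setequal(unique(b$drugs$role), c("PS", "C", "SS"))
})

test_that("header-only files give empty record sets", {
  dir <- tempfile(); dir.create(dir)
  f <- list(
    demo = write_dollar(file.path(dir, "d.txt"),
                        c("PRIMARYID", "CASEID", "FDA_DT")),
    drug = write_dollar(file.path(dir, "g.txt"),
                        c("PRIMARYID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME")),
    reac = write_dollar(file.path(dir, "r.txt"), c("PRIMARYID", "PT")),
    outc = write_dollar(file.path(dir, "o.txt"), c("PRIMARYID", "OUTC_COD")),
    ther = write_dollar(file.path(dir, "t.txt"),
                        c("PRIMARYID", "DSG_DRUG_SEQ", "START_DT")))
  b <- parse_quarter(f$demo, f$drug, f$reac, f$outc, f$ther, "empty")
  expect_equal(nrow(b$demo), 0L)
  expect_equal(nrow(b$reactions), 0L)
})

test_that("legacy ISR/CASE headers resolve through the alias map", {
  dir <- tempfile(); dir.create(dir)
  f <- list(
    demo = write_dollar(file.path(dir, "d.txt"),
                        c("ISR", "CASE", "FDA_DT", "GNDR_COD"),
                        c("70001$7001$20110415$F")),
    drug = write_dollar(file.path(dir, "g.txt"),
                        c("ISR", "DRUG_SEQ", "ROLE_COD", "DRUGNAME"),
                        c("70001$1$PS$VIIBRYD")),
    reac = write_dollar(file.path(dir, "r.txt"), c("ISR", "PT"),
                        c("70001$Insomnia")),
    outc = write_dollar(file.path(dir, "o.txt"), c("ISR", "OUTC_COD")),
    ther = write_dollar(file.path(dir, "t.txt"),
                        c("ISR", "DSG_DRUG_SEQ", "START_DT")))
  b <- parse_quarter(f$demo, f$drug, f$reac, f$outc, f$ther, "2011Q2")
  expect_equal(b$demo$primaryid, "70001")
  expect_equal(b$demo$caseid, "7001")
  expect_equal(b$demo$sex, "F")
  expect_equal(b$drugs$primaryid, "70001")  # mentions keyed by ISR value
})

test_that("missing files and unrecognized dialects are fatal", {
  dir <- tempfile(); dir.create(dir)
  ok <- write_dollar(file.path(dir, "ok.txt"), c("PRIMARYID", "PT"))
  bad <- write_dollar(file.path(dir, "bad.txt"), c("REPORTID", "PT"),
                      "1$Nausea")
  expect_error(parse_quarter(file.path(dir, "nope.txt"), ok, ok, ok, ok),
               "not found")
  expect_error(parse_quarter(bad, ok, ok, ok, ok), "unrecognized dialect")
})

test_that("malformed rows are skipped and counted, and rows are conserved", {
  dir <- tempfile(); dir.create(dir)
  f <- write_tiny_quarter(dir)
  # append a row with a blank key to REAC
  cat("$Orphanless\n", file = f$reac, append = TRUE)
  expect_message(
    b <- parse_quarter(f$demo, f$drug, f$reac, f$outc, f$ther, "q"),
    "skipped 1 malformed REAC")
  expect_equal(b$log$reac_rows_in,
               nrow(b$reactions) + b$log$reac_skipped + b$log$reactions_orphans)
  expect_equal(b$log$drug_rows_in,
               nrow(b$drugs) + b$log$drug_skipped + b$log$drugs_orphans)
})

test_that("date normalization is idempotent and rejects garbage", {
  raw <- c("20200229", "20200230", "1959 "," 2013", "201306", "notadate",
           "", "21000101")
  once <- faers_date_normalize(raw)
  expect_equal(once,
               c(20200229L, 0L, 0L, 20130101L, 20130601L, 0L, 0L, 0L))
  expect_equal(faers_date_normalize(once[once > 0]), once[once > 0])
  expect_equal(faers_date_precision(raw)[c(1, 4, 5, 6)],
               c("day", "year", "month", "none"))
})

test_that("write_quarter/parse_quarter round-trips both dialects", {
  b <- parse_tiny()
  for (dialect in c("modern", "legacy")) {
    dir2 <- tempfile()
    write_quarter(b, dir2, dialect = dialect)
    b2 <- suppressMessages(parse_quarter(
      file.path(dir2, "DEMO.txt"), file.path(dir2, "DRUG.txt"),
      file.path(dir2, "REAC.txt"), file.path(dir2, "OUTC.txt"),
      file.path(dir2, "THER.txt"), "rt"))
    for (nm in c("demo", "drugs", "reactions", "outcomes", "therapies")) {
      s1 <- data.table::setorderv(data.table::copy(b[[nm]]), names(b[[nm]]))
      s2 <- data.table::setorderv(data.table::copy(b2[[nm]]), names(b[[nm]]))
      expect_equal(s1, s2, ignore_attr = TRUE)
    }
  }
})

test_that("parse_deleted_list handles headers, duplicates, empty files", {
  p <- tempfile()
  writeLines(c("111", "222", "111"), p)
  expect_setequal(parse_deleted_list(p), c("111", "222"))
  writeLines(c("CASEID", "333"), p)
  expect_equal(parse_deleted_list(p), "333")
  writeLines(character(), p)
  expect_equal(parse_deleted_list(p), character())
  expect_error(parse_deleted_list(tempfile()), "not found")
})

test_that("PT/SOC maps load, look up case-insensitively, reject conflicts", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("pt,soc_name,soc_code",
               "Insomnia,Psychiatric disorders,10037175",
               "Nausea,Gastrointestinal disorders,10017947"), p)
  v <- load_pt_soc_map(p)
  hit <- map_pt_to_soc(v, c("INSOMNIA", "insomnia", "Vertigo"))
  expect_equal(hit$soc_name[1:2], rep("Psychiatric disorders", 2))
  expect_equal(hit$soc_code[1], 10037175L)
  expect_true(is.na(hit$soc_name[3]))

  writeLines(c("pt,soc_name,soc_code",
               "Nausea,Gastrointestinal disorders,10017947",
               "Nausea,Psychiatric disorders,10037175"), p)
  expect_error(load_pt_soc_map(p), "conflicting.*Nausea", ignore.case = TRUE)

  writeLines("pt,soc_name,soc_code", p)
  v0 <- load_pt_soc_map(p)
  expect_true(is.na(map_pt_to_soc(v0, "Anything")$soc_name))
})
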