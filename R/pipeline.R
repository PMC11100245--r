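# One-command pipeline runs and paper-style output tables.

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full signal-detection pipeline
#'
#' Reads (or simulates) FAERS quarters, deduplicates, selects and profiles
#' the target-drug cohort, builds PT- and SOC-level contingency tables, and
#' writes paper-style output tables:
#' `profile.csv` (cohort profile), `signals_pt.csv` and `signals_soc.csv`
#' (cells, all four statistics with CIs, threshold flags; sorted by case
#' count then EBGM, both descending), `dedup_summary.csv`, and `run.log`.
#'
#' The configuration is a list (or path to a JSON file) with keys:
#' \describe{
#'   \item{synthetic}{arguments for [synth_config()]; mutually exclusive
#'     with `quarters`. The generated files are written under
#'     `<outdir>/synthetic/` and then ingested like real data.}
#'   \item{quarters}{list of per-quarter lists with paths `demo`, `drug`,
#'     `reac`, `outc`, `ther`, optional `deleted`, optional `label`.}
#'   \item{drug_query}{list with `names`, optional `roles`, `match_fields`.}
#'   \item{vocabulary}{path to a PT/SOC CSV; required for SOC-level output
#'     (the synthetic branch defaults to the generated vocabulary).}
#'   \item{levels}{subset of `c("pt", "soc")`, default both when a
#'     vocabulary is available, else `"pt"`.}
#'   \item{min_a, yates, rule}{threshold knobs, defaults 3, FALSE, "all".}
#'   \item{seed}{seed for the synthetic branch (overrides the one in
#'     `synthetic`).}
#' }
#'
#' @param config list or path to a JSON config
#' @param outdir output directory (default `config$outdir`)
#' @return invisibly, a list with the bundle, cohort, profile, and signal
#'   tables; files are written under `outdir`
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- .read_config(config)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("no output directory given", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "run.log"), "w")
  on.exit(close(logcon))
  .log_line(logcon, "faersignal ", as.character(utils::packageVersion(
    "faersignal")), " | R ", R.version$major, ".", R.version$minor)

  vocab_path <- config$vocabulary
  deleted <- character()
  if (!is.null(config$synthetic)) {
    sargs <- config$synthetic
    if (!is.null(config$seed)) sargs$seed <- config$seed
    for (nm in c("drugs", "pts", "signal_pairs")) {
      if (!is.null(sargs[[nm]])) sargs[[nm]] <- as.data.table(sargs[[nm]])
    }
    scfg <- do.call(synth_config, sargs)
    sdir <- file.path(outdir, "synthetic")
    gen <- synth_generate(scfg, sdir)
    .log_line(logcon, "simulated ", scfg$n_reports, " reports (seed ",
              scfg$seed, ") under ", sdir)
    quarters <- list(list(demo = gen$files[["demo"]],
                          drug = gen$files[["drug"]],
                          reac = gen$files[["reac"]],
                          outc = gen$files[["outc"]],
                          ther = gen$files[["ther"]],
                          deleted = gen$files[["deleted"]],
                          label = "synthetic"))
    if (is.null(vocab_path)) vocab_path <- gen$files[["vocab"]]
  } else if (!is.null(config$quarters)) {
    quarters <- config$quarters
  } else {
    stop("config needs either 'quarters' or 'synthetic'", call. = FALSE)
  }

  bundles <- lapply(seq_along(quarters), function(i) {
    q <- quarters[[i]]
    b <- parse_quarter(q$demo, q$drug, q$reac, q$outc, q$ther,
                       quarter_label = q$label %||% paste0("Q", i))
    .log_line(logcon, "parsed quarter ", b$quarter_label, ": ",
              nrow(b$demo), " demo rows")
    b
  })
  deleted <- unique(unlist(lapply(quarters, function(q) {
    if (!is.null(q$deleted)) parse_deleted_list(q$deleted) else character()
  })))
  bundle <- if (length(bundles) == 1L) bundles[[1]] else bind_bundles(bundles)

  bundle <- dedup_bundle(bundle, deleted)
  fwrite(bundle$dedup_summary, file.path(outdir, "dedup_summary.csv"))
  .log_line(logcon, "dedup: ", bundle$dedup_summary$input_reports,
            " rows in, ", bundle$dedup_summary$versions_collapsed,
            " versions collapsed, ", bundle$dedup_summary$deleted_removed,
            " deleted, ", bundle$dedup_summary$output_reports, " kept")

  qd <- config$drug_query
  if (is.null(qd)) stop("config needs a drug_query", call. = FALSE)
  query <- drug_query(qd$names, roles = qd$roles %||% "PS",
                      match_fields = qd$match_fields %||%
                        c("drugname", "active_ingredient"))
  cohort <- select_target_reports(bundle, query)
  .log_line(logcon, "cohort: ", length(cohort), " reports match ",
            paste(query$names, collapse = "/"))
  if (!length(cohort)) warning("empty cohort: signal tables will be empty",
                               call. = FALSE)

  profile <- profile_cohort(bundle, cohort, query)
  fwrite(profile, file.path(outdir, "profile.csv"))

  vocab <- if (!is.null(vocab_path)) load_pt_soc_map(vocab_path) else NULL
  levels <- tolower(config$levels %||% if (is.null(vocab)) "pt" else
    c("pt", "soc"))
  min_a <- config$min_a %||% 3L
  yates <- isTRUE(config$yates)
  rule <- config$rule %||% "all"

  signals <- list()
  for (level in levels) {
    universe <- build_pairs(bundle, cohort, vocabulary = vocab, level = level)
    tabs <- all_tables(universe, min_a = min_a)
    sig <- evaluate_signal(signal_estimates(tabs, yates = yates),
                           rule = rule, min_a = min_a)
    setorderv(sig, c("a", "ebgm"), order = -1L, na.last = TRUE)
    fwrite(sig, file.path(outdir, paste0("signals_", level, ".csv")))
    .log_line(logcon, level, "-level: N = ", universe$N, " pairs, ",
              nrow(sig), " events with a >= ", min_a, ", ",
              sum(sig$combined), " combined signals (rule ",
              paste(rule, collapse = "+"), ")")
    signals[[level]] <- sig
  }

  invisible(list(bundle = bundle, cohort = cohort, profile = profile,
                 signals = signals, outdir = outdir))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `ingest`, `profile`, `signals`,
#' and `validate-paper`. `simulate` writes a synthetic quarter; `ingest`,
#' `profile`, and `signals` are stage-limited runs of [run_pipeline()];
#' `validate-paper` fits the global denominators to the packaged printed
#' rows and reports per-statistic reproduction (see
#' [validate_printed_rows()]).
#'
#' Flags: `--config <path>`, `--outdir <dir>`, `--seed <int>`,
#' `--level pt|soc`, `--min-a <int>`, `--yates on|off`, `--rule all|any`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`
#' @return exit status, invisibly (0 on success)
#' @export
faers_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: faersignal <simulate|ingest|profile|signals|validate-paper>",
    "[--config path] [--outdir dir] [--seed int] [--level pt|soc]",
    "[--min-a int] [--yates on|off] [--rule all|any]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- if (!is.null(opt$config)) .read_config(opt$config) else list()
        if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
        scfg <- do.call(synth_config, cfg)
        synth_generate(scfg, opt$outdir %||% ".")
        0L
      },
      ingest = ,
      profile = ,
      signals = {
        cfg <- .read_config(opt$config)
        if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
        if (!is.null(opt$level)) cfg$levels <- opt$level
        if (!is.null(opt$min_a)) cfg$min_a <- as.integer(opt$min_a)
        if (!is.null(opt$yates)) cfg$yates <- identical(opt$yates, "on")
        if (!is.null(opt$rule)) cfg$rule <- opt$rule
        run_pipeline(cfg, outdir = opt$outdir)
        0L
      },
      `validate-paper` = {
        res <- validate_printed_rows()
        out <- opt$outdir %||% "."
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        fwrite(res, file.path(out, "paper_validation.csv"))
        message(sum(res$pass_ror & pmin(res$pass_ebgm, 1)), "/", nrow(res),
                " rows reproduce ROR and EBGM within tolerance")
        0L
      },
      { message("unknown subcommand: ", cmd, "\n", usage); 1L })
  }, error = function(e) {
    message("faersignal error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
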