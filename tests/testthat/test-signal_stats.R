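# Hand-derived expectations below were frozen from the helper oracle
# (naive scalar formulas + stats::chisq.test), evaluated once and checked
# against by-hand arithmetic for the (3, 7, 30, 960) table.

ref_tab <- contingency_cells(3, 7, 30, 960)

test_that("ROR matches hand arithmetic and the oracle", {
  r <- ror(ref_tab)
  expect_equal(r$ror, 3 * 960 / (7 * 30))          # 13.7143
  expect_equal(r$ror, 13.7142857, tolerance = 1e-6)
  expect_equal(r$ror_lo, 3.3799, tolerance = 1e-4)  # SE = 0.714538
  o <- oracle_stats(3, 7, 30, 960)
  expect_equal(r$ror_hi, o$ror_hi, tolerance = 1e-12)

  sym <- ror(contingency_cells(5, 5, 5, 5))
  expect_equal(sym$ror, 1)
  expect_true(sym$ror_lo < 1 && sym$ror_hi > 1)

  expect_error(ror(contingency_cells(0, 7, 30, 960)),
               class = "faers_not_evaluable")
})

test_that("PRR matches hand arithmetic and is 1 under independence", {
  p <- prr(ref_tab)
  expect_equal(p$prr, (3 / 10) / (30 / 990))        # 9.9
  expect_equal(p$prr_lo, 3.6048, tolerance = 1e-4)  # SE = 0.515419
  expect_equal(prr(contingency_cells(10, 90, 100, 900))$prr, 1)
  expect_error(prr(contingency_cells(3, 7, 0, 990)),
               class = "faers_not_evaluable")
})

test_that("chi-squared agrees with stats::chisq.test in both variants", {
  o <- oracle_stats(3, 7, 30, 960)
  expect_equal(chi_square(ref_tab), o$chi2_plain, tolerance = 1e-12)
  expect_equal(chi_square(ref_tab), 22.57, tolerance = 1e-3)
  expect_equal(chi_square(ref_tab, yates = TRUE), o$chi2_yates,
               tolerance = 1e-12)
  expect_equal(chi_square(ref_tab, yates = TRUE), 14.91, tolerance = 1e-3)
  expect_equal(chi_square(contingency_cells(10, 90, 100, 900)), 0)
  # zero margin -> 0
  expect_equal(chi_square(contingency_cells(0, 0, 30, 960)), 0)
})

test_that("BCPNN moments match the printed closed forms", {
  # by hand: gamma = 1002 * 1002 / (11 * 34) = 2684.50, E(IC) = 1.543
  ic <- bcpnn_ic(ref_tab)
  expect_equal(ic$ic, 1.543, tolerance = 1e-3)
  o <- oracle_stats(3, 7, 30, 960)
  expect_equal(ic$ic, o$ic, tolerance = 1e-12)
  expect_equal(ic$v_ic, o$v_ic, tolerance = 1e-12)
  expect_equal(ic$ic025, o$ic025, tolerance = 1e-12)

  # independence: slightly below 0 because of shrinkage
  ic0 <- bcpnn_ic(contingency_cells(10, 90, 100, 900))
  expect_lt(ic0$ic, 0)
  expect_gt(ic0$ic, -0.2)

  # defined at a = 0 through the priors
  expect_true(is.finite(bcpnn_ic(contingency_cells(0, 10, 30, 960))$ic))

  expect_error(bcpnn_priors(alpha = 0), "positive")
})

test_that("EBGM is the observed/expected ratio with the log-scale CI", {
  e <- ebgm(ref_tab)
  expect_equal(e$ebgm, 3 * 1000 / (33 * 10))        # 9.0909
  expect_equal(e$ebgm_lo, 2.2405, tolerance = 1e-4)
  expect_equal(ebgm(contingency_cells(10, 90, 100, 900))$ebgm, 1)
  # identity: EBGM == (a/(a+b)) / ((a+c)/N), the relative reporting ratio
  with(ref_tab, expect_equal(e$ebgm, (a / (a + b)) / ((a + c) / N)))
  expect_error(ebgm(contingency_cells(0, 7, 30, 960)),
               class = "faers_not_evaluable")
})

test_that("signal thresholds and combination rules behave as printed", {
  est <- signal_estimates(data.frame(a = 3, b = 7, c = 30, d = 960))
  dec <- evaluate_signal(est, rule = "all")
  expect_true(dec$pass_ror)   # lo 3.38 > 1
  expect_true(dec$pass_prr)   # lo 3.60 > 1
  expect_equal(dec$pass_bcpnn, dec$ic025 > 0)
  expect_true(dec$pass_ebgm)  # lo 2.24 > 2
  expect_equal(dec$combined,
               dec$pass_ror & dec$pass_prr & dec$pass_bcpnn & dec$pass_ebgm)

  # a < 3 fails ROR/PRR regardless of the CI
  est2 <- signal_estimates(data.frame(a = 2, b = 1, c = 5, d = 992))
  dec2 <- evaluate_signal(est2)
  expect_false(dec2$pass_ror)
  expect_false(dec2$pass_prr)

  # independence -> nothing passes
  dec3 <- evaluate_signal(signal_estimates(
    data.frame(a = 10, b = 90, c = 100, d = 900)))
  expect_false(any(dec3[, c("pass_ror", "pass_prr", "pass_bcpnn",
                            "pass_ebgm", "combined")]))

  # subset rule
  dec4 <- evaluate_signal(est, rule = c("ror", "ebgm"))
  expect_equal(dec4$combined, dec4$pass_ror & dec4$pass_ebgm)
  dec5 <- evaluate_signal(est2, rule = "any")
  expect_equal(dec5$combined, dec5$pass_bcpnn | dec5$pass_ebgm |
                 dec5$pass_ror | dec5$pass_prr)
})

test_that("batch estimates flag zero-cell tables instead of correcting them", {
  tabs <- data.frame(a = c(3, 0, 5), b = c(7, 10, 0), c = c(30, 30, 5),
                     d = c(960, 960, 990))
  est <- signal_estimates(tabs)
  expect_equal(est$evaluable, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(est$ror[2:3])))
  expect_true(all(is.finite(est$ic)))  # BCPNN defined everywhere
  dec <- evaluate_signal(est)
  expect_false(dec$pass_ror[2])        # NA never passes
})

test_that("monotonicity: ror and ebgm strictly increase in a", {
  a <- 1:50
  est <- signal_estimates(data.frame(a = a, b = 100, c = 200, d = 10000))
  expect_true(all(diff(est$ror) > 0))
  expect_true(all(diff(est$ebgm) > 0))
})

test_that("shrinkage vanishes at scale: E(IC) -> log2(EBGM)", {
  # the residual gap behaves like log2((1 + 1/a) / (1 + EBGM/a)), so it
  # shrinks as the cells scale up at fixed EBGM
  base <- c(a = 2, b = 70, c = 1100, d = 250000)
  gaps <- sapply(c(1, 10, 100, 2000), function(k) {
    est <- signal_estimates(as.data.frame(as.list(base * k)))
    abs(est$ic - log2(est$ebgm))
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 0.01)  # a = 4000, N ~ 5e8
  big <- signal_estimates(data.frame(a = 505, b = 13995, c = 220000,
                                     d = 49700000))
  expect_lt(abs(big$ic - log2(big$ebgm)), 0.02)
})

test_that("null tables keep the one-sided ROR pass rate near nominal", {
  # independence draws with expected a = 10; pass_ror should stay below
  # 7.5% (nominal 2.5% one-sided plus small-count inflation)
  set.seed(424)
  n_tab <- 2000L
  N <- 20000L; p_drug <- 0.05; p_event <- 0.01
  probs <- c(p_drug * p_event, p_drug * (1 - p_event),
             (1 - p_drug) * p_event, (1 - p_drug) * (1 - p_event))
  cells <- stats::rmultinom(n_tab, N, probs)
  est <- evaluate_signal(signal_estimates(data.frame(
    a = cells[1, ], b = cells[2, ], c = cells[3, ], d = cells[4, ])))
  expect_lt(mean(est$pass_ror), 0.075)
})
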