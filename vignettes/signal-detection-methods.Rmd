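---
title: "Disproportionality signal detection for FAERS: models, defaults, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for FAERS: models, defaults, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(data.table)
```

## The problem

Spontaneous-reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect suspected drug–adverse-event reports with no denominator: we
observe how often a drug and an event are *reported together*, never how
often the drug is taken. Disproportionality analysis sidesteps the missing
denominator by asking whether a drug–event pair is reported more often than
the rest of the database would predict. For one target drug and one event the
data reduce to a 2×2 table

|                | event | other events | total |
|----------------|------:|-------------:|------:|
| target drug    | a     | b            | a + b |
| all other drugs| c     | d            | c + d |
| total          | a + c | b + d        | N     |

and the package computes four standard statistics on it:

* **ROR** (reporting odds ratio) `= ad/bc`, with a 95% CI from the log-scale
  standard error `sqrt(1/a + 1/b + 1/c + 1/d)`;
* **PRR** (proportional reporting ratio) `= (a/(a+b)) / (c/(c+d))`, with SE
  `sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`;
* the Pearson **χ²** on the table (Yates correction optional, off by
  default — published FAERS tables are reproducible with either variant at
  the report counts involved, so the choice is a documented knob rather than
  a silent one);
* the **BCPNN information component** `IC = log2 p(drug, event) /
  (p(drug) p(event))`, reported through its posterior moments `E(IC)` and
  `V(IC)` under Dirichlet priors, with `IC025 = E(IC) − 2·sqrt(V(IC))`;
* **EBGM**, here the observed/expected reporting ratio
  `a·N / ((a+c)(a+b))` with a log-scale CI (see *Numerical choices*).

A pair is conventionally flagged when `a ≥ 3` and the ROR/PRR CI lower bound
exceeds 1, `IC025 > 0`, and `EBGM05 > 2`; `evaluate_signal()` applies these
flags and combines them under an `all`/`any`/subset rule. How published
analyses combine the four methods into a single "signal" count is rarely
stated; the default here is the conservative `all`.

## Counting unit: report × event pairs

The cells count *pairs*, not raw reports: each deduplicated report
contributes one pair per distinct PT (or per distinct mapped primary SOC at
SOC level), flagged by whether the report names the target drug. This choice
is forced by arithmetic: published full-database tables report target-drug
margins (`a + b`) several times larger than the target cohort's report
count, which is only consistent with pair-level denominators. A report that
names the target drug contributes to `a`/`b` only — it is never recycled
into the background cells, even if it also names other suspect drugs. The
comparator is the full remaining database (the reproduced study names no
active-comparator restriction).

## Deduplication

A FAERS case (CASEID) may appear as several report versions (PRIMARYID).
`deduplicate()` keeps, per case, the version with the largest FDA receipt
date, breaking ties by the largest PRIMARYID (numeric comparison when ids
are numeric); deleted-case lists, shipped quarterly since 2019Q1, are
applied *after* version collapsing, and the union of all supplied lists is
applied globally — the source procedure does not say whether later lists
apply retroactively, and the global union is the conservative reading.
Tie-breaking beyond (FDA date, PRIMARYID) cannot arise because PRIMARYID is
unique per version; the code asserts this instead of inventing a third key.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_a` | 3 | case reports | the printed "a ≥ 3" precondition; pairs below it are not assessable |
| BCPNN priors `(α, β, α1, β1, γ11)` | (2, 2, 1, 1, 1) | pseudo-counts | the standard choice; reproduces published IC columns through the desk-scale reconstruction (e.g. Insomnia 2.96, Suicidal ideation 3.57). `γ` is derived from the margins, never set. |
| `yates` | off | — | both variants reproduce published χ² within rounding at these counts |
| `rule` | `all` | — | conservative combination of the four flags |
| age unit factors | YR 1, DEC 10, MON 1/12, WK 1/52.18, DY 1/365.25, HR 1/8766 | years per unit | FAERS `AGE_COD` codes |

Age groups are left-closed, right-open at the joints (`[18,45)`, `[45,65)`,
`[65,75)`, `[75,∞)`): published tables print overlapping labels ("18–45",
"45–65", …), and half-open bins are the unique deterministic disjoint
reading. Onset-day bins are closed as printed: `[0,30]`, `[31,60]`, …,
`[181,360]`, `>360`; negative spans (therapy starting after the event) and
undated spans are `Unknown` rather than clamped.

## Zero cells

No Haldane–Anscombe 0.5 correction is applied anywhere. A zero cell makes
ROR/PRR/EBGM "not evaluable" (a classed condition from the scalar functions,
`NA` + `evaluable = FALSE` in batch output); the BCPNN moments remain defined
through the priors. In practice the `a ≥ 3` floor removes such pairs before
they are assessed, which is exactly how the printed threshold treats them.

## Reconstructing published statistics (the paper oracle)

Published signal tables print, per event, the case count `a` and rounded
statistics, but never the pair-level denominators `T = a + b` and `N`. Two
observations recover them:

1. eliminating `c` between the ROR and PRR formulas gives a per-row closed
   form `T = a(R − 1/PRR)/(R − 1)` with `R = ROR/PRR` — independent of `N`;
2. `EBGM = PRR·N / (N + T(PRR − 1))` is sensitive to `N` exactly for rows
   where the printed EBGM visibly drops below the printed PRR (small `a`,
   large PRR).

`fit_globals()` least-squares (T, N) on the relative errors of predicted ROR
and EBGM over three calibration rows — Diarrhoea, Nausea, Sleep paralysis,
chosen so that no reproduction target participates in its own calibration;
Sleep paralysis supplies the N-sensitivity. `predict_row()` then rebuilds
any row's full table from `(a, PRR, T, N)` and evaluates every statistic.
On the packaged rows the fit lands at `T ≈ 1.48e4`, `N ≈ 4.26e7`, and
reproduces the non-calibration rows' ROR and EBGM to well within the ±2%
rounding-propagation budget (±0.05 absolute for IC); `validate_printed_rows()`
reports the full per-row comparison. Because printed values carry ±0.005
rounding, per-row `T` estimates from rows with ROR ≈ PRR are wildly
uncertain (Dizziness's 2.67 vs 2.64 admits T anywhere in roughly
[13k, 26k]); consistency checks therefore propagate the rounding interval
instead of comparing points.

The SOC-level published table is *not* reconstructed: it prints one SOC
label twice with two different SOC codes, so its rows cannot be trusted
row-wise, and no correction is guessed.

## The synthetic generator: what it emulates, and what it does not

`synth_generate()` exists so the entire pipeline — file dialects, dedup,
cohort profiling, pair counting, statistics — runs and is tested with no
FAERS download. Its model is deliberately minimal and fully stated:

* each report includes each configured drug **independently** with its
  marginal probability. This is a deviation from a count-then-sample design:
  with Bernoulli inclusion the configured marginal *is* the inclusion
  probability, making pair expectations exact products
  (`E[a] = n·p_drug·baseline·λ`) and parameter-recovery tests closed-form.
  Reports may consequently carry zero drugs or zero reactions; both are
  harmless at the pair-counting level and are documented model properties,
  not FAERS claims;
* given the drug set, each PT is an independent Bernoulli with probability
  `baseline·λ`, where `λ` is the largest rate ratio among the report's
  drugs with a signal pair for that PT (1 otherwise); configs where
  `λ·baseline > 1` are rejected outright;
* demographics are drawn from marginals whose defaults are the reproduced
  cohort's published profile (65.40% female, 47.85% missing age, 59.78%
  consumer-reported, 98.4% US, years 2011–2023 peaking in 2013), so the
  default world is the stated one rather than a tuned one;
* duplicate versions get a strictly later FDA date, so the deduplication
  rule has a unique right answer, and the deleted list is drawn from case
  ids — dedup recovery is exact by construction.

`expected_ebgm()` computes the model-implied EBGM as a ratio of expected
cells, exactly under drug independence. Note that this is *below* the design
`λ` whenever the drug is common or its signal pairs are strong: the drug's
own elevated reporting inflates both the event margin (`a + c`) and its pair
total (`a + b`). The value approaches `λ` only in the rare-drug, rare-event
limit, and recovery tests compare the pipeline against `expected_ebgm()`,
not against `λ` itself. For the same reason the BCPNN shrinkage gap
`E(IC) − log2(EBGM)` behaves like `log2((1 + 1/a)/(1 + EBGM/a))` — it
vanishes as counts scale at fixed disproportionality, but "large counts"
means `a` large relative to `EBGM − 1`, not any fixed floor.

What the generator does **not** emulate: free-text drug-name noise beyond
configured synonyms, verbatim-term (LLT) coding, secular reporting trends,
correlated demographics, multi-axial MedDRA, or report-level covariance
between events. A green synthetic test therefore establishes that the
pipeline implements its stated model and formulas — not that the model is a
faithful portrait of FAERS reporting behaviour.

## Numerical choices

* **EBGM is the printed formula, not MGPS.** The methods tradition calls the
  DuMouchel Gamma–Poisson shrinker "EBGM", but the reproduced tables print
  the raw observed/expected ratio with a log-normal-style CI — at e.g.
  Insomnia's `a = 505` a genuinely shrunk posterior mean could not match the
  raw ratio to 2 d.p. as the printed value does. The package implements what
  the tables print; a true GPS posterior is out of scope.
* **Rounding** of printed-style percentages is half-away-from-zero
  (`round_half_up()`), matching published tables; base R's half-to-even
  would print 65.39 where the source prints 65.40.
* The global-denominator fit runs Nelder–Mead on `(log T, log N)` with a
  restart, `reltol 1e-14`; the objective is smooth and the fit is
  deterministic for a fixed row set.
* Dates are normalized to integer `YYYYMMDD`, 0 when blank or garbled;
  partial dates are padded with 01 and flagged with a precision field, which
  keeps onset-day arithmetic defined while recording the loss. Calendar
  validity is checked (2020-02-30 is garbled, not padded).
* χ² denominators are computed in doubles: the product of the four margins
  overflows 32-bit integers already at modest N.

## Known limitations

* Substring drug matching is deliberately naive: no RxNorm normalization,
  no spelling correction. Synonym lists are the user's responsibility.
* MedDRA is licensed; the package takes a user-supplied PT→SOC table and a
  packaged synthetic vocabulary for tests, with single-primary-SOC semantics
  (no multi-axiality).
* No stratified or adjusted analyses (age/sex/year), matching the crude
  statistics of the reproduced tables; no multiple-comparison control.
* The desk-scale reconstruction inherits the printed tables' rounding: its
  tolerances (±2% relative, ±0.05 on IC) are rounding-propagation budgets,
  not estimates of statistical uncertainty.
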