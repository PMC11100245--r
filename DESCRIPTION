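Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Sam", "Riley", email = "sam.riley@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for FDA Adverse Event
    Reporting System (FAERS) quarterly data: parsing of the '$'-delimited
    ASCII dialects (modern PRIMARYID/CASEID and legacy ISR/CASE), the
    FDA-recommended case deduplication rule, deleted-case removal, drug
    cohort selection and descriptive profiling, construction of drug-event
    2x2 contingency tables at MedDRA Preferred Term and System Organ Class
    level, and the four standard disproportionality statistics (reporting
    odds ratio, proportional reporting ratio with chi-squared, the Bayesian
    confidence propagation neural network information component, and the
    empirical Bayes geometric mean) with confidence intervals and signal
    thresholds. A synthetic FAERS generator with known signal structure
    supports testing without any download, and a printed-row oracle
    reconstructs full-database statistics from published summary rows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
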