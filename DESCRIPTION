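Package: vaersvasc
Title: Vasculitis Adverse-Event Analysis for VAERS Surveillance Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for retrospective analysis of vasculitis
    adverse events (Kawasaki disease, Multisystem Inflammatory Syndrome
    variants, Henoch-Schonlein purpura, and other vasculitis) in the U.S.
    Vaccine Adverse Event Reporting System (VAERS). Reads and joins the
    yearly VAERS three-file CSV exports, flags case reports by MedDRA
    preferred term, tabulates normalized reporting frequencies per 100,000
    reports with symptoms by vaccine and by age, tests each vaccine's
    frequency against a background incidence with chi-squared tests under
    Bonferroni correction, and implements an expected-count model of
    background versus vaccine-attributable reporting with day-dependent
    reporting bias, together with a Monte-Carlo simulator, a cross-vaccine
    homogeneity test, and a synthetic VAERS generator with sidecar ground
    truth so the whole pipeline runs without any data download.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
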