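Package: contactcov
Title: Contact Coverage Estimation for Severe Mental Disorders from
    Routine Service-Utilisation Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates 12-month contact coverage (the proportion of people
    with a disorder who had at least one contact with a specialist mental
    health service) for psychosis, bipolar disorder and moderate-severe
    depression from country-reported service-utilisation tables and
    population prevalence inputs. Implements validity screens for routine
    health-information-system reports (completeness, visits-per-case,
    plausibility thresholds), a follow-up-based correction for
    double-counting of individuals seen in both inpatient and outpatient
    settings, delta-method propagation of uncertainty through the coverage
    ratio and its logit transform, and DerSimonian-Laird random-effects
    pooling by income group and region with Baujat influence diagnostics.
    Ships a synthetic-cohort generator with known ground truth, including a
    patient-level simulator that serves as an oracle for the
    double-counting adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
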