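test_that("reading an atlas CSV keeps missing cells missing, never zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "country_code,disorder,inpatient_cases,outpatient_cases,inpatient_visits,outpatient_visits,representativeness,followup_category,reported_population",
    "AAA,psychosis,100,500,300,1500,0.8,2,1000000",
    "BBB,bipolar,,200,100,600,0.9,1,2000000",
    "CCC,depression,50,0,80,0,1,,"), path)
  rec <- read_atlas_table(path)
  expect_equal(nrow(rec), 3L)
  expect_true(is.na(rec$inpatient_cases[2]))
  expect_identical(rec$outpatient_cases[3], 0)   # a reported zero stays zero
  expect_true(is.na(rec$followup_category[3]))
  expect_true(is.na(rec$reported_population[3]))
})

test_that("malformed headers and invalid values are rejected with location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_code,disorder,inpatient_cases", "AAA,psychosis,1"),
             path)
  expect_error(read_atlas_table(path), "missing column")

  bad <- make_records(list(inpatient_cases = -5))
  expect_error(validate_atlas_records(bad), "row\\(s\\) 1")
  expect_error(validate_atlas_records(make_records(list(representativeness = 1.2))),
               "representativeness")
  expect_error(validate_atlas_records(make_records(list(followup_category = 7))),
               "followup_category")
  expect_error(validate_atlas_records(make_records(list(disorder = "anxiety"))),
               "unknown disorder")
})

test_that("completeness screen requires both settings and representativeness", {
  rec <- make_records(
    list(),                                       # complete
    list(outpatient_cases = NA),                  # missing a setting
    list(inpatient_cases = NA),
    list(representativeness = NA),
    list(outpatient_cases = NA, representativeness = NA))
  s <- screen_completeness(rec)
  expect_equal(s$included, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(s$reason, c("ok", "missing_inpatient_or_outpatient",
                           "missing_inpatient_or_outpatient",
                           "missing_representativeness",
                           "missing_inpatient_or_outpatient"))
  # included iff reason is ok
  expect_identical(s$included, s$reason == "ok")
  # idempotent: re-screening the same records yields identical decisions
  expect_identical(screen_completeness(rec), s)
})

test_that("visits-per-case screen excludes ratios strictly below one", {
  rec <- make_records(
    list(inpatient_cases = 100, outpatient_cases = 100,
         inpatient_visits = 150, outpatient_visits = 150),  # ratio 1.5
    list(inpatient_cases = 100, outpatient_cases = 0,
         inpatient_visits = 50, outpatient_visits = 0),     # ratio 0.5
    list(inpatient_cases = 100, outpatient_cases = 100,
         inpatient_visits = 100, outpatient_visits = 100),  # ratio exactly 1
    list(inpatient_cases = 0, outpatient_cases = 0,
         inpatient_visits = 50, outpatient_visits = 0))     # undefined ratio
  s <- visits_per_case_check(rec)
  expect_equal(s$included, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(s$reason[2], "visits_per_case_below_one")
})

test_that("records with no visit counts pass the visits screen with a warning", {
  rec <- make_records(list(inpatient_visits = NA, outpatient_visits = NA))
  expect_warning(s <- visits_per_case_check(rec), "skipped")
  expect_true(s$included)
})

test_that("population resolution prefers plausible reported figures", {
  ctx <- make_context(c("AAA", "BBB", "CCC"), un_population = c(5e6, 1.05e6, 1e6))
  rec <- make_records(
    list(country_code = "AAA", reported_population = NA),
    list(country_code = "BBB", reported_population = 1e6),    # 4.8% off UN
    list(country_code = "CCC", reported_population = 1e5))    # 90% off UN
  pop <- suppressMessages(resolve_population(rec, ctx, divergence_limit = 0.30))
  expect_equal(as.numeric(pop), c(5e6, 1e6, 1e6))
  expect_equal(attr(pop, "substituted"), c(TRUE, FALSE, TRUE))
  expect_true(all(pop > 0))
  expect_error(resolve_population(make_records(list(country_code = "ZZZ")),
                                  ctx), "ZZZ")
})

test_that("screens conserve records: included + per-reason exclusions = total", {
  sim <- simulate_atlas_cohort(n_countries = 50, seed = 11)
  s1 <- screen_completeness(sim$atlas)
  alive <- which(s1$included)
  s2 <- suppressWarnings(visits_per_case_check(sim$atlas[alive, ]))
  n_excl <- sum(!s1$included) + sum(!s2$included)
  n_incl <- sum(s2$included)
  expect_equal(n_incl + n_excl, nrow(sim$atlas))
})
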