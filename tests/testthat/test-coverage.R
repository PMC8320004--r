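test_that("treated prevalence uses the binomial standard error", {
  r <- treated_prevalence(10000, 1e6)
  expect_equal(r$p_t, 0.01)
  expect_equal(r$se_t, sqrt(0.01 * 0.99 / 1e6))
  expect_equal(r$se_t, 9.95e-5, tolerance = 1e-3)

  expect_equal(treated_prevalence(0, 1e6)$se_t, 0)
  expect_equal(treated_prevalence(5e5, 1e6)$se_t, 5e-4)
  expect_error(treated_prevalence(2e6, 1e6), "census")
})

test_that("coverage ratio and its delta-method SE behave as specified", {
  r <- coverage_ratio(0.01, 0.001, 0.02, 0.002)
  expect_equal(r$c, 0.5)
  expect_equal(r$se_c, 0.5 * sqrt(0.01 + 0.01))
  expect_equal(r$se_c, 0.0707, tolerance = 1e-3)

  expect_equal(coverage_ratio(0.01, 0, 0.02, 0)$se_c, 0)
  expect_equal(coverage_ratio(0, 0.001, 0.02, 0.002)$c, 0)
  expect_equal(coverage_ratio(0, 0.001, 0.02, 0.002)$se_c, 0.001 / 0.02)

  expect_warning(r1 <- coverage_ratio(0.02, 0, 0.02, 0), "capped")
  expect_equal(suppressWarnings(coverage_ratio(0.03, 0, 0.02, 0)$c), 0.999)
  expect_error(coverage_ratio(0.01, 0.001, 0, 0), "undefined")
})

test_that("coverage is invariant to common scaling of counts and population", {
  base <- list(cases = 12000, pop = 2e6, prev = 0.015)
  for (s in c(0.5, 3, 10)) {
    tp <- treated_prevalence(base$cases * s, base$pop * s)
    c1 <- coverage_ratio(tp$p_t, tp$se_t, base$prev, 0.001)$c
    tp0 <- treated_prevalence(base$cases, base$pop)
    c0 <- coverage_ratio(tp0$p_t, tp0$se_t, base$prev, 0.001)$c
    expect_equal(c1, c0)
  }
})

test_that("logit delta SE matches the numerical derivative across a grid", {
  grid <- seq(0.01, 0.99, by = 0.01)
  se_c <- 0.01
  h <- 1e-6
  for (c in grid) {
    lg <- logit_with_delta(c, se_c)
    num_deriv <- (log((c + h) / (1 - c - h)) -
                  log((c - h) / (1 - c + h))) / (2 * h)
    expect_equal(lg$se_logit, se_c * num_deriv, tolerance = 1e-6)
  }
  # closed-form spot values and the inverse round trip
  lg <- logit_with_delta(0.5, 0.05)
  expect_equal(lg$logit_c, 0)
  expect_equal(lg$se_logit, 0.2)
  expect_equal(logit_with_delta(0.5, 0)$se_logit, 0)
  for (c in c(0.05, 0.3, 0.77))
    expect_equal(1 / (1 + exp(-logit_with_delta(c, 0.01)$logit_c)), c,
                 tolerance = 1e-12)
})

test_that("boundary proportions get the 1/(4n) continuity correction", {
  n <- 1e4
  lg0 <- logit_with_delta(0, 0.001, n = n)
  expect_equal(lg0$logit_c, log((1 / (4 * n)) / (1 - 1 / (4 * n))))
  lg1 <- logit_with_delta(1, 0.001, n = n)
  expect_equal(lg1$logit_c, -lg0$logit_c)
  expect_error(logit_with_delta(0, 0.001), "continuity")
})

test_that("delta-method ratio SE agrees with Monte-Carlo propagation", {
  set.seed(77)
  n_draws <- 10000
  for (c_target in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    p_g <- 0.02; se_g <- 0.001
    p_t <- c_target * p_g; se_t <- 0.05 * p_t
    delta <- coverage_ratio(p_t, se_t, p_g, se_g)$se_c
    draws_t <- rnorm(n_draws, p_t, se_t)
    draws_g <- rnorm(n_draws, p_g, se_g)
    keep <- draws_t > 0 & draws_t < 1 & draws_g > 0 & draws_g < 1
    mc <- sd(draws_t[keep] / draws_g[keep])
    expect_lt(abs(delta - mc) / mc, 0.10)
  }
})

test_that("thresholds exclude strictly outside bounds; absent bounds never do", {
  thr <- data.frame(
    disorder = c("psychosis", "depression", "bipolar"),
    income_group = "high",
    lower = c(0.02, NA, NA),
    upper = c(NA, 0.506, 0.229), stringsAsFactors = FALSE)
  r <- apply_thresholds(c(0.99, 0.70, 0.001),
                        c("psychosis", "depression", "bipolar"),
                        rep("high", 3), thr)
  expect_equal(r$included, c(TRUE, FALSE, TRUE))
  expect_equal(r$reason[2], "outside_threshold")
  # below a present lower bound
  expect_false(apply_thresholds(0.01, "psychosis", "high", thr)$included)
  # exactly on a bound is inside
  expect_true(apply_thresholds(0.02, "psychosis", "high", thr)$included)
  # NULL table disables filtering
  expect_true(all(apply_thresholds(c(0, 1), rep("depression", 2),
                                   rep("high", 2), NULL)$included))
})

test_that("the shipped default threshold table is well formed", {
  thr <- default_thresholds()
  expect_setequal(unique(thr$disorder), c("psychosis", "bipolar", "depression"))
  expect_setequal(unique(thr$income_group),
                  c("low", "lower_middle", "upper_middle", "high"))
  # psychosis: lower bounds only; bipolar/depression: upper bounds only
  expect_true(all(is.na(thr$upper[thr$disorder == "psychosis"])))
  expect_true(all(!is.na(thr$lower[thr$disorder == "psychosis"])))
  expect_true(all(is.na(thr$lower[thr$disorder != "psychosis"])))
  expect_true(all(!is.na(thr$upper[thr$disorder != "psychosis"])))
})
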