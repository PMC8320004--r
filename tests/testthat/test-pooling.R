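## Fixed heterogeneous 5-study fixture; expected values frozen from the
## step-by-step oracle (oracle_dl in helper-oracles.R).
DL_Y <- c(-2.20, -1.40, -0.75, -1.90, -0.30)
DL_SE <- c(0.30, 0.20, 0.25, 0.40, 0.35)

test_that("DL pooling matches the step-by-step oracle to 1e-10", {
  fit <- dl_random_effects(DL_Y, DL_SE)
  orc <- oracle_dl(DL_Y, DL_SE)
  expect_equal(fit$pooled_logit, orc$mu, tolerance = 1e-10)
  expect_equal(fit$tau2, orc$tau2, tolerance = 1e-10)
  expect_equal(fit$Q, orc$Q, tolerance = 1e-10)
  expect_equal(fit$se_pooled, orc$se, tolerance = 1e-10)
  # frozen values from the oracle, for drift detection
  expect_equal(fit$pooled_logit, -1.30331398826969, tolerance = 1e-10)
  expect_equal(fit$tau2, 0.411258111400847, tolerance = 1e-10)
  expect_equal(fit$Q, 24.495617772627, tolerance = 1e-10)
  expect_equal(fit$I2, 83.6705485971868, tolerance = 1e-10)
})

test_that("DL pooling agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  fit <- dl_random_effects(DL_Y, DL_SE)
  mf <- metafor::rma(yi = DL_Y, sei = DL_SE, method = "DL")
  expect_equal(fit$pooled_logit, as.numeric(mf$beta), tolerance = 1e-10)
  expect_equal(fit$tau2, mf$tau2, tolerance = 1e-10)
  expect_equal(fit$Q, mf$QE, tolerance = 1e-10)
  expect_equal(fit$se_pooled, mf$se, tolerance = 1e-10)
})

test_that("homogeneous and singleton inputs degenerate correctly", {
  hom <- dl_random_effects(rep(0, 3), rep(0.1, 3))
  expect_equal(hom$pooled_logit, 0)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$Q, 0)
  expect_equal(hom$pooled_proportion, 0.5)

  one <- dl_random_effects(1.0, 0.2)
  expect_equal(one$pooled_logit, 1.0)
  expect_equal(one$tau2, 0)
  expect_equal(one$ci_lower, 1 / (1 + exp(-(1 - 1.959964 * 0.2))),
               tolerance = 1e-6)
  expect_equal(one$k, 1L)

  expect_error(dl_random_effects(numeric(0), numeric(0)), "empty")
  expect_error(dl_random_effects(c(0, 1), c(0.1, 0)), "positive")
})

test_that("with tau2 forced to zero DL reduces to fixed-effect pooling", {
  # inputs homogeneous enough that Q < k-1 truncates tau2 at exactly 0
  y <- c(-1.02, -1.00, -0.99, -1.01)
  se <- c(0.5, 0.4, 0.45, 0.55)
  fit <- dl_random_effects(y, se)
  orc <- oracle_dl(y, se)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$pooled_logit, orc$fixed)
  expect_equal(fit$se_pooled, orc$se_fixed)
})

test_that("pooled estimate is convex in the inputs and permutation invariant", {
  set.seed(12)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    y <- rnorm(k, -1, 1)
    se <- runif(k, 0.1, 0.6)
    fit <- dl_random_effects(y, se)
    expect_gte(fit$pooled_logit, min(y) - 1e-14)
    expect_lte(fit$pooled_logit, max(y) + 1e-14)
    perm <- sample(k)
    fit2 <- dl_random_effects(y[perm], se[perm])
    expect_equal(fit$pooled_logit, fit2$pooled_logit, tolerance = 1e-14)
    expect_equal(fit$tau2, fit2$tau2, tolerance = 1e-14)
  }
})

test_that("group aggregation pools included estimates only, plus an all row", {
  est <- data.frame(
    country_code = sprintf("C%02d", 1:9),
    disorder = "psychosis",
    income_group = c(rep("low", 2), rep("lower_middle", 2),
                     rep("upper_middle", 2), rep("high", 2), "high"),
    logit_c = rnorm(9, -1, 0.3),
    se_logit = runif(9, 0.2, 0.4),
    included = c(rep(TRUE, 8), FALSE),
    stringsAsFactors = FALSE)
  pooled <- aggregate_groups(est, groupings = c("income_group", "all"))
  expect_equal(nrow(pooled), 5L)    # 4 income groups + all
  expect_equal(pooled$k[pooled$grouping == "all"], 8L)  # excluded never enters

  # singleton group passes through its own estimate
  est1 <- est[est$included & est$income_group == "low", ][1, ]
  est1$included <- TRUE
  single <- aggregate_groups(rbind(est1), groupings = "income_group")
  expect_equal(single$k, 1L)
  expect_equal(single$tau2, 0)
  expect_equal(single$pooled_coverage, 1 / (1 + exp(-est1$logit_c)))

  expect_error(aggregate_groups(est, groupings = "continent"), "unknown")
})

test_that("Baujat coordinates flag a planted outlier by leave-one-out", {
  set.seed(31)
  y <- c(rnorm(9, -1.0, 0.05), 2.5)   # one planted outlier
  se <- rep(0.2, 10)
  bj <- baujat_coordinates(y, se, labels = sprintf("S%02d", 1:10))
  expect_equal(which.max(bj$x), 10L)
  expect_equal(which.max(bj$y), 10L)
  expect_true(all(bj$x >= 0 & bj$y >= 0))

  # brute-force leave-one-out oracle for the influence axis
  w <- 1 / se^2
  pooled <- sum(w * y) / sum(w)
  for (i in c(1, 5, 10)) {
    loo <- sum(w[-i] * y[-i]) / sum(w[-i])
    expect_equal(bj$y[i], (pooled - loo)^2 * sum(w[-i]), tolerance = 1e-12)
  }

  # homogeneous studies contribute almost nothing to Q
  bj0 <- baujat_coordinates(rep(-1, 4) + 1e-9 * (1:4), rep(0.2, 4))
  expect_true(all(bj0$x < 1e-12))

  # minimal case k = 2: both computable, symmetric influence
  bj2 <- baujat_coordinates(c(-1, 0), c(0.3, 0.3))
  expect_equal(bj2$x[1], bj2$x[2])
  expect_equal(bj2$y[1], bj2$y[2])
  expect_error(baujat_coordinates(1, 0.1), "at least two")
})

test_that("pooled CI covers the truth at close to nominal rate", {
  ## scaled-down recovery: 150 replications, one group of 20 countries,
  ## true mean logit -1, between-country SD 0.8, small within-study SE
  set.seed(99)
  n_rep <- 150; k <- 20; mu <- -1; tau <- 0.8
  hit <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    se <- runif(k, 0.1, 0.2)
    y <- rnorm(k, mu, tau) + rnorm(k, 0, se)
    fit <- dl_random_effects(y, se)
    lo <- fit$pooled_logit - 1.959964 * fit$se_pooled
    hi <- fit$pooled_logit + 1.959964 * fit$se_pooled
    hit[r] <- lo <= mu && mu <= hi
  }
  expect_gte(mean(hit), 0.88)
  expect_lte(mean(hit), 0.99)
})
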