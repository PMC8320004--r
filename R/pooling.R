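## Random-effects pooling of country coverage estimates on the logit
## scale, and Baujat influence diagnostics. The DerSimonian-Laird moment
## estimator is implemented in closed form; the estimator sits behind this
## one function so an alternative (e.g. REML) can be swapped in.

#' DerSimonian-Laird random-effects pooling
#'
#' Pools estimates `y_i` (here: logit coverage) with standard errors
#' `se_i` under the random-effects model `y_i ~ N(mu, se_i^2 + tau^2)`.
#' Fixed-effect weights `w_i = 1/se_i^2` give Cochran's
#' `Q = sum w_i (y_i - ybar_w)^2`; the moment estimator is
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random
#' weights `1/(se_i^2 + tau^2)` give the pooled mean and its SE;
#' `I^2 = max(0, (Q - (k-1))/Q) * 100`. A single estimate passes through
#' with `tau^2 = 0`. The pooled proportion and its confidence bounds are
#' the inverse logit of `mu +/- z * SE`.
#'
#' @param y numeric estimates on the logit scale.
#' @param se positive standard errors, same length.
#' @param conf_level confidence level for the pooled interval.
#' @return A list: `k, pooled_logit, se_pooled, pooled_proportion,
#'   ci_lower, ci_upper, tau2, Q, I2`.
#' @examples
#' dl_random_effects(c(-1.2, -0.8, -1.5), c(0.2, 0.25, 0.3))
#' @export
dl_random_effects <- function(y, se, conf_level = 0.95) {
  k <- length(y)
  if (k == 0L) stop("empty group: nothing to pool", call. = FALSE)
  if (length(se) != k) stop("y and se lengths differ", call. = FALSE)
  if (any(se <= 0))
    stop("all standard errors must be positive (degenerate weight)",
         call. = FALSE)
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  if (k == 1L) {
    tau2 <- 0
    mu <- y
    se_mu <- se
    I2 <- 0
    Q <- 0
  } else {
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    mu <- sum(ws * y) / sum(ws)
    se_mu <- sqrt(1 / sum(ws))
    I2 <- max(0, (Q - (k - 1)) / Q) * 100
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(k = k, pooled_logit = mu, se_pooled = se_mu,
       pooled_proportion = inv_logit(mu),
       ci_lower = inv_logit(mu - z * se_mu),
       ci_upper = inv_logit(mu + z * se_mu),
       tau2 = tau2, Q = Q, I2 = I2)
}

#' Pool included estimates by grouping
#'
#' Runs [dl_random_effects()] within each level of a grouping variable
#' (income group, WHO region, GBD region or super-region), per disorder,
#' plus an `all` row pooling every included country. Excluded estimates
#' never enter.
#'
#' @param estimates data.frame of country estimates with columns
#'   `disorder`, `logit_c`, `se_logit`, `included` and the grouping
#'   columns.
#' @param groupings character vector among `"income_group"`,
#'   `"who_region"`, `"gbd_region"`, `"gbd_super_region"`, `"all"`.
#' @param conf_level confidence level.
#' @return A data.frame, one row per disorder x grouping x group level:
#'   `disorder, grouping, group_label, k, pooled_coverage, ci_lower,
#'   ci_upper, tau2, Q, I2`.
#' @export
aggregate_groups <- function(estimates,
                             groupings = c("income_group", "who_region",
                                           "gbd_super_region", "all"),
                             conf_level = 0.95) {
  allowed <- c("income_group", "who_region", "gbd_region",
               "gbd_super_region", "all")
  bad <- setdiff(groupings, allowed)
  if (length(bad))
    stop("unknown grouping(s): ", paste(bad, collapse = ", "), call. = FALSE)
  est <- estimates[estimates$included, , drop = FALSE]
  rows <- list()
  for (d in unique(est$disorder)) {
    ed <- est[est$disorder == d, , drop = FALSE]
    for (g in groupings) {
      labels <- if (g == "all") rep("all", nrow(ed)) else ed[[g]]
      if (anyNA(labels))
        stop("missing ", g, " for country ",
             paste(ed$country_code[is.na(labels)], collapse = ", "),
             call. = FALSE)
      for (lv in unique(labels)) {
        sub <- ed[labels == lv, , drop = FALSE]
        fit <- dl_random_effects(sub$logit_c, sub$se_logit, conf_level)
        rows[[length(rows) + 1L]] <- data.frame(
          disorder = d, grouping = g, group_label = lv, k = fit$k,
          pooled_coverage = fit$pooled_proportion,
          ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
          tau2 = fit$tau2, Q = fit$Q, I2 = fit$I2,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows) %||% data.frame()
}

#' Baujat influence coordinates
#'
#' For each study: `x_i`, its contribution to overall heterogeneity
#' (`w_i (y_i - ybar)^2` with fixed-effect weights), and `y_i`, its
#' influence on the pooled estimate (the squared standardised change in
#' the fixed-effect pooled value when the study is removed). Outlying
#' studies sit in the upper right. Coordinates only; inspection and any
#' retention decision are left to the analyst.
#'
#' @param y,se estimates and standard errors (logit scale), `k >= 2`.
#' @param labels optional study labels (e.g. country codes).
#' @return A data.frame with `label`, `x`, `y`.
#' @export
baujat_coordinates <- function(y, se, labels = seq_along(y)) {
  k <- length(y)
  if (k < 2L)
    stop("Baujat diagnostics need at least two studies", call. = FALSE)
  w <- 1 / se^2
  pooled <- sum(w * y) / sum(w)
  x <- w * (y - pooled)^2
  infl <- vapply(seq_len(k), function(i) {
    wi <- w[-i]
    pooled_i <- sum(wi * y[-i]) / sum(wi)
    (pooled - pooled_i)^2 / (1 / sum(wi))
  }, numeric(1))
  data.frame(label = labels, x = x, y = infl, stringsAsFactors = FALSE)
}
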