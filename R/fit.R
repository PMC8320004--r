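#' Estimate contact coverage from service-utilisation reports
#'
#' The package's main fitting function. For every country x disorder
#' record it:
#'
#' 1. applies the completeness screen (both settings and
#'    representativeness reported) and the visits-per-case validity
#'    screen;
#' 2. resolves the population denominator (reported vs UN figure);
#' 3. de-duplicates treated cases across inpatient and outpatient settings
#'    using the follow-up category (regional-median imputed when missing);
#' 4. adjusts the prevalence input to the service case definition
#'    (schizophrenia to non-affective psychosis; depression point
#'    all-severity to 12-month moderate-severe) and forms expected cases
#'    in the covered population;
#' 5. computes coverage = treated / expected with delta-method standard
#'    errors, logit-transforms, and applies plausibility thresholds;
#' 6. pools included countries by income group and region with
#'    DerSimonian-Laird random effects and computes Baujat influence
#'    coordinates per group.
#'
#' @param atlas service-utilisation records ([read_atlas_table()] layout).
#' @param context country context table ([read_country_context()]).
#' @param prevalence prevalence inputs ([read_prevalence_table()]); one
#'   row must exist for every record that survives the screens.
#' @param constants an [adjustment_constants()] object.
#' @param thresholds a threshold table ([read_thresholds()]), or `NULL`
#'   for no plausibility filtering. Default [default_thresholds()].
#' @param divergence_limit relative reported-vs-UN population difference
#'   above which the UN figure is used. Default 0.30.
#' @param visits_per_case_min visits-per-case exclusion bound. Default 1.
#' @param groupings grouping schemes to pool by.
#' @param conf_level confidence level for all intervals. Default 0.95.
#' @return An object of class `coverage_fit`: a list with `estimates`
#'   (per-record data.frame, included and excluded rows alike),
#'   `exclusions` (the exclusion ledger: country, disorder, stage,
#'   reason), `pooled` ([aggregate_groups()] output), `baujat` (influence
#'   coordinates per disorder x grouping x group) and the configuration
#'   used.
#' @examples
#' sim <- simulate_atlas_cohort(n_countries = 40, seed = 7,
#'                              quality_probs = c(1, 0, 0))
#' fit <- fit_contact_coverage(sim$atlas, sim$context, sim$prevalence)
#' fit
#' @export
fit_contact_coverage <- function(atlas, context, prevalence,
                                 constants = adjustment_constants(),
                                 thresholds = default_thresholds(),
                                 divergence_limit = 0.30,
                                 visits_per_case_min = 1,
                                 groupings = c("income_group", "who_region",
                                               "gbd_super_region", "all"),
                                 conf_level = 0.95) {
  atlas <- validate_atlas_records(atlas)
  n <- nrow(atlas)
  est <- atlas[c("country_code", "disorder")]
  ctx_idx <- match(atlas$country_code, context$country_code)
  if (anyNA(ctx_idx))
    stop("no context row for country: ",
         paste(unique(atlas$country_code[is.na(ctx_idx)]), collapse = ", "),
         call. = FALSE)
  est$income_group <- context$income_group[ctx_idx]
  est$who_region <- context$who_region[ctx_idx]
  est$gbd_region <- context$gbd_region[ctx_idx]
  est$gbd_super_region <- context$gbd_super_region[ctx_idx]

  ## stage 1: completeness
  s1 <- screen_completeness(atlas)
  est$included <- s1$included
  est$exclusion_reason <- s1$reason
  est$stage <- ifelse(s1$included, NA_character_, "completeness")

  ## stage 2: visits per case (only records still standing)
  alive <- est$included
  if (any(alive)) {
    s2 <- visits_per_case_check(atlas[alive, , drop = FALSE],
                                min_ratio = visits_per_case_min)
    est$included[alive] <- s2$included
    est$exclusion_reason[alive] <- s2$reason
    est$stage[alive] <- ifelse(s2$included, NA_character_, "visits_per_case")
  }

  ## population, treated cases, expected cases, coverage for survivors
  num_cols <- c("population", "effective_population", "unique_cases",
                "midpoint_used", "expected_cases", "coverage", "se",
                "logit_c", "se_logit", "ci_lower", "ci_upper")
  for (col in num_cols) est[[col]] <- NA_real_
  est$prioritisation <- NA_character_
  est$midpoint_imputed <- NA
  est$negative_fallback_used <- NA
  est$capped <- NA

  alive <- which(est$included)
  if (length(alive)) {
    sub <- atlas[alive, , drop = FALSE]
    pop <- resolve_population(sub, context, divergence_limit)
    est$population[alive] <- as.numeric(pop)

    ## follow-up midpoints: imputation pools every surviving record in the
    ## GBD region (follow-up is a property of the country's system)
    mid_rep <- followup_midpoint(sub$followup_category)
    mid <- impute_followup(est$gbd_region[alive], mid_rep)
    tc <- unique_treated_cases(sub$inpatient_cases, sub$outpatient_cases,
                               as.numeric(mid))
    est$unique_cases[alive] <- tc$unique_cases
    est$prioritisation[alive] <- tc$prioritisation
    est$midpoint_used[alive] <- tc$midpoint_used
    est$midpoint_imputed[alive] <- attr(mid, "imputed")
    est$negative_fallback_used[alive] <- tc$negative_fallback_used

    prev_idx <- match(paste(sub$country_code, sub$disorder),
                      paste(prevalence$country_code, prevalence$disorder))
    if (anyNA(prev_idx))
      stop("no prevalence input for: ",
           paste(unique(paste(sub$country_code, sub$disorder)[is.na(prev_idx)]),
                 collapse = ", "), call. = FALSE)

    for (j in seq_along(alive)) {
      i <- alive[j]
      prow <- adjust_prevalence(as.list(prevalence[prev_idx[j], ]), constants)
      exp_c <- expected_case_count(prow, est$population[i],
                                   sub$representativeness[j])
      est$effective_population[i] <- exp_c$effective_population
      est$expected_cases[i] <- exp_c$count
      tp <- treated_prevalence(est$unique_cases[i],
                               exp_c$effective_population)
      p_g <- exp_c$count / exp_c$effective_population
      se_g <- exp_c$se / exp_c$effective_population
      cr <- suppressWarnings(coverage_ratio(tp$p_t, tp$se_t, p_g, se_g))
      lg <- logit_with_delta(cr$c, cr$se_c, n = exp_c$effective_population)
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      est$coverage[i] <- cr$c
      est$se[i] <- cr$se_c
      est$capped[i] <- cr$capped
      est$logit_c[i] <- lg$logit_c
      est$se_logit[i] <- lg$se_logit
      est$ci_lower[i] <- inv_logit(lg$logit_c - z * lg$se_logit)
      est$ci_upper[i] <- inv_logit(lg$logit_c + z * lg$se_logit)
    }
    if (any(est$capped[alive]))
      warning(sum(est$capped[alive]),
              " coverage ratio(s) above 1 capped at 0.999", call. = FALSE)

    ## stage 3: plausibility thresholds
    s3 <- apply_thresholds(est$coverage[alive], est$disorder[alive],
                           est$income_group[alive], thresholds)
    est$included[alive] <- s3$included
    est$exclusion_reason[alive] <- s3$reason
    est$stage[alive] <- ifelse(s3$included, NA_character_, "threshold")
  }

  exclusions <- est[!est$included,
                    c("country_code", "disorder", "stage", "exclusion_reason")]
  names(exclusions)[4] <- "reason"
  rownames(exclusions) <- NULL

  pooled <- aggregate_groups(est, groupings, conf_level)
  baujat <- baujat_by_group(est, groupings)

  structure(list(estimates = est, exclusions = exclusions, pooled = pooled,
                 baujat = baujat, constants = constants,
                 thresholds = thresholds, groupings = groupings,
                 conf_level = conf_level, call = match.call()),
            class = "coverage_fit")
}

baujat_by_group <- function(est, groupings) {
  inc <- est[est$included, , drop = FALSE]
  rows <- list()
  for (d in unique(inc$disorder)) {
    ed <- inc[inc$disorder == d, , drop = FALSE]
    for (g in groupings) {
      labels <- if (g == "all") rep("all", nrow(ed)) else ed[[g]]
      for (lv in unique(labels)) {
        sub <- ed[labels == lv, , drop = FALSE]
        if (nrow(sub) < 2L) next
        bj <- baujat_coordinates(sub$logit_c, sub$se_logit,
                                 sub$country_code)
        rows[[length(rows) + 1L]] <- data.frame(
          disorder = d, grouping = g, group_label = lv,
          country_code = bj$label, x = bj$x, y = bj$y,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows) %||%
    data.frame(disorder = character(), grouping = character(),
               group_label = character(), country_code = character(),
               x = numeric(), y = numeric())
}

#' @export
print.coverage_fit <- function(x, ...) {
  est <- x$estimates
  cat("Contact coverage fit\n")
  cat(sprintf("  records: %d  included: %d  excluded: %d\n",
              nrow(est), sum(est$included), sum(!est$included)))
  tab <- table(x$exclusions$reason)
  if (length(tab))
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  ov <- x$pooled[x$pooled$grouping == "all", , drop = FALSE]
  if (nrow(ov)) {
    cat("  pooled coverage (all countries):\n")
    for (i in seq_len(nrow(ov)))
      cat(sprintf("    %-10s %5.1f%% (%.1f-%.1f)  k=%d  I2=%.0f%%\n",
                  ov$disorder[i], 100 * ov$pooled_coverage[i],
                  100 * ov$ci_lower[i], 100 * ov$ci_upper[i],
                  ov$k[i], ov$I2[i]))
  }
  invisible(x)
}

#' @export
summary.coverage_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.coverage_fit")
}

#' @export
print.summary.coverage_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPooled estimates by group:\n")
  p <- x$fit$pooled
  p$pooled_coverage <- round(100 * p$pooled_coverage, 1)
  p$ci_lower <- round(100 * p$ci_lower, 1)
  p$ci_upper <- round(100 * p$ci_upper, 1)
  p$tau2 <- signif(p$tau2, 3)
  p$Q <- signif(p$Q, 3)
  p$I2 <- round(p$I2, 1)
  print(p, row.names = FALSE)
  invisible(x)
}

#' Pooled coverage proportions from a fit
#'
#' @param object a `coverage_fit`.
#' @param grouping which grouping scheme to extract. Default `"all"`.
#' @param ... unused.
#' @return Named numeric vector of pooled coverage proportions
#'   (`disorder:group`).
#' @export
coef.coverage_fit <- function(object, grouping = "all", ...) {
  p <- object$pooled[object$pooled$grouping == grouping, , drop = FALSE]
  stats::setNames(p$pooled_coverage,
                  paste(p$disorder, p$group_label, sep = ":"))
}

#' Baujat plot of a pooled group
#'
#' Scatters each included country's contribution to heterogeneity (x)
#' against its influence on the pooled estimate (y); outliers sit top
#' right.
#'
#' @param x a `coverage_fit`.
#' @param disorder,grouping,group_label which pooled group to plot;
#'   defaults to all countries for the first fitted disorder.
#' @param ... passed to [graphics::plot()].
#' @export
plot.coverage_fit <- function(x, disorder = NULL, grouping = "all",
                              group_label = "all", ...) {
  bj <- x$baujat
  disorder <- disorder %||% bj$disorder[1]
  sel <- bj$disorder == disorder & bj$grouping == grouping &
    bj$group_label == group_label
  bj <- bj[sel, , drop = FALSE]
  if (!nrow(bj))
    stop("no Baujat coordinates for that group (need >= 2 countries)",
         call. = FALSE)
  graphics::plot(bj$x, bj$y,
                 xlab = "Contribution to heterogeneity (Q)",
                 ylab = "Influence on pooled estimate",
                 main = sprintf("Baujat diagnostics: %s (%s = %s)",
                                disorder, grouping, group_label), ...)
  graphics::text(bj$x, bj$y, labels = bj$country_code, pos = 3, cex = 0.7)
  invisible(bj)
}
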