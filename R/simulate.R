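## Synthetic Atlas-like cohorts with known ground truth.
##
## The generator emulates the *structure* of country-reported
## service-utilisation data, not the 2017 country distribution: per
## country and disorder it draws a true prevalence, a true coverage (by
## income group, with between-country spread on the logit scale), a true
## inpatient follow-up fraction, and then lets a registry "report" what it
## would see -- case tallies per setting with binomial inpatient/outpatient
## overlap, visit counts, a binned follow-up category, and configurable
## corruption (incomplete reports; visits mistaken for cases).

## Default true mean coverage by income group, per disorder. These mirror
## the pooled group-level coverage a large Atlas-style exercise reports:
## psychosis highest and strongly income-graded, bipolar low throughout,
## moderate-severe depression low with a steep income gradient.
default_true_coverage <- function() {
  list(psychosis  = c(low = 0.109, lower_middle = 0.215,
                      upper_middle = 0.292, high = 0.595),
       bipolar    = c(low = 0.031, lower_middle = 0.035,
                      upper_middle = 0.031, high = 0.104),
       depression = c(low = 0.029, lower_middle = 0.043,
                      upper_middle = 0.130, high = 0.311))
}

## True 12-month prevalence means on the *service case definition* scale
## (non-affective psychosis; bipolar disorder; moderate-severe
## depression).
default_true_prevalence <- function() {
  c(psychosis = 0.005, bipolar = 0.006, depression = 0.012)
}

## Bins: <=25%, 26-50%, 51-75%, >75% (right-closed, so 0.25 is bin 1).
followup_category_of <- function(f) {
  as.integer(cut(f, breaks = c(-Inf, 0.25, 0.50, 0.75, Inf)))
}

#' Patient-level simulator of inpatient/outpatient overlap
#'
#' Instantiates `n_treated` treated individuals, assigns a share of them
#' to inpatient care, and lets each inpatient independently receive an
#' outpatient follow-up with probability `followup_fraction`. Returns the
#' tallies a registry without a unique patient identifier would report —
#' every person appearing in a setting counts there — together with the
#' exact number of unique persons. This is the oracle against which the
#' formula-based de-duplication is checked.
#'
#' @param n_treated number of unique treated persons.
#' @param inpatient_share fraction of treated persons seen as inpatients.
#' @param followup_fraction probability an inpatient also appears in the
#'   outpatient tally.
#' @return A list with `unique_persons`, `inpatient`, `outpatient`.
#' @export
simulate_patient_level <- function(n_treated, inpatient_share,
                                   followup_fraction) {
  stopifnot(n_treated >= 0, inpatient_share >= 0, inpatient_share <= 1,
            followup_fraction >= 0, followup_fraction <= 1)
  n_in <- round(n_treated * inpatient_share)
  n_out_only <- n_treated - n_in
  followed <- if (n_in > 0)
    sum(stats::runif(n_in) < followup_fraction) else 0L
  list(unique_persons = n_treated,
       inpatient = n_in,
       outpatient = n_out_only + followed)
}

#' Generate a synthetic Atlas-style cohort with known truth
#'
#' Draws `n_countries` countries with income groups and regions, true
#' prevalence (log-normal spread around disorder means), true coverage
#' (normal spread on the logit scale around income-group means) and a true
#' follow-up fraction, then simulates what each country's health
#' information system would report. Reporting quality per country is
#' `cases` (clean), `visits_mistaken_as_cases` (visit counts land in the
#' cases columns, inflating coverage far past any plausible bound) or
#' `incomplete` (a required field is dropped). Clean reporters' per-case
#' visit rates are at least 1, so the visits-per-case screen can only fire
#' on data that deserve it.
#'
#' @param n_countries number of countries. Default 177 (a full reporting
#'   round).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param disorders subset of `c("psychosis", "bipolar", "depression")`.
#' @param quality_probs probabilities of reporting quality
#'   `c(cases, visits_mistaken_as_cases, incomplete)`. The default
#'   `c(0.28, 0.12, 0.60)` reproduces the attrition of a real reporting
#'   round, where most countries cannot report completely.
#' @param coverage_logit_sd between-country SD of true coverage on the
#'   logit scale. Default 0.8 (substantial cross-country heterogeneity).
#' @param prevalence_log_sd log-scale SD of true prevalence around the
#'   disorder mean. Default 0.2.
#' @param prevalence_rel_se relative half-width/1.96 of the prevalence
#'   interval handed to the pipeline. Default 0.10.
#' @param true_coverage named list per disorder of income-group mean
#'   coverages; defaults to the package's study conditions.
#' @param true_prevalence named vector of disorder mean prevalences.
#' @param inpatient_share_range range of the inpatient share of treated
#'   persons for outpatient-oriented countries. Default `c(0.05, 0.45)`.
#' @param inpatient_heavy_prob probability a country is inpatient-heavy
#'   (share drawn from `c(0.55, 0.85)`), exercising the unadjusted branch.
#'   Default 0.1.
#' @param followup_missing_prob probability the follow-up category is not
#'   reported (exercising regional-median imputation). Default 0.1.
#' @param constants [adjustment_constants()] used to emit prevalence
#'   inputs on the scale the pipeline expects (schizophrenia scale for
#'   psychosis; all-severity point scale for depression), so the
#'   pipeline's adjustments recover the truth exactly.
#' @param dir optional directory; when given, the four CSVs
#'   (`atlas_records.csv`, `country_context.csv`, `prevalence.csv`,
#'   `truth.csv`) are written there.
#' @return A list of four data.frames: `atlas`, `context`, `prevalence`,
#'   `truth`. Truth is emitted alongside the data and never leaks into the
#'   pipeline inputs.
#' @export
simulate_atlas_cohort <- function(n_countries = 177, seed = 1,
                                  disorders = DISORDERS,
                                  quality_probs = c(cases = 0.28,
                                                    visits_mistaken_as_cases = 0.12,
                                                    incomplete = 0.60),
                                  coverage_logit_sd = 0.8,
                                  prevalence_log_sd = 0.2,
                                  prevalence_rel_se = 0.10,
                                  true_coverage = default_true_coverage(),
                                  true_prevalence = default_true_prevalence(),
                                  inpatient_share_range = c(0.05, 0.45),
                                  inpatient_heavy_prob = 0.1,
                                  followup_missing_prob = 0.1,
                                  constants = adjustment_constants(),
                                  dir = NULL) {
  stopifnot(n_countries >= 1, all(disorders %in% DISORDERS),
            length(quality_probs) == 3, all(quality_probs >= 0),
            coverage_logit_sd >= 0, prevalence_log_sd >= 0,
            prevalence_rel_se > 0,
            diff(inpatient_share_range) >= 0,
            inpatient_share_range[1] >= 0, inpatient_share_range[2] <= 0.45)
  set.seed(seed)
  qp <- quality_probs / sum(quality_probs)
  names(qp) <- c("cases", "visits_mistaken_as_cases", "incomplete")

  iso <- sprintf("C%02d%s", seq_len(n_countries),
                 LETTERS[(seq_len(n_countries) - 1L) %% 26L + 1L])
  income <- sample(INCOME_GROUPS, n_countries, replace = TRUE)
  who <- sample(WHO_REGIONS, n_countries, replace = TRUE)
  super <- sample(paste0("SR", 1:7), n_countries, replace = TRUE)
  region <- paste0(super, "_", sample(1:2, n_countries, replace = TRUE))
  un_pop <- round(exp(stats::runif(n_countries, log(1e6), log(1e8))))
  ## reported population: mostly close to UN, some missing, some divergent
  pop_noise <- stats::runif(n_countries, 0.95, 1.05)
  reported_pop <- round(un_pop * pop_noise)
  reported_pop[stats::runif(n_countries) < 0.05] <- NA
  far <- stats::runif(n_countries) < 0.05
  reported_pop[far] <- round(un_pop[far] * 2.5)

  followup_true <- stats::runif(n_countries)
  quality <- sample(names(qp), n_countries, replace = TRUE, prob = qp)
  heavy <- stats::runif(n_countries) < inpatient_heavy_prob
  share <- ifelse(heavy,
                  stats::runif(n_countries, 0.55, 0.85),
                  stats::runif(n_countries, inpatient_share_range[1],
                               inpatient_share_range[2]))
  repr <- stats::runif(n_countries, 0.5, 1)

  atlas <- list(); prevalence <- list(); truth <- list()
  split_mult <- constants$depression_point_to_12m_factor *
    (constants$depression_moderate_prop + constants$depression_severe_prop)

  for (i in seq_len(n_countries)) {
    ## covered population matches what the pipeline will resolve:
    ## the reported figure when present and close to the UN one, else UN
    n_base <- if (is.na(reported_pop[i]) || far[i]) un_pop[i]
              else reported_pop[i]
    n_cov <- round(n_base * repr[i])
    for (d in disorders) {
      p_true <- true_prevalence[[d]] *
        exp(stats::rnorm(1, 0, prevalence_log_sd))
      mu <- stats::qlogis(true_coverage[[d]][[income[i]]])
      c_true <- stats::plogis(stats::rnorm(1, mu, coverage_logit_sd))
      cases_cov <- stats::rbinom(1, n_cov, p_true)
      n_treated <- stats::rbinom(1, cases_cov, c_true)
      pl <- simulate_patient_level(n_treated, share[i], followup_true[i])
      visit_rate <- 1 + stats::rgamma(1, shape = 2, scale = 3)

      in_cases <- pl$inpatient; out_cases <- pl$outpatient
      in_visits <- round(in_cases * visit_rate)
      out_visits <- round(out_cases * visit_rate)
      q <- quality[i]
      if (q == "visits_mistaken_as_cases") {
        ## visit volumes land in the cases columns; the rate is scaled so
        ## the implied coverage provably exceeds 1 and hits the cap
        rate_corrupt <- max(10, 2.2 / c_true)
        in_cases <- round(pl$inpatient * rate_corrupt)
        out_cases <- round(pl$outpatient * rate_corrupt)
        in_visits <- in_cases
        out_visits <- out_cases
      }
      fu_cat <- followup_category_of(followup_true[i])
      rec <- data.frame(
        country_code = iso[i], disorder = d,
        inpatient_cases = in_cases, outpatient_cases = out_cases,
        inpatient_visits = in_visits, outpatient_visits = out_visits,
        representativeness = repr[i],
        followup_category = if (stats::runif(1) < followup_missing_prob)
          NA_integer_ else fu_cat,
        reported_population = reported_pop[i],
        stringsAsFactors = FALSE)
      if (q == "incomplete") {
        drop <- sample(c("inpatient_cases", "outpatient_cases",
                         "representativeness"), 1)
        rec[[drop]] <- NA
      }
      atlas[[length(atlas) + 1L]] <- rec

      ## prevalence input on the scale the pipeline adjusts from
      input_rate <- switch(d,
        psychosis = p_true * constants$schiz_to_psychosis_ratio,
        depression = p_true / split_mult,
        bipolar = p_true)
      half <- Z975 * prevalence_rel_se * input_rate
      prevalence[[length(prevalence) + 1L]] <- data.frame(
        country_code = iso[i], disorder = d, rate = input_rate,
        lower95 = max(input_rate - half, 1e-9),
        upper95 = min(input_rate + half, 1 - 1e-9),
        time_frame = if (d == "bipolar") "twelve_month" else "point",
        stringsAsFactors = FALSE)

      truth[[length(truth) + 1L]] <- data.frame(
        country_code = iso[i], disorder = d,
        true_coverage = c_true, true_prevalence = p_true,
        true_followup_fraction = followup_true[i],
        true_unique_cases = pl$unique_persons,
        population = un_pop[i], income_group = income[i],
        who_region = who[i], gbd_region = region[i],
        gbd_super_region = super[i],
        reporting_quality = q, stringsAsFactors = FALSE)
    }
  }

  out <- list(
    atlas = do.call(rbind, atlas),
    context = data.frame(country_code = iso, income_group = income,
                         who_region = who, gbd_region = region,
                         gbd_super_region = super, un_population = un_pop,
                         stringsAsFactors = FALSE),
    prevalence = do.call(rbind, prevalence),
    truth = do.call(rbind, truth))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$atlas, file.path(dir, "atlas_records.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(out$context, file.path(dir, "country_context.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(out$prevalence, file.path(dir, "prevalence.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(out$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE, na = "")
  }
  out
}
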