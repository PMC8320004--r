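## Conversion of prevalence inputs into expected 12-month prevalent case
## counts in the covered population, with propagated uncertainty.

#' Standard error from a 95% interval
#'
#' Reconstructs a standard error from a central 95% normal interval:
#' `(upper - lower) / (2 * 1.959964)`.
#'
#' @param lower95,upper95 interval bounds, `lower95 <= upper95`.
#' @return Numeric standard error(s), vectorised.
#' @examples
#' se_from_interval(0.008, 0.012)
#' @export
se_from_interval <- function(lower95, upper95) {
  if (any(lower95 > upper95))
    stop("lower95 must not exceed upper95", call. = FALSE)
  (upper95 - lower95) / (2 * Z975)
}

## Relative SE of the combined moderate+severe split, reconstructed from
## the split intervals and combined in quadrature. Isolated so the
## uncertainty-combination rule can be swapped out in one place.
split_relative_se <- function(consts) {
  se_mod <- se_from_interval(consts$depression_moderate_ci[1],
                             consts$depression_moderate_ci[2])
  se_sev <- se_from_interval(consts$depression_severe_ci[1],
                             consts$depression_severe_ci[2])
  total <- consts$depression_moderate_prop + consts$depression_severe_prop
  sqrt(se_mod^2 + se_sev^2) / total
}

#' Adjust depression prevalence to 12-month moderate-severe prevalence
#'
#' Point prevalence of depression (all severities) is converted to the
#' 12-month prevalence of moderate-severe depression — the case definition
#' under which specialist services treat — by multiplying by the
#' point-to-12-month factor and by the combined moderate + severe severity
#' split. Interval bounds are scaled by the same factor, then widened to
#' reflect the uncertainty of the split itself: the relative standard error
#' of the combined split (reconstructed from its 95% intervals) is added in
#' quadrature to the prevalence's relative standard error.
#'
#' @param prev one-row data.frame (or list) with `rate`, `lower95`,
#'   `upper95`, `time_frame` for a depression record.
#' @param consts an [adjustment_constants()] object.
#' @return The adjusted prevalence row with `time_frame = "twelve_month"`.
#' @export
adjust_depression <- function(prev, consts = adjustment_constants()) {
  fac <- consts$depression_point_to_12m_factor
  if (identical(prev$time_frame, "twelve_month") && fac != 1)
    stop("depression prevalence is already twelve_month; refusing to apply ",
         "the point-to-12-month factor twice", call. = FALSE)
  split <- consts$depression_moderate_prop + consts$depression_severe_prop
  mult <- fac * split
  rate <- prev$rate * mult
  se_prev <- se_from_interval(prev$lower95, prev$upper95)
  rel <- if (prev$rate > 0) se_prev / prev$rate else 0
  rel_out <- sqrt(rel^2 + split_relative_se(consts)^2)
  se_out <- rate * rel_out
  list(rate = rate,
       lower95 = max(rate - Z975 * se_out, .Machine$double.xmin),
       upper95 = min(rate + Z975 * se_out, 1 - 1e-12),
       time_frame = "twelve_month")
}

#' Adjust schizophrenia prevalence to non-affective psychosis prevalence
#'
#' Schizophrenia (ICD-10 F20) is a subset of non-affective psychosis
#' (F20–29); its prevalence is divided by the ratio of the two (default
#' 0.49) to recover the broader definition services report against. Bounds
#' scale by the same factor; the time frame is unchanged (point prevalence
#' of psychosis is accepted as a 12-month proxy, the two not differing
#' detectably for this chronic condition).
#'
#' @param prev one-row data.frame (or list) with `rate`, `lower95`,
#'   `upper95`, `time_frame` for a psychosis record on the schizophrenia
#'   scale.
#' @param consts an [adjustment_constants()] object.
#' @return The adjusted prevalence row.
#' @export
adjust_psychosis <- function(prev, consts = adjustment_constants()) {
  ratio <- consts$schiz_to_psychosis_ratio
  if (ratio <= 0) stop("schiz_to_psychosis_ratio must be positive",
                       call. = FALSE)
  rate <- prev$rate / ratio
  if (rate >= 1)
    stop("adjusted psychosis prevalence reaches ", signif(rate, 4),
         "; prevalence must remain below 1", call. = FALSE)
  list(rate = rate, lower95 = prev$lower95 / ratio,
       upper95 = prev$upper95 / ratio, time_frame = prev$time_frame)
}

#' Adjust a prevalence row for one disorder
#'
#' Dispatch wrapper: depression rows go through [adjust_depression()],
#' psychosis rows through [adjust_psychosis()], bipolar rows (already
#' 12-month under a matching definition) pass through unchanged.
#'
#' @param prev one-row prevalence record with a `disorder` field.
#' @param consts an [adjustment_constants()] object.
#' @return Adjusted prevalence list with `rate`, `lower95`, `upper95`,
#'   `time_frame`.
#' @export
adjust_prevalence <- function(prev, consts = adjustment_constants()) {
  switch(prev$disorder,
         depression = adjust_depression(prev, consts),
         psychosis = adjust_psychosis(prev, consts),
         bipolar = {
           if (!identical(prev$time_frame, "twelve_month"))
             stop("bipolar prevalence input must be twelve_month",
                  call. = FALSE)
           prev[c("rate", "lower95", "upper95", "time_frame")]
         },
         stop("unknown disorder: ", prev$disorder, call. = FALSE))
}

#' Expected prevalent cases in the covered population
#'
#' The coverage denominator: prevalence times the population actually
#' covered by the reporting system (`population * representativeness`).
#' The count's standard error is the prevalence standard error (from the
#' interval) scaled by the same effective population.
#'
#' @param prev adjusted prevalence list (`rate`, `lower95`, `upper95`).
#' @param population resolved population denominator (persons).
#' @param representativeness fraction of the population covered by the
#'   reporting system, in \[0, 1\]; must be present (screened earlier).
#' @return A list with `count`, `se` and `effective_population`.
#' @export
expected_case_count <- function(prev, population, representativeness) {
  if (is.na(representativeness))
    stop("representativeness is missing; records must pass ",
         "screen_completeness() before estimation", call. = FALSE)
  stopifnot(population > 0, representativeness >= 0, representativeness <= 1)
  n_eff <- population * representativeness
  list(count = prev$rate * n_eff,
       se = se_from_interval(prev$lower95, prev$upper95) * n_eff,
       effective_population = n_eff)
}
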