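## Unique treated cases: correcting inpatient/outpatient double counting.
##
## In countries where most care is outpatient, everyone seen as an
## inpatient is assumed to also appear in the outpatient tally; the
## expected overlap (follow-up fraction x inpatient cases) is subtracted
## from the outpatient count. Countries where inpatient care dominates are
## left unadjusted.

#' Classify a country's service prioritisation
#'
#' A record is inpatient-prioritised when more reported cases are treated
#' in inpatient than outpatient facilities, and outpatient-prioritised
#' otherwise. Ties go to outpatient-prioritised, the conservative choice
#' (the de-duplication adjustment applies).
#'
#' @param inpatient_cases,outpatient_cases reported 12-month case counts.
#' @return Character vector, `"inpatient_prioritised"` or
#'   `"outpatient_prioritised"`.
#' @export
classify_prioritisation <- function(inpatient_cases, outpatient_cases) {
  stopifnot(!anyNA(inpatient_cases), !anyNA(outpatient_cases))
  ifelse(inpatient_cases > outpatient_cases,
         "inpatient_prioritised", "outpatient_prioritised")
}

#' Midpoint of a follow-up category
#'
#' The follow-up item bins the share of discharged inpatients who received
#' an outpatient visit within one month: category 1 is 25% or less, 2 is
#' 26–50%, 3 is 51–75% and 4 is more than 75%. Averaging each range gives
#' the fraction used by the de-duplication formula.
#'
#' @param category integer vector with values in 1–4.
#' @return Numeric vector of midpoints: 0.125, 0.38, 0.63, 0.875.
#' @export
followup_midpoint <- function(category) {
  if (any(!is.na(category) & !category %in% 1:4))
    stop("followup category must be in {1,2,3,4}", call. = FALSE)
  c(0.125, 0.38, 0.63, 0.875)[category]
}

#' Impute a follow-up midpoint from regional reporters
#'
#' Countries that did not report a follow-up category receive the median of
#' the reported category midpoints within their GBD region. Regions with no
#' reporter at all fall back to the global median (with a warning). The
#' median operates on the midpoint scale — the scale the formula uses — and
#' an even count of reporters yields the mean of the two middle values.
#'
#' @param region GBD region of each record.
#' @param midpoint reported midpoint of each record (`NA` when the category
#'   was not reported).
#' @return Numeric vector: the reported midpoint where present, the imputed
#'   one otherwise, with a logical attribute `"imputed"`.
#' @export
impute_followup <- function(region, midpoint) {
  if (all(is.na(midpoint)))
    stop("no record anywhere reports a follow-up category; ",
         "supply an explicit midpoint", call. = FALSE)
  global_med <- stats::median(midpoint, na.rm = TRUE)
  region_med <- tapply(midpoint, region, stats::median, na.rm = TRUE)
  fill <- region_med[region]
  if (any(is.na(fill) & is.na(midpoint))) {
    warning("GBD region(s) without any follow-up reporter: ",
            paste(unique(region[is.na(fill) & is.na(midpoint)]),
                  collapse = ", "),
            "; global median used", call. = FALSE)
    fill[is.na(fill)] <- global_med
  }
  out <- ifelse(is.na(midpoint), fill, midpoint)
  attr(out, "imputed") <- is.na(midpoint)
  names(out) <- NULL
  out
}

#' Unique treated cases after the double-counting adjustment
#'
#' For outpatient-prioritised records the adjusted outpatient count is
#' `outpatient - midpoint * inpatient` (the expected number of inpatients
#' reappearing in the outpatient tally is removed) and unique cases are
#' `inpatient + adjusted outpatient`. If the adjustment would drive the
#' outpatient count negative, the original outpatient value is used
#' instead (fallback, flagged). Inpatient-prioritised records are not
#' adjusted: unique cases are the plain sum. Fractional results are kept —
#' downstream quantities are proportions.
#'
#' @param inpatient_cases,outpatient_cases reported case counts.
#' @param midpoint follow-up fraction(s) in \[0, 1\] (reported or imputed).
#' @param prioritisation from [classify_prioritisation()]; recomputed when
#'   omitted.
#' @return A data.frame with `unique_cases`, `prioritisation`,
#'   `midpoint_used` and `negative_fallback_used`.
#' @export
unique_treated_cases <- function(inpatient_cases, outpatient_cases, midpoint,
                                 prioritisation = NULL) {
  stopifnot(all(midpoint >= 0 & midpoint <= 1))
  if (is.null(prioritisation))
    prioritisation <- classify_prioritisation(inpatient_cases,
                                              outpatient_cases)
  adjusted_out <- outpatient_cases - midpoint * inpatient_cases
  outp <- prioritisation == "outpatient_prioritised"
  fallback <- outp & adjusted_out < 0
  unique_cases <- ifelse(outp & !fallback,
                         inpatient_cases + adjusted_out,
                         inpatient_cases + outpatient_cases)
  data.frame(unique_cases = unique_cases,
             prioritisation = prioritisation,
             midpoint_used = midpoint,
             negative_fallback_used = fallback,
             stringsAsFactors = FALSE)
}
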