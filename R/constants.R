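#' Case-definition and severity adjustment constants
#'
#' Bundles the constants used to reconcile prevalence inputs with the case
#' definitions under which services report. Defaults are the values used
#' throughout the package:
#'
#' * `schiz_to_psychosis_ratio = 0.49` — schizophrenia (ICD-10 F20)
#'   prevalence as a fraction of non-affective psychosis (F20–29)
#'   prevalence; psychosis prevalence inputs supplied as schizophrenia
#'   rates are divided by this ratio.
#' * `depression_moderate_prop = 0.17` (95% CI 0.13–0.22) and
#'   `depression_severe_prop = 0.10` (95% CI 0.03–0.20) — severity split of
#'   depression prevalence; only moderate plus severe cases are retained,
#'   since mild depression is rarely treated in specialist services.
#' * `depression_point_to_12m_factor = 1.30` — multiplier converting point
#'   prevalence of depression to 12-month prevalence. NOTE: no published
#'   value of this coefficient is available to this package; 1.30 is a
#'   documented placeholder consistent with the episodic course of
#'   depression, and should be replaced by the user when a value is known.
#'
#' @param schiz_to_psychosis_ratio fraction in (0, 1].
#' @param depression_moderate_prop,depression_severe_prop central estimates
#'   of the severity-split proportions, each in (0, 1).
#' @param depression_moderate_ci,depression_severe_ci length-2 numeric 95%
#'   intervals for the split proportions.
#' @param depression_point_to_12m_factor multiplier `>= 1`.
#' @return An object of class `adjustment_constants` (a named list).
#' @examples
#' adjustment_constants()
#' @export
adjustment_constants <- function(schiz_to_psychosis_ratio = 0.49,
                                 depression_moderate_prop = 0.17,
                                 depression_moderate_ci = c(0.13, 0.22),
                                 depression_severe_prop = 0.10,
                                 depression_severe_ci = c(0.03, 0.20),
                                 depression_point_to_12m_factor = 1.30) {
  if (!is.numeric(schiz_to_psychosis_ratio) || schiz_to_psychosis_ratio <= 0)
    stop("schiz_to_psychosis_ratio must be a positive number", call. = FALSE)
  props <- c(depression_moderate_prop, depression_severe_prop)
  if (any(props <= 0) || any(props >= 1))
    stop("severity-split proportions must lie in (0, 1)", call. = FALSE)
  if (depression_point_to_12m_factor < 1)
    stop("depression_point_to_12m_factor must be >= 1 (point prevalence ",
         "cannot exceed 12-month prevalence)", call. = FALSE)
  for (ci in list(depression_moderate_ci, depression_severe_ci))
    if (length(ci) != 2L || ci[1] > ci[2])
      stop("split CIs must be length-2 with lower <= upper", call. = FALSE)
  structure(list(
    schiz_to_psychosis_ratio = schiz_to_psychosis_ratio,
    depression_moderate_prop = depression_moderate_prop,
    depression_moderate_ci = depression_moderate_ci,
    depression_severe_prop = depression_severe_prop,
    depression_severe_ci = depression_severe_ci,
    depression_point_to_12m_factor = depression_point_to_12m_factor
  ), class = "adjustment_constants")
}

#' @export
print.adjustment_constants <- function(x, ...) {
  cat("Adjustment constants:\n")
  cat(sprintf("  schizophrenia : non-affective psychosis ratio  %.2f\n",
              x$schiz_to_psychosis_ratio))
  cat(sprintf("  depression moderate proportion  %.2f (%.2f-%.2f)\n",
              x$depression_moderate_prop, x$depression_moderate_ci[1],
              x$depression_moderate_ci[2]))
  cat(sprintf("  depression severe proportion    %.2f (%.2f-%.2f)\n",
              x$depression_severe_prop, x$depression_severe_ci[1],
              x$depression_severe_ci[2]))
  cat(sprintf("  depression point -> 12-month factor  %.2f (placeholder, see docs)\n",
              x$depression_point_to_12m_factor))
  invisible(x)
}
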