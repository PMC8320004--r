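## Ingest and validity screens for Atlas-style service-utilisation tables.
## Missing cells are NA throughout -- an empty CSV cell is a missing report,
## never a zero, because zero cases is itself a legitimate report.

ATLAS_COLUMNS <- c("country_code", "disorder", "inpatient_cases",
                   "outpatient_cases", "inpatient_visits", "outpatient_visits",
                   "representativeness", "followup_category",
                   "reported_population")
CONTEXT_COLUMNS <- c("country_code", "income_group", "who_region",
                     "gbd_region", "gbd_super_region", "un_population")
PREVALENCE_COLUMNS <- c("country_code", "disorder", "rate", "lower95",
                        "upper95", "time_frame")

check_header <- function(found, wanted, what) {
  missing <- setdiff(wanted, found)
  if (length(missing))
    stop(sprintf("%s: malformed header, missing column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read a service-utilisation (Atlas-style) table
#'
#' Reads one row per country x disorder with 12-month counts of treated
#' cases and visits in inpatient and outpatient specialist facilities, the
#' fraction of the national population covered by the reporting system
#' (`representativeness`), the inpatient follow-up category (1–4, the share
#' of discharged inpatients seen in outpatient care within a month:
#' <=25%, 26–50%, 51–75%, >75%) and the country-reported population.
#' Empty cells become `NA`.
#'
#' @param path path to a CSV file with columns `country_code, disorder,
#'   inpatient_cases, outpatient_cases, inpatient_visits, outpatient_visits,
#'   representativeness, followup_category, reported_population`.
#' @return A data.frame with those columns, one row per record.
#' @export
read_atlas_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), colClasses = "character")
  check_header(names(df), ATLAS_COLUMNS, "atlas table")
  df <- df[ATLAS_COLUMNS]
  num_cols <- setdiff(ATLAS_COLUMNS, c("country_code", "disorder"))
  for (col in num_cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  validate_atlas_records(df)
}

#' Validate service-utilisation records
#'
#' Checks field-level invariants of a record table: counts are non-negative
#' when present, representativeness lies in \[0, 1\], follow-up category is
#' in 1–4 and the disorder label is known. Errors cite the offending row.
#'
#' @param records data.frame in the [read_atlas_table()] layout.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_atlas_records <- function(records) {
  check_header(names(records), ATLAS_COLUMNS, "atlas table")
  bad_disorder <- !records$disorder %in% DISORDERS
  if (any(bad_disorder))
    stop("unknown disorder in row(s) ",
         paste(which(bad_disorder), collapse = ", "),
         " (expected one of: ", paste(DISORDERS, collapse = ", "), ")",
         call. = FALSE)
  counts <- c("inpatient_cases", "outpatient_cases",
              "inpatient_visits", "outpatient_visits", "reported_population")
  for (col in counts) {
    bad <- !is.na(records[[col]]) & records[[col]] < 0
    if (any(bad))
      stop(sprintf("negative %s in row(s) %s", col,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  r <- records$representativeness
  bad <- !is.na(r) & (r < 0 | r > 1)
  if (any(bad))
    stop("representativeness outside [0, 1] in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  f <- records$followup_category
  bad <- !is.na(f) & !f %in% 1:4
  if (any(bad))
    stop("followup_category outside {1,2,3,4} in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  records
}

#' Read the country context table
#'
#' One row per country: World Bank income group, WHO region, GBD region and
#' super-region, and the UN population estimate used as the fallback
#' denominator.
#'
#' @param path path to a CSV with columns `country_code, income_group,
#'   who_region, gbd_region, gbd_super_region, un_population`.
#' @return A validated data.frame.
#' @export
read_country_context <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  check_header(names(df), CONTEXT_COLUMNS, "country context")
  if (anyDuplicated(df$country_code))
    stop("country context: duplicated country_code", call. = FALSE)
  bad <- !df$income_group %in% INCOME_GROUPS
  if (any(bad))
    stop("unknown income_group in row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$un_population) | df$un_population <= 0))
    stop("un_population must be present and positive for every country",
         call. = FALSE)
  df[CONTEXT_COLUMNS]
}

#' Read the prevalence input table
#'
#' One row per country x disorder: a prevalence proportion with its 95%
#' interval and the time frame it refers to (`point` or `twelve_month`).
#' Psychosis rows are expected on the schizophrenia scale and depression
#' rows on the all-severity scale; [adjust_prevalence()] converts both.
#'
#' @param path path to a CSV with columns `country_code, disorder, rate,
#'   lower95, upper95, time_frame`.
#' @return A validated data.frame.
#' @export
read_prevalence_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  check_header(names(df), PREVALENCE_COLUMNS, "prevalence table")
  bad <- !df$disorder %in% DISORDERS
  if (any(bad))
    stop("unknown disorder in prevalence row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  bad <- !df$time_frame %in% c("point", "twelve_month")
  if (any(bad))
    stop("time_frame must be 'point' or 'twelve_month' (row(s) ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  with(df, {
    bad <- is.na(rate) | is.na(lower95) | is.na(upper95) |
      lower95 > rate | rate > upper95 | lower95 <= 0 | upper95 >= 1
    if (any(bad))
      stop("prevalence rows must satisfy 0 < lower95 <= rate <= upper95 < 1",
           " (row(s) ", paste(which(bad), collapse = ", "), ")",
           call. = FALSE)
  })
  df[PREVALENCE_COLUMNS]
}

#' Completeness screen
#'
#' A record can only contribute a coverage estimate if it reports service
#' utilisation from both inpatient and outpatient facilities and states how
#' representative the reporting system is. Records failing either
#' requirement are excluded before any estimation.
#'
#' @param records data.frame of validated service-utilisation records.
#' @return A data.frame with logical `included` and character `reason`
#'   (`"ok"`, `"missing_inpatient_or_outpatient"` or
#'   `"missing_representativeness"`), one row per record.
#' @export
screen_completeness <- function(records) {
  miss_cases <- is.na(records$inpatient_cases) | is.na(records$outpatient_cases)
  miss_repr <- is.na(records$representativeness)
  reason <- ifelse(miss_cases, "missing_inpatient_or_outpatient",
                   ifelse(miss_repr, "missing_representativeness", "ok"))
  data.frame(included = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

#' Visits-per-case validity screen
#'
#' Health information systems sometimes record visits where cases were
#' requested. A report in which the number of visits per treated case falls
#' below one is internally inconsistent (every case implies at least one
#' visit) and is excluded. The ratio pools inpatient and outpatient totals.
#' Records that report no visit counts at all cannot be checked and pass
#' with a warning; a report of visits against zero cases is likewise
#' inconsistent and is excluded.
#'
#' @param records data.frame of records that passed [screen_completeness()].
#' @param min_ratio exclusion bound; reports with strictly fewer visits per
#'   case are dropped. Default 1.
#' @return A data.frame with `included` and `reason`
#'   (`"visits_per_case_below_one"` when the screen fires).
#' @export
visits_per_case_check <- function(records, min_ratio = 1) {
  visits <- rowSums(cbind(records$inpatient_visits,
                          records$outpatient_visits), na.rm = TRUE)
  no_visits <- is.na(records$inpatient_visits) &
    is.na(records$outpatient_visits)
  cases <- records$inpatient_cases + records$outpatient_cases
  ratio <- visits / cases
  excluded <- !no_visits & (cases == 0 | ratio < min_ratio)
  if (any(no_visits))
    warning(sum(no_visits), " record(s) report no visit counts; ",
            "visits-per-case check skipped for them", call. = FALSE)
  reason <- ifelse(excluded, "visits_per_case_below_one", "ok")
  data.frame(included = !excluded, reason = reason, stringsAsFactors = FALSE)
}

#' Resolve the population denominator
#'
#' Uses the country-reported population when it is present and within
#' `divergence_limit` (relative difference) of the UN estimate; otherwise
#' falls back to the UN estimate. Substitutions are reported via `message()`.
#'
#' @param records data.frame of service-utilisation records.
#' @param context country context table ([read_country_context()]).
#' @param divergence_limit maximum tolerated relative difference between
#'   reported and UN population before the UN figure is substituted.
#'   Default 0.30.
#' @return Numeric vector of resolved populations (one per record), with a
#'   logical attribute `"substituted"` marking rows where the UN estimate
#'   was used.
#' @export
resolve_population <- function(records, context, divergence_limit = 0.30) {
  idx <- match(records$country_code, context$country_code)
  if (anyNA(idx))
    stop("no context row for country: ",
         paste(unique(records$country_code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  un <- context$un_population[idx]
  reported <- records$reported_population
  diverged <- !is.na(reported) & abs(reported - un) / un > divergence_limit
  use_un <- is.na(reported) | diverged
  if (any(use_un))
    message("UN population substituted for ", sum(use_un), " record(s) (",
            sum(diverged), " divergent, ", sum(is.na(reported)), " missing)")
  out <- ifelse(use_un, un, reported)
  stopifnot(all(out > 0))
  attr(out, "substituted") <- use_un
  out
}
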