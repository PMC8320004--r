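## Per-country coverage: treated prevalence over expected prevalence, with
## delta-method standard errors carried through the ratio and the logit.

#' Treated prevalence and its standard error
#'
#' The proportion of the covered population in contact with services, with
#' a binomial standard error: `sqrt(p * (1 - p) / n)`.
#'
#' @param unique_cases unique treated persons (after de-duplication).
#' @param effective_population covered population (persons), `> 0`.
#' @return A list with `p_t` and `se_t` (vectorised).
#' @export
treated_prevalence <- function(unique_cases, effective_population) {
  stopifnot(all(effective_population > 0))
  if (any(unique_cases > effective_population))
    stop("unique treated cases exceed the covered population; ",
         "coverage cannot exceed the census", call. = FALSE)
  p <- unique_cases / effective_population
  list(p_t = p, se_t = sqrt(p * (1 - p) / effective_population))
}

#' Coverage as a ratio of two proportions, with delta-method SE
#'
#' Coverage `c = p_t / p_g` (treated prevalence over expected prevalence)
#' with the independent-ratio delta method:
#' `se_c = c * sqrt((se_t/p_t)^2 + (se_g/p_g)^2)`. A zero numerator gives
#' `c = 0` with the numerator term only; ratios above 1 (treated exceeding
#' expected, a symptom of visits reported as cases) are capped at 0.999
#' with a warning — the plausibility thresholds, not the cap, decide
#' exclusion.
#'
#' @param p_t,se_t treated prevalence and SE.
#' @param p_g,se_g expected (disorder) prevalence and SE; `p_g > 0`.
#' @return A list with `c`, `se_c` and logical `capped` (vectorised).
#' @export
coverage_ratio <- function(p_t, se_t, p_g, se_g) {
  if (any(p_g <= 0))
    stop("expected prevalence must be positive; coverage undefined",
         call. = FALSE)
  cc <- p_t / p_g
  rel_t2 <- ifelse(p_t > 0, (se_t / p_t)^2, 0)
  se_c <- ifelse(p_t > 0,
                 cc * sqrt(rel_t2 + (se_g / p_g)^2),
                 se_t / p_g)
  capped <- cc >= 1
  if (any(capped))
    warning(sum(capped), " coverage ratio(s) at or above 1 capped at 0.999",
            call. = FALSE)
  cc[capped] <- 0.999
  list(c = cc, se_c = se_c, capped = capped)
}

#' Logit transform with delta-method standard error
#'
#' `logit(c) = log(c / (1 - c))` with `se_logit = se_c / (c * (1 - c))`.
#' Proportions at exactly 0 or 1 receive the standard continuity
#' correction for logit meta-analysis, `1/(4n)` and `1 - 1/(4n)` with `n`
#' the effective population.
#'
#' @param c proportion(s) in \[0, 1\].
#' @param se_c standard error(s) on the natural scale.
#' @param n effective population, required only when some `c` is exactly 0
#'   or 1.
#' @return A list with `logit_c` and `se_logit`.
#' @export
logit_with_delta <- function(c, se_c, n = NULL) {
  boundary <- c <= 0 | c >= 1
  if (any(boundary)) {
    if (is.null(n))
      stop("c at 0 or 1 requires the effective population n for the ",
           "continuity correction", call. = FALSE)
    n <- rep_len(n, length(c))
    c <- ifelse(c <= 0, 1 / (4 * n), ifelse(c >= 1, 1 - 1 / (4 * n), c))
  }
  list(logit_c = log(c / (1 - c)), se_logit = se_c / (c * (1 - c)))
}

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Read a plausibility-threshold table
#'
#' Parses a YAML mapping `disorder -> income_group -> {lower, upper}` into
#' a threshold data.frame. `null` (absent) bounds never exclude.
#'
#' @param path YAML file path.
#' @return A data.frame with columns `disorder`, `income_group`, `lower`,
#'   `upper` (`NA` = no bound).
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  y <- y[names(y) %in% DISORDERS]
  rows <- list()
  for (d in names(y)) for (g in names(y[[d]])) {
    b <- y[[d]][[g]]
    rows[[length(rows) + 1L]] <- data.frame(
      disorder = d, income_group = g,
      lower = as.numeric(b$lower %||% NA), upper = as.numeric(b$upper %||% NA),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  bad <- !is.na(tab$lower) & !is.na(tab$upper) & tab$lower >= tab$upper
  if (any(bad)) stop("threshold lower must be below upper", call. = FALSE)
  tab
}

#' Default plausibility thresholds
#'
#' The admissible coverage band per disorder and income group used to
#' detect reports of visits (or otherwise implausible counts) in the cases
#' fields. Psychosis has lower bounds only — genuinely high specialist
#' coverage for psychosis is plausible, so no upper limit is set — while
#' bipolar disorder and depression have upper bounds only, to retain the
#' genuinely low coverage expected for these disorders. The shipped values
#' (inst/extdata/thresholds.yaml) are reconstructed from published
#' survey-based service-use estimates and are editable configuration, not
#' measured quantities.
#'
#' @return A threshold data.frame (see [read_thresholds()]).
#' @export
default_thresholds <- function() {
  read_thresholds(system.file("extdata", "thresholds.yaml",
                              package = "contactcov", mustWork = TRUE))
}

#' Apply plausibility thresholds to coverage estimates
#'
#' An estimate is excluded (reason `outside_threshold`) when its coverage
#' falls strictly below the lower bound or strictly above the upper bound
#' for its disorder and income group. Absent bounds never exclude.
#'
#' @param coverage numeric coverage proportions.
#' @param disorder,income_group vectors aligned with `coverage`.
#' @param thresholds a threshold data.frame, or `NULL` to disable
#'   filtering.
#' @return A data.frame with `included` and `reason`.
#' @export
apply_thresholds <- function(coverage, disorder, income_group,
                             thresholds = default_thresholds()) {
  n <- length(coverage)
  if (is.null(thresholds))
    return(data.frame(included = rep(TRUE, n), reason = rep("ok", n),
                      stringsAsFactors = FALSE))
  idx <- match(paste(disorder, income_group),
               paste(thresholds$disorder, thresholds$income_group))
  lower <- thresholds$lower[idx]
  upper <- thresholds$upper[idx]
  out <- (!is.na(lower) & coverage < lower) |
    (!is.na(upper) & coverage > upper)
  data.frame(included = !out,
             reason = ifelse(out, "outside_threshold", "ok"),
             stringsAsFactors = FALSE)
}
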