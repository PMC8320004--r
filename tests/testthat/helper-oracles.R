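## Independent oracles and fixture builders shared across tests.

## Step-by-step DerSimonian-Laird oracle, written directly from the
## textbook moment formulas and kept independent of the package's
## implementation.
oracle_dl <- function(y, se) {
  k <- length(y)
  w <- 1 / se^2
  fixed <- sum(w * y) / sum(w)
  Q <- sum(w * (y - fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se^2 + tau2)
  mu <- sum(w_star * y) / sum(w_star)
  list(mu = mu, se = sqrt(1 / sum(w_star)), tau2 = tau2, Q = Q,
       fixed = fixed, se_fixed = sqrt(1 / sum(w)))
}

## Build a small atlas-style record table; NA marks a missing cell.
make_records <- function(...) {
  rows <- list(...)
  cols <- c("country_code", "disorder", "inpatient_cases",
            "outpatient_cases", "inpatient_visits", "outpatient_visits",
            "representativeness", "followup_category",
            "reported_population")
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(country_code = "AAA", disorder = "psychosis",
                     inpatient_cases = 100, outpatient_cases = 500,
                     inpatient_visits = 300, outpatient_visits = 1500,
                     representativeness = 1, followup_category = 2,
                     reported_population = 1e6)
    defaults[names(r)] <- r
    as.data.frame(defaults[cols], stringsAsFactors = FALSE)
  }))
}

make_context <- function(codes, income = "high", un_population = 1e6) {
  data.frame(country_code = codes,
             income_group = rep_len(income, length(codes)),
             who_region = "EUR", gbd_region = "SR1_1",
             gbd_super_region = "SR1",
             un_population = rep_len(un_population, length(codes)),
             stringsAsFactors = FALSE)
}

make_prevalence <- function(codes, disorder = "psychosis", rate = 0.0049,
                            rel = 0.1, time_frame = "point") {
  half <- 1.959964 * rel * rate
  data.frame(country_code = codes, disorder = disorder, rate = rate,
             lower95 = rate - half, upper95 = rate + half,
             time_frame = time_frame, stringsAsFactors = FALSE)
}
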