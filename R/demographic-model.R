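# Closed-form demography: survey growth rates, the recruitment-mortality
# (R-M) equation, calf production, study-derived recruitment and mortality
# back-calculation, plus the year-indexed table that ties them together.

#' Survey-based finite annual growth rate
#'
#' Geometric growth rate between two abundance estimates,
#' \eqn{\lambda = (N_t / N_0)^{1/t}}, the per-year rate realized over an
#' interval of `t` years.
#'
#' @param n0 Abundance at the start of the interval (animals, > 0).
#' @param nt Abundance at the end of the interval (animals, > 0).
#' @param t Interval length in whole years (>= 1).
#' @return The finite annual growth rate \eqn{\lambda} (dimensionless).
#'   Values > 1 indicate growth, < 1 decline.
#' @examples
#' growth_rate_survey(2760, 4350, 1)  # the largest single-year rate, 1.58
#' growth_rate_survey(8840, 3710, 11) # mean annual rate over a long decline
#' @seealso [rm_lambda()] for the vital-rate route to the same quantity.
#' @export
growth_rate_survey <- function(n0, nt, t = 1) {
  if (anyNA(c(n0, nt, t))) abort_invalid("must not be missing", "n0/nt/t")
  if (any(n0 <= 0)) abort_invalid("abundance must be > 0", "n0")
  if (any(nt <= 0)) abort_invalid("abundance must be > 0", "nt")
  if (any(t < 1) || any(t != round(t))) {
    abort_invalid("must be a whole number of years >= 1", "t")
  }
  (nt / n0)^(1 / t)
}

#' Growth rate from the recruitment-mortality equation
#'
#' The R-M equation \eqn{\lambda = (1 - M)/(1 - R)} relates the finite
#' annual adult mortality rate M and the finite annual recruitment rate R
#' (the calf proportion of the population at recruitment age) to the
#' population growth rate. When mortality exactly balances recruitment
#' (M = R) the population is stationary and \eqn{\lambda = 1}.
#'
#' @param m Finite annual adult mortality rate, in \[0, 1\].
#' @param r Finite annual recruitment rate, in \[0, 1).
#' @return Growth rate \eqn{\lambda} (dimensionless, > 0).
#' @examples
#' rm_lambda(0.14, 0.20)  # low mortality + high recruitment: growth
#' rm_lambda(0.15, 0.15)  # balanced: exactly 1
#' @export
rm_lambda <- function(m, r) {
  check_prob(m, "m")
  if (anyNA(r)) abort_invalid("must not be missing", "r")
  if (any(r < 0)) abort_invalid("must be >= 0", "r")
  if (any(r >= 1)) abort_domain("recruitment rate r must be < 1 (division by 1 - r)")
  ifelse(m == r, 1, (1 - m) / (1 - r))
}

#' Back-calculate adult mortality from growth rate and recruitment
#'
#' Rearranges the R-M equation to \eqn{M = 1 - \lambda (1 - R)}. Feeding in
#' a survey-derived growth rate and the survey calf fraction gives the adult
#' mortality the survey trajectory implies; implausible survey jumps show up
#' as impossible (negative) mortalities.
#'
#' @param lam Finite annual growth rate (> 0).
#' @param r Finite annual recruitment rate, in \[0, 1).
#' @return Implied adult mortality rate. May be negative when the observed
#'   growth exceeds what recruitment alone can supply.
#' @examples
#' backcalc_mortality(1.58, 0.15)  # about -0.34: biologically impossible
#' backcalc_mortality(0.9, 0.3)    # 0.37
#' @export
backcalc_mortality <- function(lam, r) {
  if (anyNA(c(lam, r))) abort_invalid("must not be missing", "lam/r")
  if (any(lam <= 0)) abort_invalid("growth rate must be > 0", "lam")
  if (any(r < 0)) abort_invalid("must be >= 0", "r")
  if (any(r >= 1)) abort_domain("recruitment rate r must be < 1")
  1 - lam * (1 - r)
}

#' Expected calf production
#'
#' Expected number of calves born to an adult population:
#' `adult_n * prop_cows * pregnancy_rate * (1 + twinning_rate)`. Each
#' pregnant cow produces one calf, plus a second with probability equal to
#' the twinning rate.
#'
#' @param adult_n Adult population size (animals, >= 0).
#' @param prop_cows Proportion of the adult population that is cows, \[0, 1\].
#' @param pregnancy_rate Proportion of cows pregnant, \[0, 1\].
#' @param twinning_rate Proportion of pregnant cows producing twins, \[0, 1\].
#' @return Expected calves born (animals, real-valued).
#' @examples
#' calf_production(5593, 0.48, 0.83, 0.30)
#' @export
calf_production <- function(adult_n, prop_cows, pregnancy_rate, twinning_rate) {
  if (anyNA(adult_n)) abort_invalid("must not be missing", "adult_n")
  if (any(adult_n < 0)) abort_invalid("must be >= 0", "adult_n")
  check_prob(prop_cows, "prop_cows")
  check_prob(pregnancy_rate, "pregnancy_rate")
  check_prob(twinning_rate, "twinning_rate")
  adult_n * prop_cows * pregnancy_rate * (1 + twinning_rate)
}

#' Study-derived recruitment rate
#'
#' Recruitment for year t from the previous year's calf crop: the calves
#' produced in year t-1 that survive their first year, as a proportion of
#' the year t-1 population estimate. Animals are considered recruited once
#' they reach one year of age, hence the one-year lag.
#'
#' @param s_calf_prev Previous year's birth-to-age-1 calf survival, \[0, 1\].
#' @param calf_production_prev Previous year's expected calf production
#'   (animals, >= 0).
#' @param n_prev Previous year's population estimate (animals, > 0).
#' @return Recruitment rate R (proportion).
#' @examples
#' recruitment_study(0.28, 1040, 2760)
#' @export
recruitment_study <- function(s_calf_prev, calf_production_prev, n_prev) {
  check_prob(s_calf_prev, "s_calf_prev")
  if (anyNA(c(calf_production_prev, n_prev))) {
    abort_invalid("must not be missing", "calf_production_prev/n_prev")
  }
  if (any(calf_production_prev < 0)) abort_invalid("must be >= 0", "calf_production_prev")
  if (any(n_prev <= 0)) abort_invalid("population estimate must be > 0", "n_prev")
  s_calf_prev * calf_production_prev / n_prev
}

#' Percent decline between two abundances
#'
#' @param n0 Earlier abundance (> 0).
#' @param nt Later abundance (>= 0).
#' @return Percent decline, `100 * (1 - nt/n0)`; negative values indicate
#'   an increase.
#' @examples
#' percent_decline(8840, 3710)  # about 58
#' @export
percent_decline <- function(n0, nt) {
  if (any(n0 <= 0)) abort_invalid("must be > 0", "n0")
  if (any(nt < 0)) abort_invalid("must be >= 0", "nt")
  100 * (1 - nt / n0)
}

#' Derive the per-year demography table
#'
#' Joins an aerial-survey series with a collar-study vital-rates series by
#' year and computes every derived quantity: calf production, study-derived
#' recruitment, survey and R-M growth rates, and back-calculated adult
#' mortality. Lagged quantities (R_study, lambda_survey, lambda_rm) are
#' computed only for years whose immediate predecessor is present; cells
#' lacking an input are `NA`, never imputed.
#'
#' @details
#' Per year t:
#' \itemize{
#'   \item adult population = `abundance * (1 - calf_fraction)`;
#'   \item `calf_production` from that year's adult population, cow
#'     proportion, pregnancy and twinning rates;
#'   \item `r_study(t) = s_calf(t-1) * calf_production(t-1) / abundance(t-1)`;
#'   \item `lambda_survey(t) = abundance(t) / abundance(t-1)`;
#'   \item `lambda_rm(t) = (1 - M) / (1 - r_study(t))` with adult mortality
#'     `M = 1 - s_adult` taken from year t-1 by default (`m_alignment =
#'     "lagged"`, matching the recruitment lag) or from year t
#'     (`"same_year"`);
#'   \item `m_backcalc(t) = 1 - lambda_survey(t) * (1 - r_survey(t))`.
#' }
#'
#' `lambda_inputs` controls the precision at which M and the recruitment
#' rates enter the ratio equations. `"printed"` (default) keeps two decimal
#' digits of `r_study`, `r_survey` and `lambda_survey` (digits beyond the
#' second are dropped) and uses M at two decimals, matching the tabular
#' convention of published agency reports in which the ratio columns are
#' computed from the printed-precision rate columns. `"exact"` uses full
#' precision throughout, and is the mode under which the R-M identity
#' `lambda_rm * (1 - r_study) = 1 - M` holds to machine precision.
#'
#' @param survey Data frame of survey estimates with columns `year`,
#'   `abundance` and optionally `ci90_low`, `ci90_high`, `calf_fraction`,
#'   `bull_cow_ratio`, `twin_fraction` (see [read_survey_csv()]).
#' @param vitals Data frame of vital rates with columns `year`, `s_adult`,
#'   `s_calf`, `pregnancy_rate`, `twinning_rate`, `prop_cows`
#'   (see [read_vitals_csv()]).
#' @param lambda_inputs `"printed"` or `"exact"`; see Details.
#' @param m_alignment `"lagged"` (M from year t-1; default) or `"same_year"`.
#' @return A data frame of class `derived_demography` with one row per year
#'   and columns `year`, `abundance`, `m_adult`, `s_calf`, `r_survey`,
#'   `r_study`, `pregnancy_rate`, `calf_production`, `lambda_survey`,
#'   `lambda_rm`, `m_backcalc`.
#' @examples
#' survey <- read_survey_csv(rmgrowth_example("mn_moose_survey_2013_2017.csv"))
#' vitals <- read_vitals_csv(rmgrowth_example("mn_moose_vitals_2013_2017.csv"))
#' derive_table(survey, vitals)
#' @seealso [derive_summary()] for the mean/SE footer rows.
#' @export
derive_table <- function(survey, vitals,
                         lambda_inputs = c("printed", "exact"),
                         m_alignment = c("lagged", "same_year")) {
  lambda_inputs <- match.arg(lambda_inputs)
  m_alignment <- match.arg(m_alignment)
  for (nm in c("year", "abundance")) {
    if (!nm %in% names(survey)) abort_invalid("missing from survey table", nm)
  }
  for (nm in c("year", "s_adult", "s_calf", "pregnancy_rate",
               "twinning_rate", "prop_cows")) {
    if (!nm %in% names(vitals)) abort_invalid("missing from vitals table", nm)
  }
  if (anyDuplicated(survey$year)) {
    abort_invalid(sprintf("duplicate survey years: %s",
                          paste(unique(survey$year[duplicated(survey$year)]),
                                collapse = ", ")), "year")
  }
  if (anyDuplicated(vitals$year)) {
    abort_invalid(sprintf("duplicate vitals years: %s",
                          paste(unique(vitals$year[duplicated(vitals$year)]),
                                collapse = ", ")), "year")
  }
  if (is.unsorted(survey$year, strictly = TRUE)) {
    abort_invalid("survey years must be strictly increasing", "year")
  }

  opt <- function(df, nm) if (nm %in% names(df)) df[[nm]] else rep(NA_real_, nrow(df))
  years <- sort(union(survey$year, vitals$year))
  si <- match(years, survey$year)
  vi <- match(years, vitals$year)

  n        <- survey$abundance[si]
  cf       <- opt(survey, "calf_fraction")[si]
  s_adult  <- vitals$s_adult[vi]
  s_calf   <- vitals$s_calf[vi]
  preg     <- vitals$pregnancy_rate[vi]
  twin     <- vitals$twinning_rate[vi]
  pc       <- vitals$prop_cows[vi]

  m_adult <- 1 - s_adult
  adult_n <- n * (1 - cf)
  cp <- adult_n * pc * preg * (1 + twin)

  ny <- length(years)
  lag_ok <- c(FALSE, diff(years) == 1)          # year t-1 present?
  prev <- function(x) c(NA_real_, x[-ny])

  lambda_survey <- ifelse(lag_ok & !is.na(prev(n)) & !is.na(n), n / prev(n), NA_real_)
  r_study <- ifelse(lag_ok, prev(s_calf) * prev(cp) / prev(n), NA_real_)
  m_for_lambda <- if (m_alignment == "lagged") prev(m_adult) else m_adult

  if (lambda_inputs == "printed") {
    r_rm  <- trunc_digits(r_study, 2)
    m_rm  <- round_half_up(m_for_lambda, 2)
    lam_s <- round_half_up(lambda_survey, 2)
    r_sv  <- trunc_digits(cf, 2)
  } else {
    r_rm  <- r_study
    m_rm  <- m_for_lambda
    lam_s <- lambda_survey
    r_sv  <- cf
  }

  lambda_rm <- ifelse(!is.na(m_rm) & !is.na(r_rm), (1 - m_rm) / (1 - r_rm), NA_real_)
  m_backcalc <- ifelse(!is.na(lam_s) & !is.na(r_sv), 1 - lam_s * (1 - r_sv), NA_real_)

  out <- data.frame(
    year = years,
    abundance = n,
    m_adult = m_adult,
    s_calf = s_calf,
    r_survey = cf,
    r_study = r_study,
    pregnancy_rate = preg,
    calf_production = cp,
    lambda_survey = lambda_survey,
    lambda_rm = lambda_rm,
    m_backcalc = m_backcalc
  )
  attr(out, "lambda_inputs") <- lambda_inputs
  attr(out, "m_alignment") <- m_alignment
  class(out) <- c("derived_demography", "data.frame")
  out
}

#' Mean and standard error of the derived table's columns
#'
#' Arithmetic mean and standard error (sample SD with n-1 denominator,
#' divided by sqrt(n)) of every numeric column of a [derive_table()] result,
#' over the years for which each quantity is available.
#'
#' @param derived A `derived_demography` data frame from [derive_table()].
#' @return A data frame with rows `mean`, `se` and `n_years`, one column per
#'   derived quantity.
#' @export
derive_summary <- function(derived) {
  cols <- setdiff(names(derived), "year")
  stat <- vapply(cols, function(nm) {
    x <- derived[[nm]][!is.na(derived[[nm]])]
    if (length(x) == 0) return(c(NA_real_, NA_real_, 0))
    c(mean(x),
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
      length(x))
  }, numeric(3))
  out <- as.data.frame(t(stat))
  names(out) <- c("mean", "se", "n_years")
  out <- cbind(quantity = cols, out)
  rownames(out) <- NULL
  out
}

#' @export
print.derived_demography <- function(x, digits = 3, ...) {
  cat(sprintf("Derived demography table: %d years (%s-%s), lambda inputs \"%s\"\n",
              nrow(x), min(x$year), max(x$year), attr(x, "lambda_inputs")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
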