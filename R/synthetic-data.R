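# Seed-deterministic generators for survey series, collar cohorts and
# calving outcomes with the statistical structure the analysis assumes, so
# the full pipeline is testable against known truth.

#' Ground truth for a simulation
#'
#' Defines the latent state behind a synthetic dataset. When `true_lambda`
#' is `NULL` (default) it is derived from the vital rates so that the bundle
#' is internally consistent with the R-M equation: at a steady calf fraction
#' the per-capita recruitment solves \eqn{R = A (1 - R)} with
#' \eqn{A = S_{calf} \cdot propcows \cdot preg \cdot (1 + twin)}, giving
#' \eqn{R = A / (1 + A)} and \eqn{\lambda = S_{adult} / (1 - R)}. A
#' `true_lambda` supplied explicitly decouples the trajectory from the
#' rates (useful for survey-only simulations); the implied calf fraction is
#' then \eqn{1 - S_{adult}/\lambda}.
#'
#' @param s_adult,s_calf,pregnancy_rate,twinning_rate,prop_cows True vital
#'   rates, each in \[0, 1\].
#' @param true_lambda Annual growth rate of the latent trajectory, or `NULL`
#'   to derive it from the rates.
#' @param n0 Starting abundance (animals, > 0).
#' @param survey_cv Coefficient of variation of the multiplicative survey
#'   observation error (>= 0; 0 means the survey observes the latent
#'   trajectory exactly).
#' @param composition_ess Effective sample size of the survey's composition
#'   counts: the observed calf fraction is Beta-distributed with this
#'   concentration around the true fraction. `Inf` (used with
#'   `survey_cv = 0` for noise-free bundles) reports the true fraction
#'   exactly.
#' @param seed Integer RNG seed stored with the truth.
#' @return A list of class `simulation_truth` including the derived fields
#'   `true_lambda` and `calf_fraction`.
#' @examples
#' simulation_truth()  # study-like defaults, lambda just below 1
#' @export
simulation_truth <- function(s_adult = 0.85, s_calf = 0.35,
                             pregnancy_rate = 0.83, twinning_rate = 0.30,
                             prop_cows = 0.48, true_lambda = NULL,
                             n0 = 4350, survey_cv = 0.15,
                             composition_ess = 500, seed = 1) {
  for (nm in c("s_adult", "s_calf", "pregnancy_rate", "twinning_rate", "prop_cows")) {
    check_prob(get(nm), nm)
  }
  if (n0 <= 0) abort_invalid("must be > 0", "n0")
  if (survey_cv < 0) abort_invalid("must be >= 0", "survey_cv")
  if (composition_ess <= 0) abort_invalid("must be > 0", "composition_ess")
  a <- s_calf * prop_cows * pregnancy_rate * (1 + twinning_rate)
  if (is.null(true_lambda)) {
    r <- a / (1 + a)
    true_lambda <- s_adult / (1 - r)
  } else {
    if (true_lambda <= 0) abort_invalid("must be > 0", "true_lambda")
    r <- 1 - s_adult / true_lambda
    if (r < 0 || r >= 1) {
      abort_invalid("incompatible with s_adult: implied calf fraction outside [0, 1)",
                    "true_lambda")
    }
  }
  out <- list(true_lambda = true_lambda, true_s_adult = s_adult,
              true_s_calf = s_calf, true_pregnancy = pregnancy_rate,
              true_twinning = twinning_rate, true_prop_cows = prop_cows,
              calf_fraction = r, n0 = n0, survey_cv = survey_cv,
              composition_ess = composition_ess, seed = as.integer(seed))
  class(out) <- "simulation_truth"
  out
}

#' Simulate an aerial-survey abundance series
#'
#' The latent population follows geometric growth,
#' \eqn{N_t = N_0 \lambda^t}. Observed abundance is the latent value times a
#' lognormal error with median 1 and coefficient of variation `survey_cv`
#' (\eqn{\sigma = \sqrt{\log(1 + cv^2)}}); 90% CI bounds are placed at the
#' lognormal 5th/95th quantiles around each observation. The observed calf
#' fraction is Beta-distributed around the truth-implied fraction with
#' concentration `composition_ess`.
#'
#' @param truth A [simulation_truth()].
#' @param years Number of annual surveys (>= 2).
#' @param start_year Calendar year of the first survey.
#' @return Data frame in the survey dialect (see [read_survey_csv()]) with
#'   columns `year`, `abundance`, `ci90_low`, `ci90_high`, `calf_fraction`,
#'   `bull_cow_ratio`, `twin_fraction`.
#' @examples
#' simulate_survey_series(simulation_truth(seed = 3), years = 5)
#' @export
simulate_survey_series <- function(truth, years, start_year = 2013) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (years < 2) abort_invalid("must be >= 2", "years")
  set.seed(truth$seed)
  t_idx <- 0:(years - 1)
  latent <- truth$n0 * truth$true_lambda^t_idx
  sigma <- sqrt(log(1 + truth$survey_cv^2))
  obs <- latent * exp(stats::rnorm(years, 0, sigma))
  z90 <- stats::qnorm(0.95)
  cf <- if (is.infinite(truth$composition_ess)) {
    rep(truth$calf_fraction, years)
  } else {
    stats::rbeta(years,
                 truth$calf_fraction * truth$composition_ess,
                 (1 - truth$calf_fraction) * truth$composition_ess)
  }
  data.frame(
    year = start_year + t_idx,
    abundance = obs,
    ci90_low = obs * exp(-z90 * sigma),
    ci90_high = obs * exp(z90 * sigma),
    calf_fraction = cf,
    bull_cow_ratio = (1 - truth$true_prop_cows) / truth$true_prop_cows,
    twin_fraction = truth$true_twinning
  )
}

#' Simulate a collared-animal monitoring cohort
#'
#' Death times are exponential with the constant daily hazard
#' \eqn{h = -\log(S)/365} implied by the true annual survival; independent
#' censoring times are exponential with the daily hazard matching
#' `censor_rate` per year. Entry days are uniform over
#' `[0, entry_window]` (staggered entry); records are right-censored at the
#' study end.
#'
#' @param n Number of animals (>= 1).
#' @param true_annual_s True annual survival probability, (0, 1\].
#' @param censor_rate Annual probability of (non-death) censoring, \[0, 1).
#' @param seed Integer RNG seed.
#' @param entry_window Width in days of the uniform staggered-entry window
#'   (0 = common entry at day 0).
#' @param study_days Study end (days); defaults to `entry_window + 365` so
#'   every animal can be observed a full year.
#' @param cohort Label stored in the records (`"adult"` or `"calf"`).
#' @return Data frame in the collar dialect (see [read_collar_csv()]):
#'   `animal_id`, `cohort`, `entry_day`, `exit_day`, `event`.
#' @examples
#' rec <- simulate_collar_cohort(200, 0.85, censor_rate = 0.2, seed = 11)
#' annual_survival(rec)
#' @export
simulate_collar_cohort <- function(n, true_annual_s, censor_rate = 0, seed = 1,
                                   entry_window = 0, study_days = entry_window + 365,
                                   cohort = c("adult", "calf")) {
  cohort <- match.arg(cohort)
  if (n < 1 || n != round(n)) abort_invalid("must be an integer >= 1", "n")
  if (is.na(true_annual_s) || true_annual_s <= 0 || true_annual_s > 1) {
    abort_invalid("must lie in (0, 1] (0 implies an infinite hazard)", "true_annual_s")
  }
  if (censor_rate < 0 || censor_rate >= 1) abort_invalid("must lie in [0, 1)", "censor_rate")
  if (entry_window < 0) abort_invalid("must be >= 0", "entry_window")
  if (study_days <= entry_window) abort_invalid("must exceed entry_window", "study_days")
  set.seed(seed)
  entry <- if (entry_window > 0) stats::runif(n, 0, entry_window) else rep(0, n)
  h_death <- -log(true_annual_s) / 365
  h_cens <- if (censor_rate > 0) -log(1 - censor_rate) / 365 else 0
  t_death <- if (h_death > 0) stats::rexp(n, h_death) else rep(Inf, n)
  t_cens <- if (h_cens > 0) stats::rexp(n, h_cens) else rep(Inf, n)
  t_end <- study_days - entry
  t_obs <- pmin(t_death, t_cens, t_end)
  # product-limit needs exit > entry; give instantaneous events a half-day
  t_obs <- pmax(t_obs, 0.5)
  event <- ifelse(t_death <= pmin(t_cens, t_end), "death", "censored")
  data.frame(
    animal_id = sprintf("%s-%04d", toupper(substr(cohort, 1, 1)), seq_len(n)),
    cohort = cohort,
    entry_day = entry,
    exit_day = entry + t_obs,
    event = event
  )
}

#' Simulate per-cow calving outcomes
#'
#' Each cow is pregnant with probability `pregnancy_rate`; each pregnant cow
#' produces twins with probability `twinning_rate` (two calves, otherwise
#' one); each calf independently survives its first year with probability
#' `s_calf`. Expected calves per cow is
#' `pregnancy_rate * (1 + twinning_rate)`.
#'
#' @param n_cows Number of cows (>= 1).
#' @param pregnancy_rate,twinning_rate,s_calf True rates, each \[0, 1\].
#' @param seed Integer RNG seed.
#' @return Data frame with one row per cow: `cow_id`, `pregnant` (0/1),
#'   `twins` (0/1), `calves_born` (0-2), `calves_recruited` (0-2).
#' @examples
#' out <- simulate_calving_outcomes(1000, 0.83, 0.30, 0.35, seed = 5)
#' mean(out$calves_born)  # about 0.83 * 1.30
#' @export
simulate_calving_outcomes <- function(n_cows, pregnancy_rate, twinning_rate,
                                      s_calf, seed = 1) {
  if (n_cows < 1 || n_cows != round(n_cows)) abort_invalid("must be an integer >= 1", "n_cows")
  check_prob(pregnancy_rate, "pregnancy_rate")
  check_prob(twinning_rate, "twinning_rate")
  check_prob(s_calf, "s_calf")
  set.seed(seed)
  pregnant <- stats::rbinom(n_cows, 1, pregnancy_rate)
  twins <- ifelse(pregnant == 1, stats::rbinom(n_cows, 1, twinning_rate), 0L)
  born <- pregnant * (1L + twins)
  recruited <- stats::rbinom(n_cows, born, s_calf)
  data.frame(cow_id = sprintf("C-%05d", seq_len(n_cows)),
             pregnant = pregnant, twins = twins,
             calves_born = born, calves_recruited = recruited)
}

#' Generate a consistent end-to-end dataset bundle
#'
#' Ties the generators together: a survey series observed around the latent
#' trajectory, a vital-rates table carrying the latent true rates (point
#' estimates, as the analysis consumes them), and a collar cohort drawn at
#' the true adult survival so the survival estimator can be exercised
#' against the same truth. Because the truth satisfies the R-M identity
#' \eqn{\lambda = (1 - M)/(1 - R)}, a noise-free bundle
#' (`survey_cv = 0`, `composition_ess = Inf`) passed through
#' [derive_table()] in `"exact"` mode recovers `true_lambda` exactly.
#'
#' @param truth A [simulation_truth()] (its `seed` drives all randomness).
#' @param years Number of survey years (>= 2).
#' @param collar_n Animals in the simulated collar cohort (0 skips it).
#' @param dir Optional directory: when given, writes `survey.csv`,
#'   `vitals.csv`, `collar.csv` in the package's CSV dialects plus a
#'   `truth.json` sidecar (requires jsonlite), and returns the paths in the
#'   result.
#' @param censor_rate Annual censoring rate for the collar cohort.
#' @return List with elements `survey`, `vitals`, `collar` (data frames;
#'   `collar` is `NULL` when `collar_n = 0`), `truth`, and `paths` when
#'   `dir` was given.
#' @examples
#' bundle <- end_to_end_dataset(simulation_truth(survey_cv = 0,
#'                                               composition_ess = Inf),
#'                              years = 6, collar_n = 0)
#' derive_table(bundle$survey, bundle$vitals, lambda_inputs = "exact")
#' @export
end_to_end_dataset <- function(truth, years, collar_n = 100, dir = NULL,
                               censor_rate = 0.1) {
  stopifnot(inherits(truth, "simulation_truth"))
  survey <- simulate_survey_series(truth, years)
  vitals <- data.frame(
    year = survey$year,
    s_adult = truth$true_s_adult,
    s_calf = truth$true_s_calf,
    pregnancy_rate = truth$true_pregnancy,
    twinning_rate = truth$true_twinning,
    prop_cows = truth$true_prop_cows
  )
  collar <- if (collar_n > 0) {
    simulate_collar_cohort(collar_n, truth$true_s_adult,
                           censor_rate = censor_rate,
                           seed = truth$seed + 1L, entry_window = 120)
  } else NULL
  out <- list(survey = survey, vitals = vitals, collar = collar, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(survey = file.path(dir, "survey.csv"),
               vitals = file.path(dir, "vitals.csv"))
    write_survey_csv(survey, paths[["survey"]])
    write_vitals_csv(vitals, paths[["vitals"]])
    if (!is.null(collar)) {
      paths[["collar"]] <- file.path(dir, "collar.csv")
      write_collar_csv(collar, paths[["collar"]])
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      paths[["truth"]] <- file.path(dir, "truth.json")
      jsonlite::write_json(unclass(truth), paths[["truth"]],
                           auto_unbox = TRUE, digits = NA)
    }
    out$paths <- paths
  }
  out
}
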