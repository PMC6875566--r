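# Shared fixtures and independent oracles for the test suite.

fixture_survey <- function() {
  read_survey_csv(rmgrowth_example("mn_moose_survey_2013_2017.csv"))
}

fixture_vitals <- function() {
  read_vitals_csv(rmgrowth_example("mn_moose_vitals_2013_2017.csv"))
}

collar_df <- function(entry, exit, event, cohort = "adult") {
  data.frame(animal_id = sprintf("A-%03d", seq_along(entry)),
             cohort = rep(cohort, length.out = length(entry)),
             entry_day = entry, exit_day = exit, event = event)
}

# Independent Kaplan-Meier oracle: survival::survfit in counting-process
# form (delayed entry), evaluated as a right-continuous step function.
survfit_surv_at <- function(records, t) {
  status <- as.integer(records$event == "death")
  fit <- survival::survfit(
    survival::Surv(records$entry_day, records$exit_day, status) ~ 1)
  i <- findInterval(t, fit$time[fit$n.event > 0])
  s <- c(1, fit$surv[fit$n.event > 0])
  s[i + 1]
}

# Random censored cohort with staggered entry for agreement tests.
random_cohort <- function(n, seed) {
  set.seed(seed)
  entry <- runif(n, 0, 150)
  t_death <- rexp(n, rate = 1 / runif(1, 400, 3000))
  t_cens <- rexp(n, rate = 1 / runif(1, 400, 3000))
  t_end <- runif(1, 300, 600) + 150 - entry
  t_obs <- pmax(pmin(t_death, t_cens, t_end), 0.5)
  collar_df(entry, entry + t_obs,
            ifelse(t_death <= pmin(t_cens, t_end), "death", "censored"))
}
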