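# One-at-a-time local sensitivity of the R-M growth rate to each vital rate.

#' Baseline vital rates for the sensitivity analysis
#'
#' Mean-level vital rates at which all parameters but one are held during
#' the one-at-a-time search. The defaults are the study means of the
#' 2013-2017 northeastern Minnesota moose series; at these values the R-M
#' growth rate is 0.997, i.e. 1.00 at two decimals. `population` is carried
#' for completeness but cancels out of the growth rate (recruitment is a
#' per-capita ratio), so abundance never drives the sensitivity results.
#'
#' @param s_adult Annual adult survival.
#' @param s_calf Birth-to-age-1 calf survival.
#' @param prop_cows Cow proportion of the adult population.
#' @param pregnancy_rate Proportion of cows pregnant.
#' @param twinning_rate Proportion of pregnant cows producing twins.
#' @param population Mean population size (animals; immaterial to lambda).
#' @return A list of class `sensitivity_baseline`.
#' @export
sensitivity_baseline <- function(s_adult = 0.85, s_calf = 0.285,
                                 prop_cows = 0.48, pregnancy_rate = 0.83,
                                 twinning_rate = 0.30, population = 5593) {
  for (nm in c("s_adult", "s_calf", "prop_cows", "pregnancy_rate", "twinning_rate")) {
    check_prob(get(nm), nm)
  }
  if (population <= 0) abort_invalid("must be > 0", "population")
  out <- list(s_adult = s_adult, s_calf = s_calf, prop_cows = prop_cows,
              pregnancy_rate = pregnancy_rate, twinning_rate = twinning_rate,
              population = population)
  class(out) <- "sensitivity_baseline"
  out
}

sensitivity_parameters <- c("s_adult", "s_calf", "prop_cows",
                            "pregnancy_rate", "twinning_rate")

#' R-M growth rate from vital rates
#'
#' Composes the R-M equation with the per-capita recruitment implied by the
#' vital rates. At a quasi-steady state the recruitment rate is
#' \eqn{R = S_{calf} \cdot propcows \cdot preg \cdot (1 + twin)} (population
#' size cancels from calf production divided by abundance), and
#' \deqn{\lambda = S_{adult} / (1 - R).}
#'
#' @param s_adult Annual adult survival, \[0, 1\].
#' @param s_calf Calf survival to age 1, \[0, 1\].
#' @param prop_cows Cow proportion, \[0, 1\].
#' @param pregnancy_rate Pregnancy rate, \[0, 1\].
#' @param twinning_rate Twinning rate, \[0, 1\].
#' @return Growth rate \eqn{\lambda}.
#' @examples
#' lambda_from_rates(0.85, 0.285, 0.48, 0.83, 0.30)  # about 1.00
#' @export
lambda_from_rates <- function(s_adult, s_calf, prop_cows, pregnancy_rate,
                              twinning_rate) {
  for (nm in sensitivity_parameters) check_prob(get(nm), nm)
  r <- s_calf * prop_cows * pregnancy_rate * (1 + twinning_rate)
  if (any(r >= 1)) abort_domain("implied recruitment rate >= 1")
  s_adult / (1 - r)
}

lambda_at <- function(baseline, parameter, value) {
  rates <- baseline[sensitivity_parameters]
  rates[[parameter]] <- value
  do.call(lambda_from_rates, rates)
}

#' One-at-a-time sensitivity search
#'
#' Increments a single vital rate from its baseline value in steps of
#' `step`, holding every other rate at its mean level, until the R-M growth
#' rate reaches the target. With the default `stop_rule = "rounded"` the
#' search stops at the first value where lambda, rounded half away from zero
#' to two decimals, is at least the target rounded the same way -- the
#' stopping convention under which a target printed as 1.10 is reached as
#' soon as lambda rounds to it. `"exact"` stops at the first unrounded
#' lambda >= target. If the parameter's natural upper bound (1) is hit
#' before the target, the result is flagged `capped` with the lambda
#' achieved at the bound.
#'
#' @param baseline A [sensitivity_baseline()].
#' @param parameter One of `"s_adult"`, `"s_calf"`, `"prop_cows"`,
#'   `"pregnancy_rate"`, `"twinning_rate"`.
#' @param target_lambda Target growth rate (default 1.10, the level taken to
#'   reverse a decline).
#' @param step Increment applied to the parameter (> 0; default 0.005).
#' @param stop_rule `"rounded"` (default) or `"exact"`; see Description.
#' @return One-row data frame of class `sensitivity_result`: `parameter`,
#'   `baseline`, `threshold`, `achieved_lambda`, `steps`, `capped`.
#' @examples
#' sensitivity_search(sensitivity_baseline(), "s_calf", 1.10)    # 0.435
#' sensitivity_search(sensitivity_baseline(), "pregnancy_rate")  # capped at 1
#' @seealso [sensitivity_closed_form()] for the analytic root,
#'   [sensitivity_table()] for all parameters at once.
#' @export
sensitivity_search <- function(baseline = sensitivity_baseline(), parameter,
                               target_lambda = 1.10, step = 0.005,
                               stop_rule = c("rounded", "exact")) {
  stopifnot(inherits(baseline, "sensitivity_baseline"))
  stop_rule <- match.arg(stop_rule)
  if (!is.character(parameter) || length(parameter) != 1 ||
      !parameter %in% sensitivity_parameters) {
    abort_invalid(sprintf("must be one of %s",
                          paste(sensitivity_parameters, collapse = ", ")),
                  "parameter")
  }
  if (step <= 0) abort_invalid("must be > 0", "step")
  hit <- if (stop_rule == "rounded") {
    tgt <- round_half_up(target_lambda, 2)
    function(lam) round_half_up(lam, 2) >= tgt
  } else {
    function(lam) lam >= target_lambda
  }

  start <- baseline[[parameter]]
  value <- start
  steps <- 0L
  lam <- lambda_at(baseline, parameter, value)
  while (!hit(lam) && value < 1) {
    value <- min(1, value + step)
    steps <- steps + 1L
    lam <- lambda_at(baseline, parameter, value)
  }
  capped <- !hit(lam)
  out <- data.frame(parameter = parameter, baseline = start,
                    threshold = value, achieved_lambda = lam,
                    steps = steps, capped = capped)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Analytic parameter value reaching a target growth rate
#'
#' Solves \eqn{\lambda(\theta) = } `target_lambda` exactly for a single
#' vital rate, all others held at the baseline. Each rate enters lambda
#' through one linear factor, so the root is closed-form; it serves as the
#' oracle for [sensitivity_search()], whose threshold must lie within one
#' step of the root (or below it, under the rounded stop rule).
#'
#' @inheritParams sensitivity_search
#' @return One-row data frame: `parameter`, `baseline`, `exact_root`
#'   (`NA` when the root exceeds the natural bound), `capped`.
#' @examples
#' sensitivity_closed_form(sensitivity_baseline(), "s_calf", 1.10)  # 0.4388
#' @export
sensitivity_closed_form <- function(baseline = sensitivity_baseline(),
                                    parameter, target_lambda = 1.10) {
  stopifnot(inherits(baseline, "sensitivity_baseline"))
  if (!is.character(parameter) || length(parameter) != 1 ||
      !parameter %in% sensitivity_parameters) {
    abort_invalid(sprintf("must be one of %s",
                          paste(sensitivity_parameters, collapse = ", ")),
                  "parameter")
  }
  b <- baseline
  root <- switch(parameter,
    s_adult = {
      r <- b$s_calf * b$prop_cows * b$pregnancy_rate * (1 + b$twinning_rate)
      target_lambda * (1 - r)
    },
    s_calf = (1 - b$s_adult / target_lambda) /
      (b$prop_cows * b$pregnancy_rate * (1 + b$twinning_rate)),
    prop_cows = (1 - b$s_adult / target_lambda) /
      (b$s_calf * b$pregnancy_rate * (1 + b$twinning_rate)),
    pregnancy_rate = (1 - b$s_adult / target_lambda) /
      (b$s_calf * b$prop_cows * (1 + b$twinning_rate)),
    twinning_rate = (1 - b$s_adult / target_lambda) /
      (b$s_calf * b$prop_cows * b$pregnancy_rate) - 1
  )
  capped <- root > 1 | root < 0
  data.frame(parameter = parameter, baseline = b[[parameter]],
             exact_root = ifelse(capped, NA_real_, root), capped = capped)
}

#' Sensitivity table over all vital rates
#'
#' Runs [sensitivity_search()] and [sensitivity_closed_form()] for every
#' parameter and binds the results.
#'
#' @inheritParams sensitivity_search
#' @return Data frame with one row per parameter: the search threshold,
#'   achieved lambda, capped flag and the analytic root.
#' @export
sensitivity_table <- function(baseline = sensitivity_baseline(),
                              target_lambda = 1.10, step = 0.005,
                              stop_rule = c("rounded", "exact")) {
  stop_rule <- match.arg(stop_rule)
  rows <- lapply(sensitivity_parameters, function(p) {
    s <- sensitivity_search(baseline, p, target_lambda, step, stop_rule)
    cf <- sensitivity_closed_form(baseline, p, target_lambda)
    s$exact_root <- cf$exact_root
    s
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
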