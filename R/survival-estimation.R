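# Product-limit (Kaplan-Meier) survival with staggered entry and Greenwood
# variance, the estimator class behind collar-study annual survival rates.

validate_collar <- function(records) {
  req <- c("entry_day", "exit_day", "event")
  miss <- setdiff(req, names(records))
  if (length(miss)) abort_invalid("missing collar columns", paste(miss, collapse = ", "))
  if (nrow(records) == 0) abort_invalid("needs at least one record", "records")
  if (anyNA(records$entry_day) || anyNA(records$exit_day)) {
    abort_invalid("entry_day/exit_day must not be missing", "records")
  }
  if (any(records$entry_day < 0)) abort_invalid("must be >= 0", "entry_day")
  if (any(records$exit_day <= records$entry_day)) {
    abort_invalid("exit_day must exceed entry_day for every record", "exit_day")
  }
  if (!all(records$event %in% c("death", "censored"))) {
    abort_invalid('must be "death" or "censored"', "event")
  }
  invisible(records)
}

#' Kaplan-Meier survival curve with staggered entry
#'
#' Product-limit estimate of the survivor function from collar monitoring
#' records. Animals enter the risk set at `entry_day` (staggered entry /
#' left truncation: a collared animal contributes information only from the
#' day it is first monitored) and leave at `exit_day` by death or censoring.
#' At each distinct death time d, the risk set counts records with
#' `entry_day < d <= exit_day`, so animals censored on a death day are still
#' at risk at that day -- the standard convention that deaths precede
#' censorings at tied times.
#'
#' The variance of S(t) is Greenwood's estimator,
#' \eqn{\widehat{Var}[S(t)] = S(t)^2 \sum_{d_i \le t} d_i / (n_i (n_i - d_i))}.
#'
#' @param records Data frame of collar records with columns `entry_day`,
#'   `exit_day` (days, `exit_day > entry_day >= 0`) and `event` (`"death"`
#'   or `"censored"`); see [read_collar_csv()].
#' @return An object of class `km_fit`: a list with the distinct death times
#'   (`time`), numbers at risk (`n_risk`), deaths (`n_event`), the survival
#'   estimate (`surv`), its Greenwood standard error (`se`), the cumulative
#'   Greenwood sum (`greenwood_sum`), and the record count (`n`).
#' @examples
#' rec <- data.frame(entry_day = c(0, 0, 50), exit_day = c(100, 200, 400),
#'                   event = c("death", "censored", "censored"))
#' fit <- km_curve(rec)
#' surv_at(fit, 365)  # 2/3
#' @seealso [annual_survival()], [surv_at()]
#' @export
km_curve <- function(records) {
  validate_collar(records)
  death_times <- sort(unique(records$exit_day[records$event == "death"]))
  n <- nrow(records)
  if (length(death_times) == 0) {
    out <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                surv = numeric(0), se = numeric(0), greenwood_sum = numeric(0),
                n = n)
    class(out) <- "km_fit"
    return(out)
  }
  n_risk <- vapply(death_times, function(d) {
    sum(records$entry_day < d & records$exit_day >= d)
  }, numeric(1))
  n_event <- vapply(death_times, function(d) {
    sum(records$exit_day == d & records$event == "death")
  }, numeric(1))
  if (any(n_risk < n_event)) {
    abort_domain("death time with fewer at-risk animals than deaths: records are inconsistent")
  }
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood term is undefined once the curve hits zero (n_i == d_i).
  gterm <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), NA_real_)
  gsum <- cumsum(gterm)
  se <- surv * sqrt(gsum)
  se[surv == 0] <- 0
  out <- list(time = death_times, n_risk = n_risk, n_event = n_event,
              surv = surv, se = se, greenwood_sum = gsum, n = n)
  class(out) <- "km_fit"
  out
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' @param fit A `km_fit` from [km_curve()].
#' @param t Time (days) at which to evaluate the step function.
#' @return Named vector with elements `surv`, `se` and `greenwood_sum` at
#'   time `t` (`surv = 1`, `se = 0` before the first death).
#' @export
surv_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"), length(t) == 1, t >= 0)
  i <- findInterval(t, fit$time)
  if (i == 0) {
    c(surv = 1, se = 0, greenwood_sum = 0)
  } else {
    c(surv = fit$surv[i], se = fit$se[i], greenwood_sum = fit$greenwood_sum[i])
  }
}

#' Annual survival from collar records
#'
#' Kaplan-Meier survival evaluated at a fixed horizon (365 days by default),
#' with Greenwood standard error and a confidence interval. The default
#' interval is the normal approximation on the log-survival scale,
#' \eqn{\exp(\log S \pm z \cdot SE[\log S])}, which respects the \[0, 1\]
#' bounds better than the plain Greenwood interval near the boundaries; the
#' plain interval \eqn{S \pm z \cdot SE[S]} is available as an option.
#'
#' @inheritParams km_curve
#' @param horizon_days Evaluation horizon in days (> 0); 365 gives annual
#'   survival.
#' @param ci `"log"` (default) or `"plain"`.
#' @param conf_level Confidence level for the interval.
#' @return A one-row data frame: `survival`, `se`, `ci_low`, `ci_high`,
#'   `n`, `n_deaths` (deaths at or before the horizon), `horizon_days`.
#' @examples
#' rec <- data.frame(entry_day = c(0, 0, 50), exit_day = c(100, 200, 400),
#'                   event = c("death", "censored", "censored"))
#' annual_survival(rec)
#' @export
annual_survival <- function(records, horizon_days = 365,
                            ci = c("log", "plain"), conf_level = 0.95) {
  ci <- match.arg(ci)
  if (length(horizon_days) != 1 || is.na(horizon_days) || horizon_days <= 0) {
    abort_invalid("must be a single positive number of days", "horizon_days")
  }
  fit <- km_curve(records)
  at <- surv_at(fit, horizon_days)
  s <- at[["surv"]]; se <- at[["se"]]; g <- at[["greenwood_sum"]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (s == 0) {
    lo <- hi <- 0
  } else if (ci == "log") {
    se_log <- sqrt(g)          # SE of log S(t)
    lo <- s * exp(-z * se_log)
    hi <- min(1, s * exp(z * se_log))
  } else {
    lo <- max(0, s - z * se)
    hi <- min(1, s + z * se)
  }
  data.frame(survival = s, se = se, ci_low = lo, ci_high = hi,
             n = fit$n,
             n_deaths = sum(fit$n_event[fit$time <= horizon_days]),
             horizon_days = horizon_days)
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: %d records, %d death times\n",
              x$n, length(x$time)))
  if (length(x$time)) {
    print.data.frame(data.frame(time = x$time, n_risk = x$n_risk,
                                n_event = x$n_event, surv = x$surv, se = x$se),
                     digits = 4, row.names = FALSE)
  }
  invisible(x)
}
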