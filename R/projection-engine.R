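# Deterministic geometric projection and stochastic birth-pulse Monte Carlo
# projection of population trajectories.

#' Deterministic geometric projection
#'
#' Projects abundance forward under a constant finite annual growth rate:
#' `trajectory[t] = n0 * lam^t`.
#'
#' @param n0 Starting abundance (animals, >= 0).
#' @param lam Finite annual growth rate (> 0).
#' @param years Projection horizon in years (integer >= 0).
#' @return Numeric vector of length `years + 1`, named by year offset 0..years.
#' @examples
#' project_deterministic(4350, 1.01, 30)
#' @export
project_deterministic <- function(n0, lam, years) {
  if (length(n0) != 1 || is.na(n0) || n0 < 0) abort_invalid("must be a single value >= 0", "n0")
  if (length(lam) != 1 || is.na(lam) || lam <= 0) abort_invalid("growth rate must be > 0", "lam")
  if (length(years) != 1 || is.na(years) || years < 0 || years != round(years)) {
    abort_invalid("must be a non-negative integer", "years")
  }
  out <- n0 * lam^(0:years)
  names(out) <- 0:years
  out
}

#' Configuration for a stochastic projection
#'
#' Bundles and validates the inputs of [project_stochastic()]. Each
#' projected year draws that year's adult survival from a normal
#' distribution truncated to \[0, 1\] and that year's litter size (calves
#' born per cow, i.e. the calf:cow ratio at birth, so twins push it above 1)
#' from a normal truncated to \[0, Inf) -- environmental stochasticity in
#' the vital rates. Optionally a first-year survival rate is drawn and
#' applied to the recruits.
#'
#' @param n0 Starting abundance (animals).
#' @param years Horizon (integer >= 0).
#' @param replicates Number of Monte Carlo replicates (integer >= 1).
#' @param seed Integer RNG seed.
#' @param s_adult_center,s_adult_sd Mean and SD of annual adult survival.
#' @param litter_center,litter_sd Mean and SD of litter size (calves per cow
#'   at birth).
#' @param prop_cows Cow proportion of the population, \[0, 1\].
#' @param s_firstyear_center,s_firstyear_sd Mean and SD of first-year
#'   (birth to age 1) survival applied to recruits when
#'   `include_firstyear_survival` is `TRUE`. The default center (0.35) is
#'   the study-mean calf survival; its SD defaults to 0 because the
#'   published stochastic run varied only adult survival and litter size.
#' @param include_firstyear_survival Apply first-year survival to recruits?
#'   Default `TRUE`: litter size is a calf:cow ratio at birth, so without
#'   this discount every newborn would be recruited and the update would
#'   badly overstate growth. Set `FALSE` when the litter distribution
#'   already expresses recruits.
#' @param mode `"expected"` (default): fractional animals, expected-value
#'   dynamics. `"demographic"`: integer animals with binomial survivors and
#'   Poisson recruits, adding demographic stochasticity.
#' @return A validated list of class `projection_config`.
#' @examples
#' cfg <- projection_config(n0 = 4350, years = 30, replicates = 1000, seed = 42,
#'                          s_adult_center = 0.85, s_adult_sd = 0.04,
#'                          litter_center = 1.12, litter_sd = 0.32,
#'                          prop_cows = 0.48)
#' @export
projection_config <- function(n0 = 4350, years = 30, replicates = 1000,
                              seed = 1,
                              s_adult_center = 0.85, s_adult_sd = 0.04,
                              litter_center = 1.12, litter_sd = 0.32,
                              prop_cows = 0.48,
                              s_firstyear_center = 0.35, s_firstyear_sd = 0,
                              include_firstyear_survival = TRUE,
                              mode = c("expected", "demographic")) {
  mode <- match.arg(mode)
  if (n0 < 0) abort_invalid("must be >= 0", "n0")
  if (years < 0 || years != round(years)) abort_invalid("must be a non-negative integer", "years")
  if (replicates < 1 || replicates != round(replicates)) {
    abort_invalid("must be an integer >= 1", "replicates")
  }
  for (nm in c("s_adult_sd", "litter_sd", "s_firstyear_sd")) {
    if (get(nm) < 0) abort_invalid("standard deviation must be >= 0", nm)
  }
  check_prob(s_adult_center, "s_adult_center")
  check_prob(prop_cows, "prop_cows")
  check_prob(s_firstyear_center, "s_firstyear_center")
  if (litter_center < 0) abort_invalid("must be >= 0", "litter_center")
  out <- list(n0 = n0, years = as.integer(years),
              replicates = as.integer(replicates), seed = as.integer(seed),
              s_adult_center = s_adult_center, s_adult_sd = s_adult_sd,
              litter_center = litter_center, litter_sd = litter_sd,
              prop_cows = prop_cows,
              s_firstyear_center = s_firstyear_center,
              s_firstyear_sd = s_firstyear_sd,
              include_firstyear_survival = isTRUE(include_firstyear_survival),
              mode = mode)
  class(out) <- "projection_config"
  out
}

# Truncated-normal draws by rejection; sd = 0 collapses to the (clamped)
# center. The rejection loop is capped so a pathological configuration
# (center far outside the bounds) fails loudly instead of spinning.
rtruncnorm_capped <- function(n, mean, sd, lower = -Inf, upper = Inf,
                              max_tries = 10000) {
  if (sd == 0) {
    x <- rep(mean, n)
    if (any(x < lower | x > upper)) abort_domain("degenerate draw outside truncation bounds")
    return(x)
  }
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (i in seq_len(max_tries)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  abort_domain(sprintf(
    "truncated-normal rejection failed after %d rounds (mean %g, sd %g on [%g, %g])",
    max_tries, mean, sd, lower, upper))
}

# Deterministic per-replicate substream seed, so replicate i's trajectory
# does not depend on how many replicates are run. Kept below 2^31 (and the
# intermediate product below 2^53, where doubles are exact).
replicate_seed <- function(seed, i) {
  as.integer(((seed %% 2147483647) * 69069 + i * 7919) %% 2147483647) + 1L
}

#' Stochastic birth-pulse population projection
#'
#' Monte Carlo projection under year-to-year environmental stochasticity in
#' adult survival and litter size. Each replicate and year draws
#' \eqn{S_t \sim N(\mu_S, \sigma_S)} truncated to \[0, 1\] and
#' \eqn{L_t \sim N(\mu_L, \sigma_L)} truncated to \[0, Inf), then applies
#' the birth-pulse update
#' \deqn{N_{t+1} = N_t S_t + N_t \cdot propcows \cdot L_t \cdot S^{(0)}_t}
#' where the first-year survival factor \eqn{S^{(0)}_t} is drawn only when
#' `include_firstyear_survival` is set (otherwise 1, i.e. the litter-size
#' distribution is taken to already express recruits). Abundance is floored
#' at zero and zero is absorbing (extinction).
#'
#' Identical configurations (including `seed`) give bit-identical results,
#' and each replicate uses its own RNG substream derived from
#' `(seed, replicate index)`.
#'
#' @param config A [projection_config()].
#' @param keep_draws Keep the sampled vital rates (`replicates x years`
#'   matrices `draws_s`, `draws_l`, `draws_s0`) in the result? Useful for
#'   auditing the truncation bounds.
#' @return An object of class `projection_result`: list with `trajectories`
#'   (`replicates x (years+1)` matrix, column 0 constant at `n0`),
#'   `lambda_per_rep` (per-replicate realized rate \eqn{(N_T/N_0)^{1/T}};
#'   0 for extinct replicates), `lambda_mean`, `lambda_sd`, `lambda_se`,
#'   `extinct_fraction`, and the `config`.
#' @examples
#' res <- project_stochastic(projection_config(replicates = 100, seed = 7))
#' res$lambda_mean
#' @export
project_stochastic <- function(config, keep_draws = FALSE) {
  stopifnot(inherits(config, "projection_config"))
  yrs <- config$years
  reps <- config$replicates
  traj <- matrix(NA_real_, nrow = reps, ncol = yrs + 1,
                 dimnames = list(NULL, 0:yrs))
  traj[, 1] <- config$n0
  ds <- dl <- d0 <- if (keep_draws && yrs > 0) matrix(NA_real_, reps, yrs) else NULL

  for (i in seq_len(reps)) {
    set.seed(replicate_seed(config$seed, i))
    if (yrs > 0) {
      s  <- rtruncnorm_capped(yrs, config$s_adult_center, config$s_adult_sd, 0, 1)
      l  <- rtruncnorm_capped(yrs, config$litter_center, config$litter_sd, 0, Inf)
      s0 <- if (config$include_firstyear_survival) {
        rtruncnorm_capped(yrs, config$s_firstyear_center, config$s_firstyear_sd, 0, 1)
      } else rep(1, yrs)
      n <- config$n0
      for (t in seq_len(yrs)) {
        if (config$mode == "demographic") {
          n_int <- round(n)
          survivors <- if (n_int > 0) stats::rbinom(1, n_int, s[t]) else 0
          recruits <- stats::rpois(1, n_int * config$prop_cows * l[t] * s0[t])
          n <- survivors + recruits
        } else {
          n <- n * s[t] + n * config$prop_cows * l[t] * s0[t]
        }
        n <- max(0, n)
        traj[i, t + 1] <- n
      }
      if (keep_draws) { ds[i, ] <- s; dl[i, ] <- l; d0[i, ] <- s0 }
    }
  }

  lambda_per_rep <- if (yrs > 0 && config$n0 > 0) {
    (traj[, yrs + 1] / config$n0)^(1 / yrs)
  } else rep(NA_real_, reps)
  extinct <- if (yrs > 0) mean(traj[, yrs + 1] == 0) else 0

  out <- list(trajectories = traj,
              lambda_per_rep = lambda_per_rep,
              lambda_mean = mean(lambda_per_rep),
              lambda_sd = if (reps > 1) stats::sd(lambda_per_rep) else NA_real_,
              lambda_se = if (reps > 1) stats::sd(lambda_per_rep) / sqrt(reps) else NA_real_,
              extinct_fraction = extinct,
              config = config)
  if (keep_draws) out[c("draws_s", "draws_l", "draws_s0")] <- list(ds, dl, d0)
  class(out) <- "projection_result"
  out
}

#' Summaries of the per-replicate realized growth rates
#'
#' Arithmetic mean, sample SD and SE (`sd / sqrt(replicates)`) of the
#' per-replicate geometric-mean growth rates of a stochastic projection.
#' Replicates absorbed at zero contribute a realized rate of 0 and are
#' reported through `extinct_fraction`.
#'
#' @param result A `projection_result` from [project_stochastic()].
#' @return Named list: `mean`, `sd`, `se`, `extinct_fraction`, `replicates`.
#' @export
stochastic_lambda_summary <- function(result) {
  stopifnot(inherits(result, "projection_result"))
  lam <- result$lambda_per_rep
  if (length(lam) < 2 || all(is.na(lam))) {
    abort_invalid("needs >= 2 replicates with a projected horizon", "result")
  }
  if (result$extinct_fraction >= 1) {
    abort_domain("all replicates went extinct; see extinct_fraction and the trajectories")
  }
  list(mean = mean(lam), sd = stats::sd(lam), se = stats::sd(lam) / sqrt(length(lam)),
       extinct_fraction = result$extinct_fraction, replicates = length(lam))
}

#' @export
print.projection_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Stochastic projection: N0 = %g, %d years, %d replicates (seed %d, %s mode)\n",
    cfg$n0, cfg$years, cfg$replicates, cfg$seed, cfg$mode))
  cat(sprintf("  realized lambda: mean %.4f, sd %.4f, se %.4f; extinct %.1f%%\n",
              x$lambda_mean, x$lambda_sd, x$lambda_se, 100 * x$extinct_fraction))
  fin <- x$trajectories[, ncol(x$trajectories)]
  q <- stats::quantile(fin, c(0.05, 0.5, 0.95))
  cat(sprintf("  final abundance: median %.0f (5th-95th pct %.0f-%.0f)\n",
              q[2], q[1], q[3]))
  invisible(x)
}
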