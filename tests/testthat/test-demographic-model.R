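# Closed-form demography: growth rates, R-M equation, calf production,
# recruitment and the derived table.

test_that("survey growth rate is the geometric annual rate", {
  expect_equal(round_half_up(growth_rate_survey(2760, 4350, 1)), 1.58)
  expect_equal(round_half_up(growth_rate_survey(4350, 3450, 1)), 0.79)
  expect_equal(growth_rate_survey(5000, 5000, 7), 1.0)
  # multiplicative over concatenated intervals: two-year rate is the
  # geometric mean of the annual rates
  for (seed in 1:20) {
    set.seed(seed)
    n <- cumprod(c(runif(1, 1000, 9000), runif(2, 0.5, 2)))
    expect_equal(growth_rate_survey(n[1], n[3], 2),
                 sqrt(growth_rate_survey(n[1], n[2], 1) *
                      growth_rate_survey(n[2], n[3], 1)),
                 tolerance = 1e-12)
  }
  expect_error(growth_rate_survey(0, 100, 1), "n0", class = "rmgrowth_invalid_input")
  expect_error(growth_rate_survey(100, -5, 1), "nt", class = "rmgrowth_invalid_input")
  expect_error(growth_rate_survey(100, 100, 0), "t", class = "rmgrowth_invalid_input")
})

test_that("R-M equation maps mortality and recruitment to growth", {
  expect_equal(round_half_up(rm_lambda(0.14, 0.20)), 1.08)
  expect_identical(rm_lambda(0.15, 0.15), 1)
  expect_identical(rm_lambda(0, 0), 1)
  expect_error(rm_lambda(0.1, 1), class = "rmgrowth_domain_error")
  expect_error(rm_lambda(1.2, 0.1), class = "rmgrowth_invalid_input")
})

test_that("mortality back-calculation inverts the R-M equation", {
  expect_equal(round_half_up(100 * backcalc_mortality(1.58, 0.15), 0), -34)
  expect_equal(backcalc_mortality(1, 0), 0)
  expect_equal(backcalc_mortality(0.9, 0.3), 0.37)  # 1 - 0.9 * 0.7
  # inverse identity over a grid
  set.seed(101)
  lam <- runif(200, 1e-3, 3)
  r <- runif(200, 0, 0.9)
  m <- backcalc_mortality(lam, r)
  ok <- m >= 0 & m <= 1  # rm_lambda only accepts proper mortality rates
  expect_gt(sum(ok), 50)
  expect_equal(rm_lambda(m[ok], r[ok]), lam[ok], tolerance = 1e-12)
  # outside [0,1] the algebraic identity still holds
  expect_equal((1 - m) / (1 - r), lam, tolerance = 1e-12)
})

test_that("calf production is the pregnant-cow expectation, linear in adults", {
  expect_equal(calf_production(1000, 0.5, 0, 0.3), 0)
  expect_equal(calf_production(1000, 0.5, 0.8, 0), 400)
  # direct arithmetic oracle at the sensitivity baseline
  expect_equal(calf_production(5593, 0.48, 0.83, 0.30),
               5593 * 0.48 * 0.83 * 1.30, tolerance = 1e-12)
  expect_equal(round(calf_production(5593, 0.48, 0.83, 0.30), 1), 2896.7)
  # degree-1 homogeneity and monotonicity in each rate
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 0, 9000); k <- runif(1, 0.1, 5)
    r3 <- runif(3)
    expect_equal(calf_production(k * a, r3[1], r3[2], r3[3]),
                 k * calf_production(a, r3[1], r3[2], r3[3]), tolerance = 1e-12)
    d <- runif(1, 0, 1 - max(r3))
    base <- calf_production(a, r3[1], r3[2], r3[3])
    expect_gte(calf_production(a, r3[1] + d, r3[2], r3[3]), base)
    expect_gte(calf_production(a, r3[1], r3[2] + d, r3[3]), base)
    expect_gte(calf_production(a, r3[1], r3[2], r3[3] + d), base)
  }
  expect_error(calf_production(100, 1.2, 0.5, 0.5), class = "rmgrowth_invalid_input")
})

test_that("study recruitment is lagged survived calf crop per capita", {
  expect_equal(recruitment_study(0.28, 1040, 2760), 0.28 * 1040 / 2760)
  expect_equal(round_half_up(recruitment_study(0.40, 1732, 3450)), 0.20)
  expect_equal(recruitment_study(0, 1040, 2760), 0)
  expect_error(recruitment_study(0.3, 1000, 0), "n_prev",
               class = "rmgrowth_invalid_input")
})

test_that("derived table reproduces the fixture's printed columns", {
  d <- derive_table(fixture_survey(), fixture_vitals())
  expect_s3_class(d, "derived_demography")
  expect_equal(d$year, 2013:2017)
  # calf production to the printed animal
  expect_equal(round(d$calf_production), c(1040, 1747, 1732, 1893, 1824))
  # growth rate columns at printed precision
  expect_true(is.na(d$lambda_rm[1]))
  expect_equal(round_half_up(d$lambda_rm[2:5]), c(0.90, 1.05, 1.08, 1.00))
  expect_equal(round_half_up(d$lambda_survey[2:5]), c(1.58, 0.79, 1.17, 0.92))
  # recruitment column keeps the two printed digits
  expect_equal(trunc(d$r_study[2:5] * 100) / 100, c(0.10, 0.16, 0.20, 0.15))
  expect_true(all(abs(d$r_study[2:5] - c(0.10, 0.16, 0.20, 0.15)) < 0.01))
  # mortality columns
  expect_equal(d$m_adult[1:4], c(0.19, 0.12, 0.14, 0.15))
  expect_equal(round_half_up(100 * d$m_backcalc[2], 0), -34)
  # summary footer
  s <- derive_summary(d)
  expect_equal(round_half_up(s$mean[s$quantity == "lambda_rm"]), 1.01)
  expect_equal(round_half_up(s$se[s$quantity == "lambda_rm"]), 0.04)
  expect_equal(round_half_up(s$se[s$quantity == "lambda_survey"]), 0.17)
})

test_that("exact mode satisfies the R-M identity; lagged alignment is the default", {
  d <- derive_table(fixture_survey(), fixture_vitals(), lambda_inputs = "exact")
  m_prev <- c(NA, d$m_adult[-5])
  ok <- !is.na(d$lambda_rm)
  expect_equal(d$lambda_rm[ok] * (1 - d$r_study[ok]) + m_prev[ok],
               rep(1, sum(ok)), tolerance = 1e-12)
  # same-year mode uses the current year's mortality instead
  d2 <- derive_table(fixture_survey(), fixture_vitals(),
                     lambda_inputs = "exact", m_alignment = "same_year")
  expect_equal(d2$lambda_rm[2:4] * (1 - d2$r_study[2:4]) + d2$m_adult[2:4],
               rep(1, 3), tolerance = 1e-12)
  expect_true(is.na(d2$lambda_rm[5]))  # 2017 has no same-year mortality
})

test_that("derived table handles degenerate series and bad input", {
  one <- derive_table(fixture_survey()[2, ], fixture_vitals()[2, ])
  expect_true(all(is.na(c(one$lambda_survey, one$lambda_rm, one$r_study))))
  expect_false(is.na(one$calf_production))

  dup <- rbind(fixture_survey(), fixture_survey()[3, ])
  expect_error(derive_table(dup[order(dup$year), ], fixture_vitals()),
               "duplicate", class = "rmgrowth_invalid_input")

  # a gap in years: lagged fields stay NA on the far side of the gap
  gap <- fixture_survey()[-2, ]
  dg <- derive_table(gap, fixture_vitals()[-2, ])
  expect_true(is.na(dg$lambda_rm[dg$year == 2015]))
  expect_false(is.na(dg$lambda_rm[dg$year == 2016]))
})

test_that("a closed constant population with M = R gives lambda exactly 1", {
  # brute-force oracle: iterate N(t+1) = N(t)(1 - M) + recruits with the
  # recruit stream chosen so recruits/N(t+1) = R = M
  m <- 0.15; r <- 0.15; n <- 5000
  for (t in 1:10) {
    n_next <- n * (1 - m) / (1 - r)
    recruits <- r * n_next
    expect_equal(n * (1 - m) + recruits, n_next, tolerance = 1e-9)
    expect_equal(n_next / n, rm_lambda(m, r), tolerance = 1e-9)
    n <- n_next
  }
  expect_equal(n, 5000, tolerance = 1e-6)
})

test_that("R-M consistency holds on growing and declining closed populations", {
  for (pars in list(c(0.10, 0.25), c(0.3, 0.05), c(0.15, 0.15))) {
    m <- pars[1]; r <- pars[2]
    n <- 4000
    traj <- numeric(8)
    traj[1] <- n
    for (t in 2:8) {
      n_next <- n * (1 - m) / (1 - r)   # solves N(t+1) = N(t)(1-M) + R*N(t+1)
      expect_equal(n * (1 - m) + r * n_next, n_next, tolerance = 1e-9)
      traj[t] <- n <- n_next
    }
    realized <- traj[-1] / traj[-8]
    expect_equal(realized, rep(rm_lambda(m, r), 7), tolerance = 1e-9)
  }
})

test_that("percent decline matches the long-term survey drop", {
  expect_equal(round_half_up(percent_decline(8840, 3710), 0), 58)
  expect_equal(percent_decline(100, 100), 0)
  expect_lt(percent_decline(100, 150), 0)
})
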