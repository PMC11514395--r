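test_that("mortality curve fitting recovers exact polynomials", {
  ages <- c(47, 52, 57, 62, 67, 72, 77, 82)
  # construct-then-fit: exact quadratic is recovered to machine precision
  true_coef <- c(2e-3, -1e-4, 2e-6)
  tab <- data.frame(age_mid = ages,
                    rate = true_coef[1] + true_coef[2] * ages + true_coef[3] * ages^2)
  fit <- fit_mortality_curve(tab, degree = 2)
  expect_equal(unname(fit$coefficients), true_coef, tolerance = 1e-9)
  expect_equal(unname(predict(fit, 55)),
               sum(true_coef * 55^(0:2)), tolerance = 1e-9)

  # constant rates give a constant curve
  flat <- fit_mortality_curve(data.frame(age_mid = ages, rate = 0.01), degree = 2)
  expect_equal(unname(predict(flat, c(50, 70, 80))), rep(0.01, 3), tolerance = 1e-9)

  # degree 0 is the mean of the rates (closed-form least squares)
  r <- c(0.01, 0.02, 0.04, 0.05)
  d0 <- fit_mortality_curve(data.frame(age_mid = ages[1:4], rate = r), degree = 0)
  expect_equal(unname(predict(d0, 60)), mean(r), tolerance = 1e-12)

  # insufficient support and out-of-range rates are rejected
  expect_error(fit_mortality_curve(data.frame(age_mid = c(50, 55), rate = c(.1, .2)),
                                   degree = 2), "degree")
  expect_error(fit_mortality_curve(data.frame(age_mid = ages, rate = 2)), "\\[0, 1\\]")
  # evaluation clamps to [0, 1]
  steep <- fit_mortality_curve(data.frame(age_mid = ages, rate = seq(.1, .94, length.out = 8)),
                               degree = 1)
  expect_lte(max(predict(steep, 200)), 1)
  expect_gte(min(predict(steep, 0)), 0)
})

test_that("annual-to-cycle probability conversion matches the closed form", {
  expect_equal(per_cycle_probability(0, 0.25), 0)
  expect_equal(per_cycle_probability(1, 0.25), 1)
  expect_equal(per_cycle_probability(0.04, 0.25), 1 - 0.96^0.25)
  expect_equal(per_cycle_probability(0.04, 0.25), 0.0101536, tolerance = 1e-5)
  expect_error(per_cycle_probability(1.2, 0.25), "\\[0, 1\\]")
  expect_error(per_cycle_probability(0.1, 0), "> 0")
})

test_that("transition matrices are valid and age-monotone in mortality", {
  p <- base_params()
  for (variant in c("reconciled", "as_printed")) {
    p$markov$variant <- variant
    for (s in c("PGX", "SOC")) {
      P <- build_transition_matrix(s, 60, p)
      expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
      expect_true(all(P >= 0))
      expect_equal(P["SUICIDE_DEATH", "SUICIDE_DEATH"], 1)
      expect_equal(P["NONSUICIDE_DEATH", "NONSUICIDE_DEATH"], 1)
      P50 <- build_transition_matrix(s, 50, p)
      P80 <- build_transition_matrix(s, 80, p)
      expect_gt(P80["RESPONSE", "NONSUICIDE_DEATH"], P50["RESPONSE", "NONSUICIDE_DEATH"])
      # frozen mortality when age trends are off
      Poff <- build_transition_matrix(s, 80, p, age_trends = FALSE)
      expect_equal(Poff["RESPONSE", "NONSUICIDE_DEATH"],
                   build_transition_matrix(s, p$markov$start_age, p)["RESPONSE", "NONSUICIDE_DEATH"])
    }
  }
})

test_that("overfull transition rows are renormalized with a warning", {
  p <- base_params()
  p$transitions$relapse_onset[1] <- 0.7
  p$transitions$no_response_onset[1] <- 0.5
  expect_warning(P <- build_transition_matrix("PGX", 60, p), "renormaliz")
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
})

test_that("cohort occupancy is conserved and absorbing states never shrink", {
  for (seed in 1:25) {
    p <- random_parameter_set(synthetic_spec(seed = seed))
    tr <- run_cohort(if (seed %% 2) "PGX" else "SOC", p)$trace
    occ <- tr[, c("RESPONSE", "RELAPSE", "NO_RESPONSE", "SUICIDE_DEATH",
                  "NONSUICIDE_DEATH")]
    expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
    expect_true(all(diff(occ$SUICIDE_DEATH) >= -1e-12))
    expect_true(all(diff(occ$NONSUICIDE_DEATH) >= -1e-12))
  }
})

test_that("degenerate cohorts produce the closed-form rewards", {
  p <- base_params()
  # no exits from response, no discounting: LY equals the horizon
  p$transitions[, c("relapse_onset", "no_response_onset", "suicide_death")] <- 0
  p$mortality$rate <- 0
  res <- run_cohort("PGX", p, discount_on = FALSE)
  expect_equal(res$totals$LY, p$markov$end_age - p$markov$start_age, tolerance = 1e-9)
  # QALY <= LY always
  expect_lte(res$totals$QALY, res$totals$LY)

  # everyone to suicide death after the first cycle: one cycle of rewards
  p2 <- base_params()
  p2$markov$variant <- "as_printed"
  p2$transitions$suicide_death <- 1
  p2$transitions[, c("relapse_onset", "no_response_onset")] <- 0
  p2$mortality$rate <- 0
  res2 <- run_cohort("PGX", p2, discount_on = FALSE)
  expect_equal(res2$totals$LY, p2$markov$cycle_length, tolerance = 1e-9)
  expect_equal(res2$trace$SUICIDE_DEATH[2], 1, tolerance = 1e-12)
  # death states accrue no QALYs
  expect_equal(res2$totals$QALY,
               p2$markov$cycle_length * p2$utilities$response$utility[1],
               tolerance = 1e-9)
})

test_that("half-cycle correction reweights exactly the first and last cycles", {
  p <- base_params()
  # freeze the cohort in the response state so per-cycle rewards are constant
  # up to discounting; the half-cycle totals then differ by half of the
  # first plus last cycle rewards
  p$transitions[, c("relapse_onset", "no_response_onset", "suicide_death")] <- 0
  p$mortality$rate <- 0
  p$utilities$response$utility <- rep(0.8, 5)
  full <- run_cohort("PGX", p, half_cycle = FALSE)
  half <- run_cohort("PGX", p, half_cycle = TRUE)
  n <- nrow(full$trace)
  expect_equal(full$totals$LY - half$totals$LY,
               0.5 * (full$trace$LY[1] + full$trace$LY[n]), tolerance = 1e-9)
  expect_equal(full$totals$QALY - half$totals$QALY,
               0.5 * (full$trace$QALY[1] + full$trace$QALY[n]), tolerance = 1e-9)
})

test_that("discounting and horizon shortening only ever reduce totals", {
  p <- base_params()
  for (s in c("PGX", "SOC")) {
    disc <- run_cohort(s, p)
    undisc <- run_cohort(s, p, discount_on = FALSE)
    expect_lte(disc$totals$LY, undisc$totals$LY)
    expect_lte(disc$totals$QALY, undisc$totals$QALY)
    expect_lte(disc$totals$total_cost, undisc$totals$total_cost)
    five <- run_cohort(s, p, horizon_years = 5)
    expect_lte(five$totals$LY, disc$totals$LY)
    expect_lte(five$totals$QALY, disc$totals$QALY)
    expect_lte(five$totals$total_cost, disc$totals$total_cost)
  }
})

test_that("rewards respond monotonically to utilities and suicide risk", {
  p <- base_params()
  base <- run_cohort("PGX", p)$totals
  up <- set_parameter(p, "utilities.relapse", min(1, p$utilities$relapse + 0.2))
  expect_gte(run_cohort("PGX", up)$totals$QALY, base$QALY)
  p2 <- p
  p2$markov$variant <- "as_printed"
  base2 <- run_cohort("PGX", p2)$totals
  worse <- set_parameter(p2, "transitions.PGX.suicide_death",
                         min(1, p2$transitions$suicide_death[p2$transitions$strategy == "PGX"] + 0.1))
  expect_lte(run_cohort("PGX", worse)$totals$LY, base2$LY)
})

test_that("an individual-level Markov microsimulation matches the cohort expectations", {
  p <- base_params()
  for (s in c("PGX", "SOC")) {
    ms <- microsim_markov(s, p, n = 1e5, seed = 7)
    ct <- run_cohort(s, p)$totals
    expect_lt(abs(ms$LY - ct$LY), 3 * ms$se_LY)
    expect_lt(abs(ms$QALY - ct$QALY), 3 * ms$se_QALY)
    expect_lt(abs(ms$cost - ct$total_cost), 3 * ms$se_cost)
  }
})

test_that("the compiled Markov evaluator agrees exactly with run_cohort", {
  for (seed in c(3, 8)) {
    p <- random_parameter_set(synthetic_spec(seed = seed))
    cm <- pgxcea:::compile_model(p)
    for (s in c("PGX", "SOC")) {
      f <- pgxcea:::eval_long_fast(cm, s)
      r <- run_cohort(s, p)$totals
      expect_equal(unname(f[["LY"]]), r$LY, tolerance = 1e-10)
      expect_equal(unname(f[["QALY"]]), r$QALY, tolerance = 1e-10)
      expect_equal(unname(f[["cost"]]), r$total_cost, tolerance = 1e-8)
    }
  }
})

test_that("identical strategy blocks give zero increments", {
  p <- base_params()
  soc_tr <- p$transitions[p$transitions$strategy == "SOC", ]
  pgx_tr <- soc_tr; pgx_tr$strategy <- "PGX"
  p$transitions <- rbind(pgx_tr, soc_tr)
  soc_d <- p$disposition[p$disposition$strategy == "SOC", ]
  pgx_d <- soc_d; pgx_d$strategy <- "PGX"
  p$disposition <- rbind(pgx_d, soc_d)
  p$costs_long[["acquisition_PGX"]] <- p$costs_long[["acquisition_SOC"]]
  cmp <- compare_long_term(p)
  expect_equal(cmp$delta_ly, 0, tolerance = 1e-12)
  expect_equal(cmp$delta_qaly, 0, tolerance = 1e-12)
  expect_equal(cmp$delta_cost, 0, tolerance = 1e-9)
})
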