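#' Fit a polynomial mortality curve to age-group rates
#'
#' Age-group mortality rates are plotted against the band midpoint age and a
#' least-squares polynomial (default quadratic) gives per-year-of-age annual
#' rates; evaluation is clamped to \[0, 1\].
#'
#' @param age_group_table data.frame with columns `age_mid` (band midpoint,
#'   years) and `rate` (annual mortality fraction).
#' @param degree Polynomial degree (default 2).
#' @return Object of class `pgx_mortality_curve` with a `predict()` method.
#' @export
#' @examples
#' tab <- data.frame(age_mid = c(47, 52, 57, 62), rate = c(.002, .003, .005, .008))
#' curve <- fit_mortality_curve(tab)
#' predict(curve, 55)
fit_mortality_curve <- function(age_group_table, degree = 2) {
  stopifnot(all(c("age_mid", "rate") %in% names(age_group_table)))
  if (any(age_group_table$rate < 0 | age_group_table$rate > 1)) {
    stop("mortality rates must lie in [0, 1]", call. = FALSE)
  }
  if (length(unique(age_group_table$age_mid)) < degree + 1) {
    stop("need at least degree + 1 distinct midpoint ages", call. = FALSE)
  }
  x <- age_group_table$age_mid
  X <- outer(x, 0:degree, `^`)
  coef <- qr.solve(X, age_group_table$rate)
  structure(list(coefficients = coef, degree = degree,
                 age_range = range(x)),
            class = "pgx_mortality_curve")
}

#' @export
predict.pgx_mortality_curve <- function(object, newdata, ...) {
  age <- if (is.list(newdata)) newdata$age_mid else newdata
  val <- drop(outer(age, 0:object$degree, `^`) %*% object$coefficients)
  pmin(pmax(val, 0), 1)
}

#' @export
print.pgx_mortality_curve <- function(x, ...) {
  cat("<pgx_mortality_curve> degree", x$degree, "polynomial, coefficients:",
      signif(x$coefficients, 6), "\n")
  invisible(x)
}

#' Convert an annual event probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p_annual)^cycle_years`.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param cycle_years Cycle length in years (> 0).
#' @return Per-cycle probability.
#' @export
per_cycle_probability <- function(p_annual, cycle_years) {
  if (any(p_annual < 0 | p_annual > 1)) {
    stop("p_annual must lie in [0, 1]", call. = FALSE)
  }
  if (any(cycle_years <= 0)) stop("cycle_years must be > 0", call. = FALSE)
  1 - (1 - p_annual)^cycle_years
}

# Long-term transition inputs for one strategy, resolved per variant.
# Structure (both variants): from RESPONSE a cohort member can move to
# RELAPSE (relapse_onset), NO_RESPONSE (no_response_onset) or die; RELAPSE
# returns to RESPONSE at relapse_remission; NO_RESPONSE returns at
# response_return; death states are absorbing. Variants differ in the
# suicide hazard: "as_printed" keeps the published per-cycle suicide-death
# entry (applied from RESPONSE), "reconciled" derives per-state suicide
# hazards from the short-term disposition attempt shares times
# P(death | attempt), since the printed per-cycle value is not clinically
# plausible as a rate. The printed non-suicide-death entry is superseded by
# the age-specific mortality schedule in both variants.
transition_inputs <- function(params, strategy) {
  tr <- params$transitions[params$transitions$strategy == strategy, ]
  if (nrow(tr) != 1) stop("no transition row for strategy ", strategy, call. = FALSE)
  drow <- params$disposition[params$disposition$strategy == strategy, ]
  att_rel <- context_dispositions(drow, "relapse")[["SUICIDE_ATTEMPT"]]
  att_nr <- context_dispositions(drow, "no_response")[["SUICIDE_ATTEMPT"]]
  p_death <- drow$p_suicide_death_given_attempt
  if (identical(params$markov$variant, "as_printed")) {
    sd_R <- tr$suicide_death; sd_L <- 0; sd_N <- 0
    att_rate_L <- 0; att_rate_N <- 0
  } else {
    sd_R <- (tr$relapse_onset * att_rel + tr$no_response_onset * att_nr) * p_death
    sd_L <- att_rel * p_death
    sd_N <- att_nr * p_death
    att_rate_L <- att_rel; att_rate_N <- att_nr
  }
  list(rl = tr$relapse_onset, rn = tr$no_response_onset,
       lr = tr$relapse_remission, nr = tr$response_return,
       sd_R = sd_R, sd_L = sd_L, sd_N = sd_N,
       att_rate_L = att_rate_L, att_rate_N = att_rate_N,
       att_share_R = if (identical(params$markov$variant, "as_printed")) 0 else
         (tr$relapse_onset * att_rel + tr$no_response_onset * att_nr))
}

#' Per-cycle transition matrix at a given age
#'
#' Builds the 5x5 matrix over states RESPONSE, RELAPSE, NO_RESPONSE,
#' SUICIDE_DEATH, NONSUICIDE_DEATH. The non-suicide-death column comes from
#' the fitted mortality curve converted to the cycle length (frozen at the
#' start age when `age_trends` is off); each living row is closed by
#' assigning the remainder to self-transition, and death rows are absorbing.
#' If a row's off-diagonal entries exceed 1 the row is renormalized with a
#' warning.
#'
#' @param strategy `"PGX"` or `"SOC"`.
#' @param age Age (years) at the start of the cycle.
#' @param params A `pgx_parameters` object.
#' @param age_trends Apply the age trend in mortality? Defaults to the value
#'   in `params$markov`.
#' @param curve Optionally a prefitted `pgx_mortality_curve`.
#' @return 5x5 transition matrix, rows summing to 1.
#' @export
build_transition_matrix <- function(strategy, age, params,
                                    age_trends = NULL, curve = NULL) {
  age_trends <- age_trends %||% params$markov$age_trends
  if (is.null(curve)) curve <- fit_mortality_curve(params$mortality,
                                                   params$mortality_fit$degree %||% 2)
  eval_age <- if (isTRUE(age_trends)) age else params$markov$start_age
  m <- per_cycle_probability(predict(curve, eval_age), params$markov$cycle_length)
  ti <- transition_inputs(params, strategy)
  P <- matrix(0, 5, 5, dimnames = list(HEALTH_STATES, HEALTH_STATES))
  P["RESPONSE", ] <- c(0, ti$rl, ti$rn, ti$sd_R, m)
  P["RELAPSE", ] <- c(ti$lr, 0, 0, ti$sd_L, m)
  P["NO_RESPONSE", ] <- c(ti$nr, 0, 0, ti$sd_N, m)
  for (s in c("RESPONSE", "RELAPSE", "NO_RESPONSE")) {
    off <- sum(P[s, ]) - P[s, s]
    if (off > 1) {
      warning("transition row for ", s, " exceeds 1 (sum = ", signif(off, 6),
              "); renormalizing", call. = FALSE)
      P[s, ] <- P[s, ] / off
      off <- 1
    }
    P[s, s] <- 1 - off
  }
  P["SUICIDE_DEATH", "SUICIDE_DEATH"] <- 1
  P["NONSUICIDE_DEATH", "NONSUICIDE_DEATH"] <- 1
  P
}

response_utility_lookup <- function(params, age) {
  ur <- params$utilities$response
  i <- findInterval(floor(age), ur$age_min)
  i[i < 1] <- 1
  ur$utility[i]
}

#' Run the lifetime cohort simulation for one strategy
#'
#' Closed-cohort simulation from the start age (default 48) to the end age
#' (default 81) in 3-month cycles. Everyone enters the response state;
#' per-cycle occupancy is advanced by the age-appropriate transition matrix.
#' Rewards are accumulated on start-of-cycle occupancy and discounted
#' continuously at the annual rate: 0.25 life-years per living cycle,
#' utility-weighted QALYs (response utility by current age band; fixed
#' relapse and no-response utilities), per-cycle costs for medication
#' acquisition, lab/screening and follow-up while alive, and event costs.
#' Event costs are charged on incident transitions by default
#' (`event_cost_cadence = "incident"`); `"per_cycle"` charges the relapse
#' event cost for every cycle spent in the relapse state instead. The
#' survival event cost is charged once to the mass still alive at the
#' horizon. With `half_cycle` the first and last cycle rewards are weighted
#' one half (trapezoidal correction).
#'
#' @param strategy `"PGX"` or `"SOC"`.
#' @param params A `pgx_parameters` object.
#' @param half_cycle,age_trends,horizon_years,discount_on Optional overrides
#'   of the corresponding `params$markov` settings (`horizon_years` limits the
#'   simulated span; `discount_on = FALSE` sets the rate to zero).
#' @return Object of class `pgx_cohort_trace`: a per-cycle `trace` data frame
#'   (occupancies and discounted rewards) plus per-person `totals` (LY, QALY,
#'   costs by category) and the cohort-scaled totals.
#' @export
run_cohort <- function(strategy, params, half_cycle = NULL, age_trends = NULL,
                       horizon_years = NULL, discount_on = TRUE) {
  mk <- params$markov
  half_cycle <- half_cycle %||% mk$half_cycle
  age_trends <- age_trends %||% mk$age_trends
  cyc <- mk$cycle_length
  horizon <- min(horizon_years %||% mk$horizon_years %||% Inf,
                 mk$end_age - mk$start_age)
  n_cyc <- max(1L, round(horizon / cyc))
  rate <- if (discount_on) mk$discount_rate else 0

  curve <- fit_mortality_curve(params$mortality, params$mortality_fit$degree %||% 2)
  ages <- mk$start_age + cyc * (seq_len(n_cyc) - 1)
  m_vec <- per_cycle_probability(
    predict(curve, if (isTRUE(age_trends)) ages else rep(mk$start_age, n_cyc)), cyc)
  u_resp <- response_utility_lookup(params, ages)
  df <- discount_factor(cyc * (seq_len(n_cyc) - 1), rate)
  w <- rep(1, n_cyc)
  if (isTRUE(half_cycle)) { w[1] <- 0.5; w[n_cyc] <- 0.5 }

  ti <- transition_inputs(params, strategy)
  cl <- params$costs_long
  acq <- cl[[paste0("acquisition_", strategy)]]
  per_cycle_relapse <- identical(mk$event_cost_cadence, "per_cycle")

  occ <- c(R = 1, L = 0, N = 0, SD = 0, ND = 0)
  trace <- matrix(0, n_cyc, 12,
                  dimnames = list(NULL, c("cycle", "age", "RESPONSE", "RELAPSE",
                                          "NO_RESPONSE", "SUICIDE_DEATH",
                                          "NONSUICIDE_DEATH", "LY", "QALY",
                                          "cost_events", "cost_medications",
                                          "cost_care")))
  tot <- c(LY = 0, QALY = 0, events = 0, medications = 0,
           screening_lab = 0, follow_up = 0)
  for (t in seq_len(n_cyc)) {
    m <- m_vec[t]
    p_R <- c(ti$rl, ti$rn, ti$sd_R, m)           # to L, N, SD, ND
    p_L <- c(ti$lr, ti$sd_L, m)                  # to R, SD, ND
    p_N <- c(ti$nr, ti$sd_N, m)                  # to R, SD, ND
    if (sum(p_R) > 1) p_R <- p_R / sum(p_R)
    if (sum(p_L) > 1) p_L <- p_L / sum(p_L)
    if (sum(p_N) > 1) p_N <- p_N / sum(p_N)
    alive <- occ[["R"]] + occ[["L"]] + occ[["N"]]
    wd <- w[t] * df[t]

    ly <- cyc * alive
    qaly <- cyc * (occ[["R"]] * u_resp[t] + occ[["L"]] * params$utilities$relapse +
                     occ[["N"]] * params$utilities$no_response)
    meds <- acq * alive
    lab <- cl[["lab_screening"]] * alive
    fu <- cl[["follow_up"]] * alive

    inc_L <- occ[["R"]] * p_R[1]
    inc_SD <- occ[["R"]] * p_R[3] + occ[["L"]] * p_L[2] + occ[["N"]] * p_N[2]
    inc_ND <- occ[["R"]] * p_R[4] + occ[["L"]] * p_L[3] + occ[["N"]] * p_N[3]
    attempts <- ti$att_share_R * occ[["R"]] +
      ti$att_rate_L * occ[["L"]] + ti$att_rate_N * occ[["N"]]
    ev <- cl[["suicide_death_event"]] * inc_SD +
      cl[["nonsuicide_death_event"]] * inc_ND +
      cl[["suicide_attempt_event"]] * attempts +
      cl[["relapse_event"]] * (if (per_cycle_relapse) occ[["L"]] else inc_L)

    tot <- tot + wd * c(ly, qaly, ev, meds, lab, fu)
    trace[t, ] <- c(t, ages[t], occ, wd * c(ly, qaly, ev, meds, lab + fu))

    occ <- c(R = occ[["R"]] * (1 - sum(p_R)) + occ[["L"]] * p_L[1] + occ[["N"]] * p_N[1],
             L = occ[["L"]] * (1 - sum(p_L)) + occ[["R"]] * p_R[1],
             N = occ[["N"]] * (1 - sum(p_N)) + occ[["R"]] * p_R[2],
             SD = occ[["SD"]] + inc_SD,
             ND = occ[["ND"]] + inc_ND)
  }
  alive_end <- occ[["R"]] + occ[["L"]] + occ[["N"]]
  tot[["events"]] <- tot[["events"]] +
    cl[["survival_event"]] * alive_end * discount_factor(cyc * n_cyc, rate)

  totals <- as.list(tot)
  totals$total_cost <- tot[["events"]] + tot[["medications"]] +
    tot[["screening_lab"]] + tot[["follow_up"]]
  structure(list(
    strategy = strategy,
    trace = as.data.frame(trace),
    totals = totals,
    final_occupancy = occ,
    cohort_size = mk$cohort_size,
    cohort_totals = lapply(totals, function(x) x * mk$cohort_size),
    settings = list(half_cycle = half_cycle, age_trends = age_trends,
                    horizon_years = horizon, discount_rate = rate,
                    variant = mk$variant)
  ), class = "pgx_cohort_trace")
}

#' @export
print.pgx_cohort_trace <- function(x, ...) {
  cat(sprintf("<pgx_cohort_trace> %s (%s): %.3f LY, %.3f QALY, %.0f QAR/person over %g y\n",
              x$strategy, x$settings$variant, x$totals$LY, x$totals$QALY,
              x$totals$total_cost, x$settings$horizon_years))
  invisible(x)
}

#' Compare strategies over the lifetime Markov model
#'
#' Runs the cohort simulation for both arms and reports per-person
#' incremental discounted life-years, QALYs, cost saving (standard-of-care
#' cost minus guided cost) with category-level differences, and ICER /
#' dominance classifications per life-year and per QALY.
#'
#' @param params A `pgx_parameters` object.
#' @param ... Flag overrides passed to [run_cohort()] (`half_cycle`,
#'   `age_trends`, `horizon_years`, `discount_on`).
#' @return Object of class `pgx_long_comparison`.
#' @export
compare_long_term <- function(params, ...) {
  pgx <- run_cohort("PGX", params, ...)
  soc <- run_cohort("SOC", params, ...)
  delta_cost <- pgx$totals$total_cost - soc$totals$total_cost
  d_ly <- pgx$totals$LY - soc$totals$LY
  d_qaly <- pgx$totals$QALY - soc$totals$QALY
  wtp <- params$settings$wtp
  structure(list(
    PGX = pgx, SOC = soc,
    delta_ly = d_ly, delta_qaly = d_qaly,
    delta_cost = delta_cost, saving = -delta_cost,
    delta_by_category = sapply(c("events", "medications", "screening_lab", "follow_up"),
                               function(k) soc$totals[[k]] - pgx$totals[[k]]),
    icer_ly = classify_icer(delta_cost, d_ly, wtp),
    icer_qaly = classify_icer(delta_cost, d_qaly, wtp)
  ), class = "pgx_long_comparison")
}

#' @export
print.pgx_long_comparison <- function(x, ...) {
  cat("<pgx_long_comparison> lifetime Markov cohort, PGx-guided vs standard of care\n")
  cat(sprintf("  LY/person: %.4f vs %.4f (diff %+.4f)\n",
              x$PGX$totals$LY, x$SOC$totals$LY, x$delta_ly))
  cat(sprintf("  QALY/person: %.4f vs %.4f (diff %+.4f)\n",
              x$PGX$totals$QALY, x$SOC$totals$QALY, x$delta_qaly))
  cat(sprintf("  cost/person: %.0f vs %.0f QAR (saving %+.0f)\n",
              x$PGX$totals$total_cost, x$SOC$totals$total_cost, x$saving))
  cat(sprintf("  ICER per QALY: %s\n", x$icer_qaly$label))
  invisible(x)
}
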