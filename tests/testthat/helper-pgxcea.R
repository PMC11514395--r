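# Shared fixtures and independent patient-level oracles.

base_params <- function() load_parameters()

# Patient-level microsimulation of the 6-week tree, written directly against
# the parameter tables (independent of enumerate_pathways / the compiled
# evaluator). Returns means and Monte-Carlo standard errors.
microsim_short <- function(strategy, params, n = 2e5, seed = 42) {
  set.seed(seed)
  cells <- data.frame(
    gene = params$prevalence$gene,
    class = params$prevalence$class,
    carrier = ifelse(params$prevalence$class == "NORMAL", "NONCARRIER", "CARRIER"),
    w = unname(params$settings$gene_weights[params$prevalence$gene]) *
      params$prevalence$prevalence
  )
  cell <- sample.int(nrow(cells), n, replace = TRUE, prob = cells$w)
  cl <- params$clinical[params$clinical$strategy == strategy, ]
  key <- paste(cl$gene, cl$class, cl$carrier)
  row <- match(paste(cells$gene, cells$class, cells$carrier)[cell], key)
  pr <- cl$p_response[row]
  prel <- cl$p_relapse_given_response[row]
  pse <- cl$p_side_effect[row]

  responded <- stats::runif(n) < pr
  se <- responded & stats::runif(n) < pse
  relapsed <- responded & stats::runif(n) < prel

  d <- params$disposition[params$disposition$strategy == strategy, ]
  w_rel <- c(SWITCH = d$p_switch, OBSERVE = d$p_observe,
             DISCONTINUE = d$p_discontinue, SUICIDE_ATTEMPT = d$p_suicide_attempt)
  w_nr <- c(SWITCH = d$p_switch, TITRATE = d$p_titrate, OBSERVE = d$p_observe,
            DISCONTINUE = d$p_discontinue, SUICIDE_ATTEMPT = d$p_suicide_attempt)
  disp <- rep(NA_character_, n)
  i_rel <- which(relapsed)
  disp[i_rel] <- sample(names(w_rel), length(i_rel), replace = TRUE,
                        prob = w_rel / sum(w_rel))
  i_nr <- which(!responded)
  disp[i_nr] <- sample(names(w_nr), length(i_nr), replace = TRUE,
                       prob = w_nr / sum(w_nr))
  attempt <- !is.na(disp) & disp == "SUICIDE_ATTEMPT"
  died <- attempt & stats::runif(n) < d$p_suicide_death_given_attempt

  aq <- params$acquisition[params$acquisition$strategy == strategy, ]
  arow <- match(paste(cells$gene, cells$class)[cell], paste(aq$gene, aq$class))
  fl <- aq$first_line[arow]
  alt <- params$settings$alternative_course_override %||% fl
  if (length(alt) == 1) alt <- rep(alt, n)
  inc <- aq$increased_dose[arow]
  dhalf <- if (isTRUE(params$settings$discontinuation_half_rule)) fl / 2 else
    aq$discontinuation[arow]
  cs <- params$costs_short

  cost <- rep(cs[["lab_screening"]] + cs[["consultation"]] +
                if (strategy == "PGX") cs[["genotyping_panel"]] else 0, n)
  acqc <- fl
  acqc[!is.na(disp) & disp == "SWITCH"] <- (fl + alt)[!is.na(disp) & disp == "SWITCH"]
  acqc[!is.na(disp) & disp == "TITRATE"] <- (fl + inc)[!is.na(disp) & disp == "TITRATE"]
  acqc[!is.na(disp) & disp == "DISCONTINUE"] <- (dhalf + alt)[!is.na(disp) & disp == "DISCONTINUE"]
  ia <- which(attempt)
  acqc[ia] <- fl[ia] + cs[["suicide_attempt_event"]] +
    ifelse(died[ia], cs[["suicide_death_event"]],
           cs[["survival_event"]] + alt[ia])
  cost <- cost + acqc + se * cs[["side_effect_management"]] +
    relapsed * cs[["relapse_event"]]

  s1 <- responded & !se & !relapsed
  s2 <- responded & !relapsed
  if (isTRUE(params$settings$count_alternative_success)) {
    rescued <- !is.na(disp) & (disp %in% c("SWITCH", "DISCONTINUE") | (attempt & !died))
    s1 <- s1 | rescued; s2 <- s2 | rescued
  }
  list(p_no_se = mean(s1), se_p_no_se = stats::sd(s1) / sqrt(n),
       p_any_se = mean(s2), se_p_any_se = stats::sd(s2) / sqrt(n),
       cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n))
}

# Patient-level Markov microsimulation: samples individual trajectories from
# the same per-cycle transition matrices and accumulates discounted rewards,
# as an independent check of the cohort-expectation algebra.
microsim_markov <- function(strategy, params, n = 1e5, seed = 42) {
  set.seed(seed)
  mk <- params$markov
  cyc <- mk$cycle_length
  n_cyc <- round(min(mk$horizon_years %||% Inf, mk$end_age - mk$start_age) / cyc)
  ages <- mk$start_age + cyc * (seq_len(n_cyc) - 1)
  df <- discount_factor(cyc * (seq_len(n_cyc) - 1), mk$discount_rate)
  ti <- pgxcea:::transition_inputs(params, strategy)
  cl <- params$costs_long
  acq <- cl[[paste0("acquisition_", strategy)]]
  percyc <- acq + cl[["lab_screening"]] + cl[["follow_up"]]
  per_cycle_relapse <- identical(mk$event_cost_cadence, "per_cycle")
  u_rel <- params$utilities$relapse
  u_nr <- params$utilities$no_response

  state <- rep(1L, n)  # 1 R, 2 L, 3 N, 4 SD, 5 ND
  LY <- QALY <- COST <- numeric(n)
  att_rate <- c(ti$att_share_R, ti$att_rate_L, ti$att_rate_N)
  for (t in seq_len(n_cyc)) {
    P <- build_transition_matrix(strategy, ages[t], params)
    alive <- state <= 3L
    u_resp <- pgxcea:::response_utility_lookup(params, ages[t])
    LY[alive] <- LY[alive] + df[t] * cyc
    QALY <- QALY + df[t] * cyc *
      ifelse(state == 1L, u_resp, ifelse(state == 2L, u_rel,
                                         ifelse(state == 3L, u_nr, 0)))
    COST[alive] <- COST[alive] + df[t] * (percyc + cl[["suicide_attempt_event"]] *
                                            att_rate[state[alive]])
    if (per_cycle_relapse) {
      COST[state == 2L] <- COST[state == 2L] + df[t] * cl[["relapse_event"]]
    }
    new_state <- state
    for (s in 1:3) {
      idx <- which(state == s)
      if (!length(idx)) next
      new_state[idx] <- sample.int(5L, length(idx), replace = TRUE, prob = P[s, ])
    }
    moved_L <- state == 1L & new_state == 2L
    if (!per_cycle_relapse) {
      COST[moved_L] <- COST[moved_L] + df[t] * cl[["relapse_event"]]
    }
    COST[state <= 3L & new_state == 4L] <-
      COST[state <= 3L & new_state == 4L] + df[t] * cl[["suicide_death_event"]]
    COST[state <= 3L & new_state == 5L] <-
      COST[state <= 3L & new_state == 5L] + df[t] * cl[["nonsuicide_death_event"]]
    state <- new_state
  }
  dfe <- discount_factor(cyc * n_cyc, mk$discount_rate)
  COST[state <= 3L] <- COST[state <= 3L] + dfe * cl[["survival_event"]]
  list(LY = mean(LY), se_LY = stats::sd(LY) / sqrt(n),
       QALY = mean(QALY), se_QALY = stats::sd(QALY) / sqrt(n),
       cost = mean(COST), se_cost = stats::sd(COST) / sqrt(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
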