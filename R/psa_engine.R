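# Internal compiled representation of the model for repeated evaluation
# (probabilistic sensitivity analysis). The reference implementations are
# enumerate_pathways()/strategy_outcomes() and run_cohort(); the test suite
# asserts that the compiled path reproduces them exactly.

compile_model <- function(params) {
  cells <- tree_cells(params)
  half_rule <- isTRUE(params$settings$discontinuation_half_rule)
  short <- list()
  for (s in STRATEGIES) {
    pr <- prel <- pse <- fl <- inc <- dhalf <- numeric(nrow(cells))
    for (k in seq_len(nrow(cells))) {
      cl <- clinical_row(params, s, cells$gene[k], cells$class[k], cells$carrier[k])
      aq <- acquisition_row(params, s, cells$gene[k], cells$class[k])
      pr[k] <- cl$p_response; prel[k] <- cl$p_relapse_given_response
      pse[k] <- cl$p_side_effect
      fl[k] <- aq$first_line; inc[k] <- aq$increased_dose
      dhalf[k] <- if (half_rule) aq$first_line / 2 else aq$discontinuation
    }
    short[[s]] <- list(w = cells$weight, pr = pr, prel = prel, pse = pse,
                       fl = fl, alt = fl, inc = inc, dhalf = dhalf)
  }
  disp <- list()
  for (s in STRATEGIES) {
    d <- params$disposition[params$disposition$strategy == s, ]
    disp[[s]] <- c(sw = d$p_switch, ti = d$p_titrate, ob = d$p_observe,
                   di = d$p_discontinue, sa = d$p_suicide_attempt,
                   death = d$p_suicide_death_given_attempt)
  }
  long <- list()
  for (s in STRATEGIES) {
    tr <- params$transitions[params$transitions$strategy == s, ]
    long[[s]] <- c(rl = tr$relapse_onset, rn = tr$no_response_onset,
                   lr = tr$relapse_remission, nr = tr$response_return,
                   sd_printed = tr$suicide_death)
  }
  mk <- params$markov
  cyc <- mk$cycle_length
  horizon <- min(mk$horizon_years %||% Inf, mk$end_age - mk$start_age)
  n_cyc <- max(1L, round(horizon / cyc))
  ages <- mk$start_age + cyc * (seq_len(n_cyc) - 1)
  curve <- fit_mortality_curve(params$mortality, params$mortality_fit$degree %||% 2)
  m_vec <- per_cycle_probability(
    predict(curve, if (isTRUE(mk$age_trends)) ages else rep(mk$start_age, n_cyc)), cyc)
  band_idx <- findInterval(floor(ages), params$utilities$response$age_min)
  band_idx[band_idx < 1] <- 1

  list(
    short = short, disp = disp, long = long,
    costs_short = params$costs_short,
    costs_long = params$costs_long,
    u_band = params$utilities$response$utility,
    u_rel = params$utilities$relapse,
    u_nr = params$utilities$no_response,
    band_idx = band_idx, m_vec = m_vec, ages = ages,
    n_cyc = n_cyc, cyc = cyc,
    discount = mk$discount_rate,
    variant = mk$variant,
    per_cycle_relapse = identical(mk$event_cost_cadence, "per_cycle"),
    half_cycle = isTRUE(mk$half_cycle),
    count_rescue = isTRUE(params$settings$count_alternative_success),
    alt_override = params$settings$alternative_course_override
  )
}

context_shares_vec <- function(d) {
  rel <- d[c("sw", "ob", "di", "sa")]
  nr <- d[c("sw", "ti", "ob", "di", "sa")]
  list(rel = rel / sum(rel), nr = nr / sum(nr), death = d[["death"]])
}

eval_short_fast <- function(cm, strategy) {
  s <- cm$short[[strategy]]
  d <- context_shares_vec(cm$disp[[strategy]])
  cs <- cm$costs_short
  alt <- if (is.null(cm$alt_override)) s$alt else rep(cm$alt_override, length(s$alt))
  pdeath <- d$death
  p_rel_branch <- s$pr * s$prel
  p_nr <- 1 - s$pr

  base <- cs[["lab_screening"]] + cs[["consultation"]] +
    if (strategy == "PGX") cs[["genotyping_panel"]] else 0
  attempt_cost <- cs[["suicide_attempt_event"]] +
    pdeath * cs[["suicide_death_event"]] +
    (1 - pdeath) * (cs[["survival_event"]] + alt)
  acq_rel <- d$rel[["sw"]] * (s$fl + alt) + d$rel[["ob"]] * s$fl +
    d$rel[["di"]] * (s$dhalf + alt) + d$rel[["sa"]] * (s$fl + attempt_cost)
  acq_nr <- d$nr[["sw"]] * (s$fl + alt) + d$nr[["ti"]] * (s$fl + s$inc) +
    d$nr[["ob"]] * s$fl + d$nr[["di"]] * (s$dhalf + alt) +
    d$nr[["sa"]] * (s$fl + attempt_cost)
  cost <- base +
    s$pr * (1 - s$prel) * s$fl + p_rel_branch * acq_rel + p_nr * acq_nr +
    s$pr * s$pse * cs[["side_effect_management"]] +
    p_rel_branch * cs[["relapse_event"]]

  p1 <- s$pr * (1 - s$pse) * (1 - s$prel)
  p2 <- s$pr * (1 - s$prel)
  if (cm$count_rescue) {
    resc_rel <- d$rel[["sw"]] + d$rel[["di"]] + d$rel[["sa"]] * (1 - pdeath)
    resc_nr <- d$nr[["sw"]] + d$nr[["di"]] + d$nr[["sa"]] * (1 - pdeath)
    rescue <- p_rel_branch * resc_rel + p_nr * resc_nr
    p1 <- p1 + rescue
    p2 <- p2 + rescue
  }
  c(p_no_se = sum(s$w * p1), p_any_se = sum(s$w * p2), cost = sum(s$w * cost))
}

eval_long_fast <- function(cm, strategy, discount = NULL) {
  v <- cm$long[[strategy]]
  d <- context_shares_vec(cm$disp[[strategy]])
  if (identical(cm$variant, "as_printed")) {
    sd_R <- v[["sd_printed"]]; sd_L <- 0; sd_N <- 0
    att_R <- 0; att_L <- 0; att_N <- 0
  } else {
    att_rel <- d$rel[["sa"]]; att_nr <- d$nr[["sa"]]
    att_R <- v[["rl"]] * att_rel + v[["rn"]] * att_nr
    att_L <- att_rel; att_N <- att_nr
    sd_R <- att_R * d$death; sd_L <- att_L * d$death; sd_N <- att_N * d$death
  }
  cl <- cm$costs_long
  acq <- cl[[paste0("acquisition_", strategy)]]
  rate <- discount %||% cm$discount
  n <- cm$n_cyc
  df <- (1 + rate)^(-(cm$cyc * (seq_len(n) - 1)))
  w <- rep(1, n)
  if (cm$half_cycle) { w[1] <- 0.5; w[n] <- 0.5 }
  wd <- w * df
  u_resp <- cm$u_band[cm$band_idx]
  R <- 1; L <- 0; N <- 0
  LY <- QALY <- COST <- 0
  for (t in seq_len(n)) {
    m <- cm$m_vec[t]
    pR <- c(v[["rl"]], v[["rn"]], sd_R, m)
    pL <- c(v[["lr"]], sd_L, m)
    pN <- c(v[["nr"]], sd_N, m)
    sR <- sum(pR); if (sR > 1) { pR <- pR / sR; sR <- 1 }
    sL <- sum(pL); if (sL > 1) { pL <- pL / sL; sL <- 1 }
    sN <- sum(pN); if (sN > 1) { pN <- pN / sN; sN <- 1 }
    alive <- R + L + N
    inc_L <- R * pR[1]
    inc_SD <- R * pR[3] + L * pL[2] + N * pN[2]
    inc_ND <- R * pR[4] + L * pL[3] + N * pN[3]
    attempts <- att_R * R + att_L * L + att_N * N
    ev <- cl[["suicide_death_event"]] * inc_SD +
      cl[["nonsuicide_death_event"]] * inc_ND +
      cl[["suicide_attempt_event"]] * attempts +
      cl[["relapse_event"]] * (if (cm$per_cycle_relapse) L else inc_L)
    LY <- LY + wd[t] * cm$cyc * alive
    QALY <- QALY + wd[t] * cm$cyc * (R * u_resp[t] + L * cm$u_rel + N * cm$u_nr)
    COST <- COST + wd[t] * (ev + alive * (acq + cl[["lab_screening"]] + cl[["follow_up"]]))
    R_new <- R * (1 - sR) + L * pL[1] + N * pN[1]
    L <- L * (1 - sL) + inc_L
    N <- N * (1 - sN) + R * pR[2]
    R <- R_new
  }
  COST <- COST + cl[["survival_event"]] * (R + L + N) * (1 + rate)^(-(cm$cyc * n))
  c(LY = LY, QALY = QALY, cost = COST)
}

# Map a parameter identifier onto the compiled structure; returns a setter
# closure cm -> cm or NULL when the parameter does not feed the compiled
# evaluators (e.g. unused cost items).
compiled_setter <- function(params, parameter) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  comp <- parts[1]
  cells <- tree_cells(params)
  if (comp == "clinical") {
    s <- parts[2]
    k <- which(cells$gene == parts[3] & cells$class == parts[4])
    field <- c(p_response = "pr", p_relapse_given_response = "prel",
               p_side_effect = "pse")[[parts[5]]]
    if (!length(k)) return(NULL)
    return(function(cm, v) { cm$short[[s]][[field]][k] <- v; cm })
  }
  if (comp == "disposition") {
    s <- parts[2]
    field <- c(p_switch = "sw", p_titrate = "ti", p_observe = "ob",
               p_discontinue = "di", p_suicide_attempt = "sa",
               p_suicide_death_given_attempt = "death")[[parts[3]]]
    return(function(cm, v) { cm$disp[[s]][[field]] <- v; cm })
  }
  if (comp == "acquisition") {
    s <- parts[2]
    k <- which(cells$gene == parts[3] & cells$class == parts[4])
    if (!length(k)) return(NULL)
    half_rule <- isTRUE(params$settings$discontinuation_half_rule)
    if (parts[5] == "first_line") {
      return(function(cm, v) {
        cm$short[[s]]$fl[k] <- v
        cm$short[[s]]$alt[k] <- v
        if (half_rule) cm$short[[s]]$dhalf[k] <- v / 2
        cm
      })
    }
    if (parts[5] == "increased_dose") {
      return(function(cm, v) { cm$short[[s]]$inc[k] <- v; cm })
    }
    if (!half_rule && parts[5] == "discontinuation") {
      return(function(cm, v) { cm$short[[s]]$dhalf[k] <- v; cm })
    }
    return(NULL)
  }
  if (comp == "costs_short") {
    it <- parts[2]
    if (!it %in% names(params$costs_short)) return(NULL)
    return(function(cm, v) { cm$costs_short[[it]] <- v; cm })
  }
  if (comp == "costs_long") {
    it <- parts[2]
    if (!it %in% names(params$costs_long)) return(NULL)
    return(function(cm, v) { cm$costs_long[[it]] <- v; cm })
  }
  if (comp == "utilities") {
    if (parts[2] == "response") {
      j <- match(as.numeric(parts[3]), params$utilities$response$age_min)
      return(function(cm, v) { cm$u_band[j] <- v; cm })
    }
    if (parts[2] == "relapse") return(function(cm, v) { cm$u_rel <- v; cm })
    if (parts[2] == "no_response") return(function(cm, v) { cm$u_nr <- v; cm })
    return(NULL)
  }
  if (comp == "transitions") {
    s <- parts[2]
    field <- c(relapse_onset = "rl", no_response_onset = "rn",
               relapse_remission = "lr", response_return = "nr",
               suicide_death = "sd_printed")[parts[3]]
    if (is.na(field)) return(NULL)
    field <- unname(field)
    return(function(cm, v) { cm$long[[s]][[field]] <- v; cm })
  }
  if (comp == "markov" && parts[2] == "discount_rate") {
    return(function(cm, v) { cm$discount <- v; cm })
  }
  NULL
}
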