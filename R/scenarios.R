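SCENARIOS <- c("BASE", "UNDISCOUNTED", "NO_AGE_TRENDS", "HORIZON_5Y",
               "ALT_DULOXETINE", "HALF_CYCLE")

#' Apply a named scenario to a parameter set
#'
#' Pure function: returns a modified copy, touching only the documented
#' flags/parameters. `UNDISCOUNTED` zeroes the Markov discount rate (the
#' 6-week tree is never discounted), `NO_AGE_TRENDS` freezes mortality at
#' the start-age value, `HORIZON_5Y` truncates the Markov horizon to 5
#' years, `ALT_DULOXETINE` swaps the alternative-course acquisition cost to
#' the configured duloxetine course cost (both arms), `HALF_CYCLE` turns on
#' the trapezoidal half-cycle correction, `BASE` changes nothing.
#'
#' @param scenario One of `r paste(SCENARIOS, collapse = ", ")`.
#' @param params A `pgx_parameters` object.
#' @return A modified `pgx_parameters` object.
#' @export
apply_scenario <- function(scenario, params) {
  if (!scenario %in% SCENARIOS) {
    stop("unknown scenario: ", scenario, " (expected one of ",
         paste(SCENARIOS, collapse = ", "), ")", call. = FALSE)
  }
  switch(scenario,
    BASE = params,
    UNDISCOUNTED = { params$markov$discount_rate <- 0; params },
    NO_AGE_TRENDS = { params$markov$age_trends <- FALSE; params },
    HORIZON_5Y = { params$markov$horizon_years <- 5; params },
    ALT_DULOXETINE = {
      params$settings$alternative_course_override <-
        params$settings$duloxetine_course_cost
      params
    },
    HALF_CYCLE = { params$markov$half_cycle <- TRUE; params }
  )
}

run_scenarios <- function(params) {
  rows <- lapply(SCENARIOS, function(sc) {
    p2 <- apply_scenario(sc, params)
    st <- compare_short_term(p2)
    lt <- compare_long_term(p2)
    data.frame(scenario = sc,
               short_term_saving = st$saving,
               long_term_saving = lt$saving,
               delta_ly = lt$delta_ly,
               delta_qaly = lt$delta_qaly)
  })
  do.call(rbind, rows)
}

manifest_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis and write a report bundle
#'
#' Runs the requested stages on a validated parameter set and writes
#' machine-readable CSV/JSON outputs: a base-case table shaped like the
#' published results table (success probabilities, expected costs, LY/QALY
#' and ICER labels per strategy and increment), a six-row scenario table,
#' univariate sweep results, PSA draws with CEAC and tornado tables, the
#' audit pathway tables, and a run manifest (seed, package version, config
#' hash, variant, and a warning when the mortality schedule is synthetic).
#'
#' @param params A `pgx_parameters` object.
#' @param which Stages to run, subset of
#'   `c("base", "scenarios", "univariate", "psa")`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the PSA stage.
#' @param n_psa Number of PSA draws.
#' @return Invisibly, a list with the computed objects and file paths.
#' @export
run_report <- function(params, which = c("base", "scenarios"), out_dir,
                       seed = 1L, n_psa = 1000L) {
  validate_parameters(params)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  paths <- character()
  emit <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  out <- list()

  if ("base" %in% which) {
    st <- compare_short_term(params)
    lt <- compare_long_term(params)
    base_tab <- data.frame(
      section = c(rep("short_term", 4), rep("long_term", 8)),
      outcome = c("response_no_se_no_relapse", "response_any_se_no_relapse",
                  "total_cost", "icer_no_se",
                  "life_years", "qaly", "cost_events", "cost_medications",
                  "cost_screening_lab", "cost_follow_up", "total_cost",
                  "icer_qaly"),
      PGX = c(st$PGX$p_success_no_se, st$PGX$p_success_any_se,
              st$PGX$expected_cost, NA,
              lt$PGX$totals$LY, lt$PGX$totals$QALY, lt$PGX$totals$events,
              lt$PGX$totals$medications, lt$PGX$totals$screening_lab,
              lt$PGX$totals$follow_up, lt$PGX$totals$total_cost, NA),
      SOC = c(st$SOC$p_success_no_se, st$SOC$p_success_any_se,
              st$SOC$expected_cost, NA,
              lt$SOC$totals$LY, lt$SOC$totals$QALY, lt$SOC$totals$events,
              lt$SOC$totals$medications, lt$SOC$totals$screening_lab,
              lt$SOC$totals$follow_up, lt$SOC$totals$total_cost, NA),
      difference = c(st$delta_p_no_se, st$delta_p_any_se, st$saving,
                     NA, lt$delta_ly, lt$delta_qaly,
                     lt$delta_by_category[["events"]],
                     lt$delta_by_category[["medications"]],
                     lt$delta_by_category[["screening_lab"]],
                     lt$delta_by_category[["follow_up"]], lt$saving, NA),
      label = c(rep(NA, 3), st$icer_no_se$label, rep(NA, 7), lt$icer_qaly$label)
    )
    emit(base_tab, "base_case.csv")
    for (s in STRATEGIES) {
      emit(strategy_outcomes(s, params)$pathways,
           paste0("pathways_", tolower(s), ".csv"))
      emit(run_cohort(s, params)$trace, paste0("trace_", tolower(s), ".csv"))
    }
    out$base <- list(short = st, long = lt)
  }
  if ("scenarios" %in% which) {
    out$scenarios <- run_scenarios(params)
    emit(out$scenarios, "scenarios.csv")
  }
  if ("univariate" %in% which) {
    sweeps <- rbind(
      {
        sw <- univariate_sweep(params, "costs_short.genotyping_panel", 0.25, "short_saving")
        data.frame(parameter = sw$parameter, endpoint = sw$endpoint,
                   low = sw$low, base = sw$base, high = sw$high)
      },
      {
        sw <- univariate_sweep(params, "markov.discount_rate", 0.25, "long_saving")
        data.frame(parameter = sw$parameter, endpoint = sw$endpoint,
                   low = sw$low, base = sw$base, high = sw$high)
      }
    )
    out$univariate <- sweeps
    emit(sweeps, "univariate.csv")
  }
  if ("psa" %in% which) {
    psa <- run_psa(params, n = n_psa, seed = seed)
    out$psa <- psa
    emit(psa$draws, "psa_draws.csv")
    wtp_grid <- seq(0, 2 * params$settings$wtp, length.out = 41)
    emit(ceac(psa, wtp_grid), "ceac_long_qaly.csv")
    emit(ceac(psa, wtp_grid, effect = "delta_p_no_se", cost = "delta_cost_short"),
         "ceac_short_no_se.csv")
    emit(tornado_regression(psa, "delta_cost_short"), "tornado_short.csv")
    emit(tornado_regression(psa, "delta_cost_long"), "tornado_long.csv")
  }

  # regression guard: the 6-week tree is unaffected by Markov-only scenarios
  st_base <- compare_short_term(params)$saving
  for (sc in c("UNDISCOUNTED", "NO_AGE_TRENDS", "HORIZON_5Y", "HALF_CYCLE")) {
    st_sc <- compare_short_term(apply_scenario(sc, params))$saving
    if (abs(st_sc - st_base) > 1e-9) {
      stop("internal inconsistency: short-term saving changed under Markov-only scenario ", sc,
           call. = FALSE)
    }
  }

  manifest <- list(
    package = "pgxcea",
    version = as.character(utils::packageVersion("pgxcea")),
    seed = seed,
    n_psa = if ("psa" %in% which) n_psa else NULL,
    stages = which,
    variant = params$markov$variant,
    config_hash = manifest_hash(params),
    synthetic_mortality = isTRUE(params$mortality_fit$synthetic),
    warnings = if (isTRUE(params$mortality_fit$synthetic)) {
      "mortality schedule is a synthetic Gompertz stand-in, not local life-table data"
    } else NULL,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest.json"]] <- mpath
  out$paths <- paths
  invisible(out)
}
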