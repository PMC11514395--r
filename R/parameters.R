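#' @keywords internal
"_PACKAGE"

GENES <- c("CYP2D6", "CYP2C19")
MET_CLASSES <- c("PM", "IM", "RM", "URM", "NORMAL")
STRATEGIES <- c("PGX", "SOC")
HEALTH_STATES <- c("RESPONSE", "RELAPSE", "NO_RESPONSE", "SUICIDE_DEATH", "NONSUICIDE_DEATH")

`%||%` <- function(a, b) if (is.null(a)) b else a

.pgxcea_cache <- new.env(parent = emptyenv())

#' Load and validate a model parameter set
#'
#' Reads the full parameterization of the two-stage cost-effectiveness model
#' (decision tree + lifetime Markov cohort) from a YAML config that references
#' one CSV per table: metabolizer prevalences, clinical probabilities per
#' strategy/gene/carrier/class, failure dispositions, acquisition and event
#' costs, utilities, long-term transition inputs, and Markov settings. The
#' packaged default reproduces the published base case.
#'
#' The bundled mortality schedule is a synthetic Gompertz-like stand-in (no
#' local life table ships with the package); supply `mortality$table` in the
#' config to use real age-group rates.
#'
#' @param source Path to a YAML config, or `NULL` for the packaged default.
#' @param variant Long-term transition parameterization: `"reconciled"`
#'   (default; suicide hazard derived from the short-term attempt rates) or
#'   `"as_printed"` (keeps the published per-cycle suicide-death entries).
#' @return A validated object of class `pgx_parameters`.
#' @export
#' @examples
#' p <- load_parameters()
#' metabolizer_distribution("CYP2D6", p)
load_parameters <- function(source = NULL, variant = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "default", "config.yaml", package = "pgxcea")
    if (!is.null(.pgxcea_cache$default)) {
      params <- .pgxcea_cache$default
      if (!is.null(variant)) params$markov$variant <- variant
      return(params)
    }
    on.exit(if (is.null(variant)) .pgxcea_cache$default <- params)
  }
  if (!file.exists(source)) {
    stop("config file does not exist: ", source, call. = FALSE)
  }
  cfg <- yaml::read_yaml(source)
  dir <- dirname(source)
  need <- c("prevalence", "clinical", "disposition", "acquisition",
            "costs_short", "costs_long", "utilities", "transitions")
  missing_tabs <- setdiff(need, names(cfg$tables))
  if (length(missing_tabs)) {
    stop("schema error: config is missing table entries: ",
         paste(missing_tabs, collapse = ", "), call. = FALSE)
  }
  read_tab <- function(name) {
    path <- file.path(dir, cfg$tables[[name]])
    if (!file.exists(path)) stop("referenced table not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }

  prevalence <- read_tab("prevalence")
  # NORMAL is always the remainder to 1 within each gene
  prevalence <- prevalence[prevalence$class != "NORMAL", , drop = FALSE]
  normals <- do.call(rbind, lapply(split(prevalence, prevalence$gene), function(d) {
    data.frame(gene = d$gene[1], class = "NORMAL", prevalence = 1 - sum(d$prevalence))
  }))
  prevalence <- rbind(prevalence, normals)
  rownames(prevalence) <- NULL

  costs_short <- read_tab("costs_short")
  costs_long <- read_tab("costs_long")
  to_named <- function(d) stats::setNames(d$value, d$item)

  utilities_raw <- read_tab("utilities")
  resp <- utilities_raw[utilities_raw$state == "response", ]
  utilities <- list(
    response = data.frame(age_min = resp$age_min, age_max = resp$age_max,
                          utility = resp$utility),
    relapse = utilities_raw$utility[utilities_raw$state == "relapse"],
    no_response = utilities_raw$utility[utilities_raw$state == "no_response"],
    suicide_attempt = utilities_raw$utility[utilities_raw$state == "suicide_attempt"] %||% 0
  )

  mort_cfg <- cfg$mortality %||% list()
  if (!is.null(mort_cfg$table)) {
    mortality <- utils::read.csv(file.path(dir, mort_cfg$table), stringsAsFactors = FALSE)
    synthetic <- isFALSE(mort_cfg$synthetic %||% FALSE)
    synthetic <- !synthetic
  } else {
    spec <- synthetic_spec(
      mortality_base = mort_cfg$base_rate %||% 0.002,
      mortality_base_age = mort_cfg$base_age %||% 48,
      doubling_years = mort_cfg$doubling_years %||% 8,
      mortality_age_range = c(mort_cfg$age_from %||% 45, mort_cfg$age_to %||% 85),
      band_width = mort_cfg$band_width %||% 5
    )
    mortality <- synthetic_mortality_table(spec)
    synthetic <- TRUE
  }

  params <- structure(list(
    prevalence = prevalence,
    clinical = read_tab("clinical"),
    disposition = read_tab("disposition"),
    acquisition = read_tab("acquisition"),
    costs_short = to_named(costs_short),
    costs_long = to_named(costs_long),
    utilities = utilities,
    transitions = read_tab("transitions"),
    markov = list(
      start_age = cfg$markov$start_age %||% 48,
      end_age = cfg$markov$end_age %||% 81,
      cycle_length = cfg$markov$cycle_length %||% 0.25,
      discount_rate = cfg$markov$discount_rate %||% 0.03,
      cohort_size = cfg$markov$cohort_size %||% 15000,
      variant = variant %||% (cfg$markov$variant %||% "reconciled"),
      event_cost_cadence = cfg$markov$event_cost_cadence %||% "incident",
      age_trends = cfg$markov$age_trends %||% TRUE,
      half_cycle = cfg$markov$half_cycle %||% FALSE
    ),
    mortality = mortality,
    mortality_fit = list(degree = mort_cfg$fit_degree %||% 2,
                         synthetic = synthetic),
    settings = list(
      wtp = cfg$settings$wtp %||% 546000,
      usd_to_qar = cfg$settings$usd_to_qar %||% 3.64,
      gene_weights = unlist(cfg$settings$gene_weights %||%
                              list(CYP2D6 = 0.5, CYP2C19 = 0.5)),
      count_alternative_success = cfg$settings$count_alternative_success %||% FALSE,
      discontinuation_half_rule = cfg$settings$discontinuation_half_rule %||% TRUE,
      duloxetine_course_cost = cfg$settings$duloxetine_course_cost %||% 90
    )
  ), class = "pgx_parameters")
  validate_parameters(params)
  params
}

#' Validate a parameter set
#'
#' Checks the structural schema (required fields/columns present) and the
#' numeric invariants: probabilities and utilities in \[0, 1\], non-negative
#' costs, per-gene non-NORMAL prevalence sums at most 1, positive cycle
#' length, non-negative discount rate, start age before end age. All
#' violations are collected and reported together in the error message.
#'
#' @param params A `pgx_parameters` object.
#' @return `params`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_parameters <- function(params) {
  bad <- character()
  note <- function(msg) bad <<- c(bad, msg)

  required <- c("prevalence", "clinical", "disposition", "acquisition",
                "costs_short", "costs_long", "utilities", "transitions",
                "markov", "mortality", "settings")
  for (f in setdiff(required, names(params))) {
    note(paste0("schema error: missing component '", f, "'"))
  }
  if (length(bad)) stop(paste(bad, collapse = "\n"), call. = FALSE)

  chk_prob <- function(x, what) {
    idx <- which(!is.finite(x) | x < 0 | x > 1)
    for (i in idx) note(paste0(what, "[", i, "] = ", x[i], " outside [0, 1]"))
  }
  chk_cost <- function(x, what) {
    idx <- which(!is.finite(x) | x < 0)
    for (i in idx) note(paste0(what, "[", i, "] = ", x[i], " is negative or non-finite"))
  }

  chk_prob(params$prevalence$prevalence, "prevalence")
  for (g in unique(params$prevalence$gene)) {
    d <- params$prevalence[params$prevalence$gene == g & params$prevalence$class != "NORMAL", ]
    if (sum(d$prevalence) > 1 + 1e-12) {
      note(paste0("non-NORMAL prevalences for ", g, " sum to ", sum(d$prevalence), " > 1"))
    }
  }
  for (col in c("p_response", "p_relapse_given_response", "p_side_effect")) {
    if (!col %in% names(params$clinical)) {
      note(paste0("schema error: clinical table lacks column '", col, "'"))
    } else {
      chk_prob(params$clinical[[col]], paste0("clinical$", col))
    }
  }
  for (col in c("p_switch", "p_titrate", "p_observe", "p_discontinue",
                "p_suicide_attempt", "p_suicide_death_given_attempt")) {
    if (!col %in% names(params$disposition)) {
      note(paste0("schema error: disposition table lacks column '", col, "'"))
    } else {
      chk_prob(params$disposition[[col]], paste0("disposition$", col))
    }
  }
  for (col in c("first_line", "increased_dose", "discontinuation")) {
    if (!col %in% names(params$acquisition)) {
      note(paste0("schema error: acquisition table lacks column '", col, "'"))
    } else {
      chk_cost(params$acquisition[[col]], paste0("acquisition$", col))
    }
  }
  needed_costs <- c("lab_screening", "consultation", "genotyping_panel",
                    "side_effect_management", "relapse_event",
                    "suicide_death_event", "suicide_attempt_event", "survival_event")
  for (it in setdiff(needed_costs, names(params$costs_short))) {
    note(paste0("schema error: costs_short lacks '", it, "'",
                if (it == "genotyping_panel") " (genotyping panel cost)" else ""))
  }
  chk_cost(params$costs_short, "costs_short")
  needed_long <- c("acquisition_PGX", "acquisition_SOC", "lab_screening",
                   "follow_up", "relapse_event", "suicide_death_event",
                   "nonsuicide_death_event", "survival_event")
  for (it in setdiff(needed_long, names(params$costs_long))) {
    note(paste0("schema error: costs_long lacks '", it, "'"))
  }
  chk_cost(params$costs_long, "costs_long")
  chk_prob(params$utilities$response$utility, "utilities$response")
  if (is.unsorted(rev(params$utilities$response$utility))) {
    note("response utilities must be non-increasing across age bands")
  }
  chk_prob(c(params$utilities$relapse, params$utilities$no_response,
             params$utilities$suicide_attempt), "utilities (state)")
  for (col in setdiff(names(params$transitions), "strategy")) {
    chk_prob(params$transitions[[col]], paste0("transitions$", col))
  }
  mk <- params$markov
  if (mk$start_age >= mk$end_age) note("markov: start_age must be < end_age")
  if (mk$cycle_length <= 0) note("markov: cycle_length must be > 0")
  if (mk$discount_rate < 0) note("markov: discount_rate must be >= 0")
  if (!mk$variant %in% c("reconciled", "as_printed")) {
    note(paste0("markov: unknown variant '", mk$variant, "'"))
  }
  chk_prob(params$mortality$rate, "mortality$rate")
  if (params$settings$wtp <= 0) note("settings: wtp must be > 0")
  gw <- params$settings$gene_weights
  if (abs(sum(gw) - 1) > 1e-9) note("settings: gene_weights must sum to 1")

  if (length(bad)) {
    stop("parameter validation failed:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(params)
}

#' Full metabolizer-class distribution for one gene
#'
#' Completes the printed non-NORMAL phenotype prevalences with the NORMAL
#' remainder so the classes form a probability simplex.
#'
#' @param gene `"CYP2D6"` or `"CYP2C19"`.
#' @param prevalences A `pgx_parameters` object, or a data frame with columns
#'   `gene`, `class`, `prevalence` (NORMAL rows, if present, are ignored and
#'   recomputed).
#' @return Named numeric vector over classes, summing to exactly 1.
#' @export
metabolizer_distribution <- function(gene, prevalences) {
  if (inherits(prevalences, "pgx_parameters")) prevalences <- prevalences$prevalence
  d <- prevalences[prevalences$gene == gene & prevalences$class != "NORMAL", ]
  if (any(d$prevalence < 0 | d$prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(d$prevalence)
  if (s > 1 + 1e-12) {
    stop("non-NORMAL prevalences for ", gene, " sum to ", s, " > 1", call. = FALSE)
  }
  out <- stats::setNames(d$prevalence, d$class)
  c(out, NORMAL = 1 - s)
}

#' Write a parameter set back to disk
#'
#' Serializes `params` as a config.yaml plus one CSV per table, in the same
#' layout `load_parameters()` reads, so that a written set round-trips to an
#' identical object.
#'
#' @param params A `pgx_parameters` object.
#' @param dir Output directory (created if needed).
#' @return The path to the written config.yaml, invisibly.
#' @export
write_parameters <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, name) {
    utils::write.csv(d, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
    paste0(name, ".csv")
  }
  u <- params$utilities
  utilities_raw <- rbind(
    data.frame(state = "response", age_min = u$response$age_min,
               age_max = u$response$age_max, utility = u$response$utility),
    data.frame(state = c("relapse", "no_response", "suicide_attempt"),
               age_min = NA, age_max = NA,
               utility = c(u$relapse, u$no_response, u$suicide_attempt))
  )
  named_df <- function(x) data.frame(item = names(x), value = as.numeric(x))
  cfg <- list(
    tables = list(
      prevalence = wr(params$prevalence[params$prevalence$class != "NORMAL", ], "prevalence"),
      clinical = wr(params$clinical, "clinical"),
      disposition = wr(params$disposition, "disposition"),
      acquisition = wr(params$acquisition, "acquisition"),
      costs_short = wr(named_df(params$costs_short), "costs_short"),
      costs_long = wr(named_df(params$costs_long), "costs_long"),
      utilities = wr(utilities_raw, "utilities"),
      transitions = wr(params$transitions, "transitions")
    ),
    markov = params$markov,
    mortality = list(table = wr(params$mortality, "mortality"),
                     fit_degree = params$mortality_fit$degree,
                     synthetic = params$mortality_fit$synthetic),
    settings = c(params$settings[setdiff(names(params$settings), "gene_weights")],
                 list(gene_weights = as.list(params$settings$gene_weights)))
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @export
print.pgx_parameters <- function(x, ...) {
  cat("<pgx_parameters>\n")
  cat("  genes:", paste(unique(x$prevalence$gene), collapse = ", "), "\n")
  cat("  markov:", x$markov$start_age, "->", x$markov$end_age, "y,",
      x$markov$cycle_length, "y cycles, discount", x$markov$discount_rate,
      ", variant", x$markov$variant, "\n")
  cat("  WTP:", x$settings$wtp, "QAR;",
      if (isTRUE(x$mortality_fit$synthetic)) "SYNTHETIC mortality schedule"
      else "user mortality schedule", "\n")
  invisible(x)
}

# ---- parameter addressing (used by sweeps, PSA, tornado) -------------------

cell_key <- function(strategy, gene, class) paste(strategy, gene, class, sep = ".")

#' Enumerate addressable numeric parameters
#'
#' Flattens the parameter set into one row per scalar input with a dotted
#' identifier (e.g. `clinical.PGX.CYP2D6.PM.p_response`,
#' `costs_short.genotyping_panel`, `markov.discount_rate`), its base value
#' and its family (`probability`, `cost`, `utility`, `rate`). Clinical
#' identifiers address both carrier rows at once when they share a value.
#'
#' @param params A `pgx_parameters` object.
#' @return data.frame with columns `parameter`, `value`, `family`.
#' @export
parameter_table <- function(params) {
  rows <- list()
  add <- function(parameter, value, family) {
    rows[[length(rows) + 1]] <<- data.frame(parameter = parameter,
                                            value = value, family = family)
  }
  cl <- params$clinical
  for (i in seq_len(nrow(cl))) {
    if (cl$carrier[i] == "NONCARRIER" && cl$class[i] != "NORMAL") next
    pre <- paste("clinical", cl$strategy[i], cl$gene[i], cl$class[i], sep = ".")
    add(paste0(pre, ".p_response"), cl$p_response[i], "probability")
    add(paste0(pre, ".p_relapse_given_response"), cl$p_relapse_given_response[i], "probability")
    add(paste0(pre, ".p_side_effect"), cl$p_side_effect[i], "probability")
  }
  dp <- params$disposition
  for (i in seq_len(nrow(dp))) {
    for (col in c("p_switch", "p_titrate", "p_observe", "p_discontinue",
                  "p_suicide_attempt", "p_suicide_death_given_attempt")) {
      add(paste("disposition", dp$strategy[i], col, sep = "."), dp[[col]][i], "probability")
    }
  }
  aq <- params$acquisition
  for (i in seq_len(nrow(aq))) {
    pre <- paste("acquisition", aq$strategy[i], aq$gene[i], aq$class[i], sep = ".")
    add(paste0(pre, ".first_line"), aq$first_line[i], "cost")
    add(paste0(pre, ".increased_dose"), aq$increased_dose[i], "cost")
  }
  for (it in names(params$costs_short)) {
    add(paste0("costs_short.", it), params$costs_short[[it]], "cost")
  }
  for (it in names(params$costs_long)) {
    add(paste0("costs_long.", it), params$costs_long[[it]], "cost")
  }
  ur <- params$utilities$response
  for (i in seq_len(nrow(ur))) {
    add(paste0("utilities.response.", ur$age_min[i]), ur$utility[i], "utility")
  }
  add("utilities.relapse", params$utilities$relapse, "utility")
  add("utilities.no_response", params$utilities$no_response, "utility")
  tr <- params$transitions
  for (i in seq_len(nrow(tr))) {
    for (col in setdiff(names(tr), "strategy")) {
      add(paste("transitions", tr$strategy[i], col, sep = "."), tr[[col]][i], "probability")
    }
  }
  add("markov.discount_rate", params$markov$discount_rate, "rate")
  do.call(rbind, rows)
}

#' Read one parameter by identifier
#' @param params A `pgx_parameters` object.
#' @param parameter Dotted identifier as listed by [parameter_table()].
#' @return The scalar value.
#' @export
get_parameter <- function(params, parameter) {
  pt <- parameter_table(params)
  i <- match(parameter, pt$parameter)
  if (is.na(i)) stop("unknown parameter: ", parameter, call. = FALSE)
  pt$value[i]
}

#' Set one parameter by identifier
#'
#' Returns a modified copy; clinical identifiers update both carrier rows.
#' No renormalization happens here — context simplexes are renormalized where
#' they are consumed (decision-tree dispositions, transition-matrix rows).
#'
#' @inheritParams get_parameter
#' @param value New scalar value.
#' @return Modified `pgx_parameters` object.
#' @export
set_parameter <- function(params, parameter, value) {
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  comp <- parts[1]
  if (comp == "clinical") {
    i <- params$clinical$strategy == parts[2] & params$clinical$gene == parts[3] &
      params$clinical$class == parts[4]
    if (!any(i)) stop("unknown parameter: ", parameter, call. = FALSE)
    params$clinical[[parts[5]]][i] <- value
  } else if (comp == "disposition") {
    i <- params$disposition$strategy == parts[2]
    if (!any(i)) stop("unknown parameter: ", parameter, call. = FALSE)
    params$disposition[[parts[3]]][i] <- value
  } else if (comp == "acquisition") {
    i <- params$acquisition$strategy == parts[2] & params$acquisition$gene == parts[3] &
      params$acquisition$class == parts[4]
    if (!any(i)) stop("unknown parameter: ", parameter, call. = FALSE)
    params$acquisition[[parts[5]]][i] <- value
  } else if (comp == "costs_short") {
    if (!parts[2] %in% names(params$costs_short)) stop("unknown parameter: ", parameter, call. = FALSE)
    params$costs_short[[parts[2]]] <- value
  } else if (comp == "costs_long") {
    if (!parts[2] %in% names(params$costs_long)) stop("unknown parameter: ", parameter, call. = FALSE)
    params$costs_long[[parts[2]]] <- value
  } else if (comp == "utilities") {
    if (parts[2] == "response") {
      i <- match(as.numeric(parts[3]), params$utilities$response$age_min)
      if (is.na(i)) stop("unknown parameter: ", parameter, call. = FALSE)
      params$utilities$response$utility[i] <- value
    } else {
      if (!parts[2] %in% c("relapse", "no_response", "suicide_attempt")) {
        stop("unknown parameter: ", parameter, call. = FALSE)
      }
      params$utilities[[parts[2]]] <- value
    }
  } else if (comp == "transitions") {
    i <- params$transitions$strategy == parts[2]
    if (!any(i) || !parts[3] %in% names(params$transitions)) {
      stop("unknown parameter: ", parameter, call. = FALSE)
    }
    params$transitions[[parts[3]]][i] <- value
  } else if (comp == "markov") {
    if (!parts[2] %in% names(params$markov)) stop("unknown parameter: ", parameter, call. = FALSE)
    params$markov[[parts[2]]] <- value
  } else if (comp == "settings") {
    if (!parts[2] %in% names(params$settings)) stop("unknown parameter: ", parameter, call. = FALSE)
    params$settings[[parts[2]]] <- value
  } else {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  params
}
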