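OUTCOMES <- c("RESPONSE_NO_SE_NO_RELAPSE", "RESPONSE_SE_NO_RELAPSE",
              "RESPONSE_NO_SE_RELAPSE", "RESPONSE_SE_RELAPSE", "NO_RESPONSE")
DISPOSITIONS <- c("SWITCH", "TITRATE", "OBSERVE", "DISCONTINUE", "SUICIDE_ATTEMPT")

# Context-specific disposition simplexes. The printed management shares do not
# sum to 1 (PGx: 0.68+0.20+0.25+0.26+0.06 = 1.45); each decision context is
# renormalized over the options it actually offers: titration is available
# after no response but not after relapse.
context_dispositions <- function(disposition_row, context = c("relapse", "no_response")) {
  context <- match.arg(context)
  d <- disposition_row
  if (context == "relapse") {
    w <- c(SWITCH = d$p_switch, OBSERVE = d$p_observe,
           DISCONTINUE = d$p_discontinue, SUICIDE_ATTEMPT = d$p_suicide_attempt)
  } else {
    w <- c(SWITCH = d$p_switch, TITRATE = d$p_titrate, OBSERVE = d$p_observe,
           DISCONTINUE = d$p_discontinue, SUICIDE_ATTEMPT = d$p_suicide_attempt)
  }
  w / sum(w)
}

tree_cells <- function(params) {
  prev <- params$prevalence
  gw <- params$settings$gene_weights
  data.frame(
    gene = prev$gene,
    class = prev$class,
    carrier = ifelse(prev$class == "NORMAL", "NONCARRIER", "CARRIER"),
    weight = unname(gw[prev$gene]) * prev$prevalence
  )
}

clinical_row <- function(params, strategy, gene, class, carrier) {
  cl <- params$clinical
  i <- which(cl$strategy == strategy & cl$gene == gene &
               cl$class == class & cl$carrier == carrier)
  if (length(i) != 1) {
    stop("configuration error: no clinical entry for ",
         paste(strategy, gene, class, carrier), call. = FALSE)
  }
  cl[i, ]
}

acquisition_row <- function(params, strategy, gene, class) {
  aq <- params$acquisition
  i <- which(aq$strategy == strategy & aq$gene == gene & aq$class == class)
  if (length(i) != 1) {
    stop("configuration error: no acquisition cost entry for ",
         paste(strategy, gene, class), call. = FALSE)
  }
  aq[i, ]
}

#' Cost of a single decision-tree pathway
#'
#' Sums the cost components a patient on this root-to-leaf route consumes
#' during the 6-week episode: lab and screening, a consultation visit, the
#' genotyping panel (intervention arm only), first-line drug acquisition
#' (reduced-dose entries apply to PM/IM in the guided arm), side-effect
#' management when the outcome includes side effects, the relapse event cost
#' on relapse outcomes, and the disposition-specific components — a full
#' alternative course on switching, the increased-dose entry on titration,
#' nothing on observation, half the first-line course plus a full alternative
#' on discontinuation (the patient stops at week 3 and the replacement course
#' is assumed successful), and the attempt cost followed by either the death
#' event or the survival event plus an alternative course after a suicide
#' attempt.
#'
#' @param pathway A list or one-row data frame with fields `strategy`, `gene`,
#'   `class`, `outcome`, and optionally `disposition`, `suicide_result`.
#' @param params A `pgx_parameters` object (its cost tables are used).
#' @return Pathway cost in QAR.
#' @export
pathway_cost <- function(pathway, params) {
  p <- as.list(pathway)
  cs <- params$costs_short
  aq <- acquisition_row(params, p$strategy, p$gene, p$class)
  fl <- aq$first_line
  alt <- params$settings$alternative_course_override %||% fl
  cost <- cs[["lab_screening"]] + cs[["consultation"]] +
    if (p$strategy == "PGX") cs[["genotyping_panel"]] else 0
  disp <- p$disposition
  if (is.null(disp) || is.na(disp) || disp == "") disp <- "NONE"
  cost <- cost + switch(disp,
    NONE = fl,
    SWITCH = fl + alt,
    TITRATE = fl + aq$increased_dose,
    OBSERVE = fl,
    DISCONTINUE = (if (isTRUE(params$settings$discontinuation_half_rule)) fl / 2
                   else aq$discontinuation) + alt,
    SUICIDE_ATTEMPT = fl + cs[["suicide_attempt_event"]] +
      if (identical(p$suicide_result, "DEATH")) cs[["suicide_death_event"]]
      else cs[["survival_event"]] + alt,
    stop("unknown disposition: ", disp, call. = FALSE)
  )
  if (p$outcome %in% c("RESPONSE_SE_NO_RELAPSE", "RESPONSE_SE_RELAPSE")) {
    cost <- cost + cs[["side_effect_management"]]
  }
  if (p$outcome %in% c("RESPONSE_NO_SE_RELAPSE", "RESPONSE_SE_RELAPSE")) {
    cost <- cost + cs[["relapse_event"]]
  }
  unname(cost)
}

#' Enumerate all decision-tree pathways for one strategy
#'
#' Expands the 6-week tree over every gene x metabolizer-class cell: response
#' split, side-effect split among responders, relapse split, then the
#' context-specific management disposition on failure (switch / titrate /
#' observe / discontinue / suicide attempt) and the death-vs-survival split
#' after an attempt. Each cell yields 18 leaves; leaf probabilities include
#' the gene prescription-share weight and class prevalence, so the full table
#' partitions the probability space (sums to 1).
#'
#' @param strategy `"PGX"` or `"SOC"`.
#' @param params A `pgx_parameters` object.
#' @return data.frame with one row per pathway: cell identifiers, `outcome`,
#'   `disposition`, `suicide_result`, `probability`, `cost`.
#' @export
enumerate_pathways <- function(strategy, params) {
  cells <- tree_cells(params)
  drow <- params$disposition[params$disposition$strategy == strategy, ]
  d_rel <- context_dispositions(drow, "relapse")
  d_nr <- context_dispositions(drow, "no_response")
  p_death <- drow$p_suicide_death_given_attempt
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    cl <- clinical_row(params, strategy, cell$gene, cell$class, cell$carrier)
    pr <- cl$p_response; prel <- cl$p_relapse_given_response; pse <- cl$p_side_effect
    leaf <- function(outcome, disposition, suicide_result, prob) {
      data.frame(strategy = strategy, gene = cell$gene, class = cell$class,
                 carrier = cell$carrier, outcome = outcome,
                 disposition = disposition, suicide_result = suicide_result,
                 probability = cell$weight * prob)
    }
    fail_leaves <- function(outcome, p_branch, dctx) {
      rows <- lapply(setdiff(names(dctx), "SUICIDE_ATTEMPT"), function(disp) {
        leaf(outcome, disp, NA_character_, p_branch * dctx[[disp]])
      })
      c(rows, list(
        leaf(outcome, "SUICIDE_ATTEMPT", "DEATH",
             p_branch * dctx[["SUICIDE_ATTEMPT"]] * p_death),
        leaf(outcome, "SUICIDE_ATTEMPT", "SURVIVAL",
             p_branch * dctx[["SUICIDE_ATTEMPT"]] * (1 - p_death))
      ))
    }
    rows <- c(
      list(leaf("RESPONSE_NO_SE_NO_RELAPSE", NA_character_, NA_character_,
                pr * (1 - pse) * (1 - prel)),
           leaf("RESPONSE_SE_NO_RELAPSE", NA_character_, NA_character_,
                pr * pse * (1 - prel))),
      fail_leaves("RESPONSE_NO_SE_RELAPSE", pr * (1 - pse) * prel, d_rel),
      fail_leaves("RESPONSE_SE_RELAPSE", pr * pse * prel, d_rel),
      fail_leaves("NO_RESPONSE", 1 - pr, d_nr)
    )
    out[[k]] <- do.call(rbind, rows)
  }
  paths <- do.call(rbind, out)
  paths$cost <- vapply(seq_len(nrow(paths)),
                       function(i) pathway_cost(paths[i, ], params), numeric(1))
  paths
}

pathway_success_flags <- function(paths, count_alternative) {
  no_se <- paths$outcome == "RESPONSE_NO_SE_NO_RELAPSE"
  any_se <- paths$outcome %in% c("RESPONSE_NO_SE_NO_RELAPSE", "RESPONSE_SE_NO_RELAPSE")
  if (count_alternative) {
    rescued <- paths$disposition %in% c("SWITCH", "DISCONTINUE") |
      (paths$disposition %in% "SUICIDE_ATTEMPT" & paths$suicide_result %in% "SURVIVAL")
    no_se <- no_se | rescued
    any_se <- any_se | rescued
  }
  data.frame(success_no_se = no_se, success_any_se = any_se)
}

#' 6-week expected outcomes for one strategy
#'
#' Prevalence- and prescription-share-weighted success probabilities (response
#' without relapse, with the stricter no-side-effect and the looser
#' any-side-effect definition) and expected per-patient cost over all
#' pathways. Successful alternative courses after switching, discontinuation
#' or a survived attempt count toward the success endpoints only when
#' `settings$count_alternative_success` is on: success is defined on the
#' initial regimen by default, while rescue pathways always contribute cost.
#'
#' @inheritParams enumerate_pathways
#' @return An object of class `pgx_short_term` with fields
#'   `p_success_no_se`, `p_success_any_se`, `expected_cost`, `n_outcomes`
#'   (leaves per cell) and the full `pathways` table.
#' @export
strategy_outcomes <- function(strategy, params) {
  paths <- enumerate_pathways(strategy, params)
  fl <- pathway_success_flags(paths, isTRUE(params$settings$count_alternative_success))
  n_cells <- nrow(tree_cells(params))
  structure(list(
    strategy = strategy,
    p_success_no_se = sum(paths$probability * fl$success_no_se),
    p_success_any_se = sum(paths$probability * fl$success_any_se),
    expected_cost = sum(paths$probability * paths$cost),
    n_outcomes = nrow(paths) / n_cells,
    pathways = paths
  ), class = "pgx_short_term")
}

#' @export
print.pgx_short_term <- function(x, ...) {
  cat(sprintf("<pgx_short_term> %s: P(success, no SE) = %.4f, P(success, any SE) = %.4f, E[cost] = %.1f QAR (%d outcomes/cell)\n",
              x$strategy, x$p_success_no_se, x$p_success_any_se,
              x$expected_cost, as.integer(x$n_outcomes)))
  invisible(x)
}

#' Compare strategies over the 6-week decision tree
#'
#' @param params A `pgx_parameters` object.
#' @return An object of class `pgx_short_comparison`: per-strategy results,
#'   incremental success probabilities (guided minus standard), the cost
#'   saving (standard-of-care cost minus guided-strategy cost, so positive
#'   favours testing), and ICER/dominance classifications for both success
#'   endpoints at the configured willingness-to-pay.
#' @export
compare_short_term <- function(params) {
  pgx <- strategy_outcomes("PGX", params)
  soc <- strategy_outcomes("SOC", params)
  delta_cost <- pgx$expected_cost - soc$expected_cost
  d1 <- pgx$p_success_no_se - soc$p_success_no_se
  d2 <- pgx$p_success_any_se - soc$p_success_any_se
  wtp <- params$settings$wtp
  structure(list(
    PGX = pgx, SOC = soc,
    delta_p_no_se = d1,
    delta_p_any_se = d2,
    delta_cost = delta_cost,
    saving = -delta_cost,
    icer_no_se = classify_icer(delta_cost, d1, wtp),
    icer_any_se = classify_icer(delta_cost, d2, wtp)
  ), class = "pgx_short_comparison")
}

#' @export
print.pgx_short_comparison <- function(x, ...) {
  cat("<pgx_short_comparison> 6-week decision tree, PGx-guided vs standard of care\n")
  cat(sprintf("  P(response, no SE, no relapse): %.4f vs %.4f  (diff %+.5f)\n",
              x$PGX$p_success_no_se, x$SOC$p_success_no_se, x$delta_p_no_se))
  cat(sprintf("  P(response, +/- SE, no relapse): %.4f vs %.4f  (diff %+.5f)\n",
              x$PGX$p_success_any_se, x$SOC$p_success_any_se, x$delta_p_any_se))
  cat(sprintf("  expected cost/patient: %.1f vs %.1f QAR (saving %+.1f)\n",
              x$PGX$expected_cost, x$SOC$expected_cost, x$saving))
  cat(sprintf("  ICER (no-SE endpoint): %s\n", x$icer_no_se$label))
  invisible(x)
}
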