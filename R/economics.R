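#' Continuous discount factor
#'
#' `(1 + rate)^(-t_years)`; outcomes and costs are discounted continuously in
#' cycle time rather than stepped annually.
#'
#' @param t_years Time in years (>= 0).
#' @param rate Annual discount rate (>= 0), e.g. 0.03.
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(t_years, rate) {
  if (any(t_years < 0)) stop("t_years must be >= 0", call. = FALSE)
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  (1 + rate)^(-t_years)
}

#' Classify an incremental cost-effectiveness result
#'
#' Standard dominance logic on the incremental cost/effect pair: cheaper and
#' more effective is DOMINANT (the ICER is not reported for dominant or
#' dominated strategies), costlier and less effective is DOMINATED, both zero
#' is INDIFFERENT, and otherwise the ICER is compared against the
#' willingness-to-pay threshold.
#'
#' @param delta_cost Incremental cost (intervention minus comparator), QAR.
#' @param delta_effect Incremental effect (same orientation).
#' @param wtp Willingness-to-pay threshold (> 0), QAR per effect unit.
#' @return List of class `pgx_icer`: `delta_cost`, `delta_effect`, `icer`
#'   (NA when undefined), `label`.
#' @export
classify_icer <- function(delta_cost, delta_effect, wtp) {
  if (wtp <= 0) stop("wtp must be > 0", call. = FALSE)
  label <- if (delta_cost == 0 && delta_effect == 0) {
    "INDIFFERENT"
  } else if (delta_cost < 0 && delta_effect > 0) {
    "DOMINANT"
  } else if (delta_cost > 0 && delta_effect < 0) {
    "DOMINATED"
  } else if (delta_effect > 0) {
    if (delta_cost / delta_effect < wtp) "COST_EFFECTIVE" else "NOT_COST_EFFECTIVE"
  } else if (delta_effect == 0) {
    if (delta_cost < 0) "DOMINANT" else "NOT_COST_EFFECTIVE"
  } else {
    # less effective but cheaper: cost-effective only if savings per effect
    # lost exceed the threshold
    if (delta_cost / delta_effect > wtp) "COST_EFFECTIVE" else "NOT_COST_EFFECTIVE"
  }
  icer <- if (label %in% c("DOMINANT", "DOMINATED") || delta_effect == 0) {
    NA_real_
  } else {
    delta_cost / delta_effect
  }
  structure(list(delta_cost = delta_cost, delta_effect = delta_effect,
                 icer = icer, label = label), class = "pgx_icer")
}

#' @export
print.pgx_icer <- function(x, ...) {
  cat(sprintf("<pgx_icer> %s (dCost %.1f, dEffect %.5f%s)\n", x$label,
              x$delta_cost, x$delta_effect,
              if (is.na(x$icer)) "" else sprintf(", ICER %.0f", x$icer)))
  invisible(x)
}

#' Net monetary benefit
#'
#' @param delta_cost Incremental cost.
#' @param delta_effect Incremental effect.
#' @param wtp Willingness-to-pay threshold (>= 0).
#' @return `wtp * delta_effect - delta_cost`.
#' @export
nmb <- function(delta_cost, delta_effect, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * delta_effect - delta_cost
}

#' Build a cost-adaptation index set
#'
#' Indices for transferring a foreign cost estimate to 2024 QAR: currency
#' exchange, relative per-capita health expenditure, relative health price
#' level, and an inflation factor from the source year to 2024.
#'
#' @param source_currency e.g. `"USD"` or `"EUR"`.
#' @param exchange_rate_to_qar Units of QAR per unit of source currency.
#' @param expenditure_index_source,expenditure_index_target Per-capita health
#'   expenditure indices (> 0).
#' @param price_index_source,price_index_target Health price level indices (> 0).
#' @param inflation_factor Source-year to 2024 inflation factor (> 0).
#' @return List of class `pgx_adaptation_indices`.
#' @export
cost_adaptation_indices <- function(source_currency,
                                    exchange_rate_to_qar,
                                    expenditure_index_source = 1,
                                    expenditure_index_target = 1,
                                    price_index_source = 1,
                                    price_index_target = 1,
                                    inflation_factor = 1) {
  idx <- list(source_currency = source_currency,
              exchange_rate_to_qar = exchange_rate_to_qar,
              expenditure_index_source = expenditure_index_source,
              expenditure_index_target = expenditure_index_target,
              price_index_source = price_index_source,
              price_index_target = price_index_target,
              inflation_factor = inflation_factor)
  num <- unlist(idx[-1])
  if (any(num <= 0)) stop("all adaptation indices must be > 0", call. = FALSE)
  structure(idx, class = "pgx_adaptation_indices")
}

#' Adapt a foreign cost to local 2024 prices
#'
#' `amount x inflation x (target expenditure / source expenditure) /
#' (source price level / target price level) x exchange rate`. Every factor
#' applied is recorded in the result's provenance so alternative
#' compositions are a configuration change.
#'
#' @param amount Cost in the source currency (>= 0).
#' @param indices A `pgx_adaptation_indices` object.
#' @return Adapted cost in QAR with a `provenance` attribute (list of
#'   factors; serialize with `jsonlite::toJSON`).
#' @export
adapt_cost <- function(amount, indices) {
  if (any(amount < 0)) stop("amount must be >= 0", call. = FALSE)
  stopifnot(inherits(indices, "pgx_adaptation_indices"))
  expenditure_correction <- indices$expenditure_index_target / indices$expenditure_index_source
  price_correction <- indices$price_index_target / indices$price_index_source
  out <- amount * indices$inflation_factor * expenditure_correction *
    price_correction * indices$exchange_rate_to_qar
  attr(out, "provenance") <- list(
    source_currency = indices$source_currency,
    amount_source = amount,
    inflation_factor = indices$inflation_factor,
    expenditure_correction = expenditure_correction,
    price_correction = price_correction,
    exchange_rate_to_qar = indices$exchange_rate_to_qar,
    amount_qar = as.numeric(out)
  )
  out
}
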