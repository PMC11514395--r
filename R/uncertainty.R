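#' Fit a beta distribution from a mean and 95% CI
#'
#' Method of moments: the SD is approximated as `(upper95 - lower95)/3.92`
#' and the beta shape parameters follow from the mean and variance.
#'
#' @param mean Mean in (0, 1).
#' @param lower95,upper95 95% interval bounds, `0 < lower95 <= mean <= upper95 < 1`.
#' @return Named vector `c(alpha, beta)`, both > 1 (a unimodal fit; intervals
#'   too wide for the mean are rejected as overdispersed); the fitted
#'   distribution's analytic mean equals `mean` exactly.
#' @export
beta_from_mean_ci <- function(mean, lower95, upper95) {
  if (!(mean > 0 && mean < 1)) stop("mean must lie in (0, 1)", call. = FALSE)
  if (!(lower95 > 0 && lower95 <= mean && mean <= upper95 && upper95 < 1)) {
    stop("require 0 < lower95 <= mean <= upper95 < 1", call. = FALSE)
  }
  v <- ((upper95 - lower95) / 3.92)^2
  if (v >= mean * (1 - mean)) {
    stop("variance >= mean(1-mean): no valid beta distribution", call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  out <- c(alpha = mean * nu, beta = (1 - mean) * nu)
  if (any(out <= 1)) {
    stop("interval too wide for the mean (fitted shape <= 1): ",
         "no valid beta distribution", call. = FALSE)
  }
  out
}

#' Fit a gamma distribution from a mean and 95% CI
#'
#' Method of moments with `SD = (upper95 - lower95)/3.92`; a minimum
#' coefficient of variation (`cv_floor`, default 0.01) guards the degenerate
#' zero-width interval.
#'
#' @param mean Mean (> 0).
#' @param lower95,upper95 95% interval bounds, `0 < lower95 <= mean <= upper95`.
#' @param cv_floor Minimum SD/mean ratio.
#' @return Named vector `c(shape, scale)`; `shape * scale == mean` exactly.
#' @export
gamma_from_mean_ci <- function(mean, lower95, upper95, cv_floor = 0.01) {
  if (mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!(lower95 > 0 && lower95 <= mean && mean <= upper95)) {
    stop("require 0 < lower95 <= mean <= upper95", call. = FALSE)
  }
  sd <- max((upper95 - lower95) / 3.92, cv_floor * mean)
  c(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Default sampling distributions for the PSA
#'
#' One row per addressable parameter: prevalences are fixed by design;
#' probabilities and utilities get beta distributions, costs get gamma
#' distributions, and the discount rate a symmetric triangular distribution
#' (+/- 25%). Most published inputs come without printed intervals, so the
#' default 95% CI is +/- 20% of the mean for probabilities/utilities (upper
#' bounds capped below 1) and +/- 50% for costs; override rows to encode
#' known intervals.
#'
#' @param params A `pgx_parameters` object.
#' @param prob_ci_fraction,cost_ci_fraction Half-widths of the default 95%
#'   CIs, as fractions of the mean.
#' @return data.frame with columns `parameter`, `family`, `mean`, `lower95`,
#'   `upper95`, `fraction`.
#' @export
default_distribution_specs <- function(params, prob_ci_fraction = 0.20,
                                       cost_ci_fraction = 0.50) {
  pt <- parameter_table(params)
  specs <- data.frame(parameter = pt$parameter, family = "FIXED",
                      mean = pt$value, lower95 = NA_real_, upper95 = NA_real_,
                      fraction = NA_real_)
  for (i in seq_len(nrow(pt))) {
    v <- pt$value[i]
    if (pt$family[i] %in% c("probability", "utility")) {
      if (v > 0 && v < 1) {
        specs$family[i] <- "BETA"
        specs$lower95[i] <- v * (1 - prob_ci_fraction)
        specs$upper95[i] <- min(v * (1 + prob_ci_fraction), 1 - 1e-6)
      }
    } else if (pt$family[i] == "cost") {
      if (v > 0) {
        specs$family[i] <- "GAMMA"
        specs$lower95[i] <- v * (1 - cost_ci_fraction)
        specs$upper95[i] <- v * (1 + cost_ci_fraction)
      }
    } else if (pt$family[i] == "rate") {
      if (v > 0) {
        specs$family[i] <- "TRIANGULAR"
        specs$fraction[i] <- 0.25
      }
    }
  }
  specs
}

rtriangular <- function(n, mean, fraction) {
  lo <- mean * (1 - fraction); hi <- mean * (1 + fraction)
  u <- stats::runif(n)
  ifelse(u < 0.5,
         lo + sqrt(u * (hi - lo) * (mean - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mean)))
}

# One column per non-FIXED spec row; per-parameter substreams keyed off the
# master seed, so extending n never reshuffles earlier draws.
sample_spec_matrix <- function(specs, n, seed) {
  active <- which(specs$family != "FIXED")
  out <- matrix(NA_real_, nrow = n, ncol = length(active),
                dimnames = list(NULL, specs$parameter[active]))
  for (j in seq_along(active)) {
    i <- active[j]
    set.seed((as.integer(seed) + 104729L * j) %% 2147483647L)
    out[, j] <- switch(specs$family[i],
      BETA = {
        ab <- beta_from_mean_ci(specs$mean[i], specs$lower95[i], specs$upper95[i])
        stats::rbeta(n, ab[["alpha"]], ab[["beta"]])
      },
      GAMMA = {
        ss <- gamma_from_mean_ci(specs$mean[i], specs$lower95[i], specs$upper95[i])
        stats::rgamma(n, shape = ss[["shape"]], scale = ss[["scale"]])
      },
      TRIANGULAR = rtriangular(n, specs$mean[i], specs$fraction[i]),
      stop("unknown distribution family: ", specs$family[i], call. = FALSE)
    )
  }
  out
}

#' Draw one sampled parameter set
#'
#' Applies one joint draw from the uncertainty distributions to a copy of the
#' base set. FIXED parameters are untouched; sampled probabilities are
#' clamped to \[0, 1\] (beta draws already satisfy this); context simplexes
#' are renormalized downstream where they are consumed. Reproducible per
#' seed, and equal to draw 1 of [run_psa()] with the same seed.
#'
#' @param params Base `pgx_parameters` object.
#' @param specs Distribution table as from [default_distribution_specs()].
#' @param seed Integer seed.
#' @return A `pgx_parameters` object.
#' @export
sample_parameter_set <- function(params, specs = default_distribution_specs(params),
                                 seed = 1L) {
  unknown <- setdiff(specs$parameter, parameter_table(params)$parameter)
  if (length(unknown)) {
    stop("specs name unknown parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!any(specs$family != "FIXED")) return(params)
  m <- sample_spec_matrix(specs, 1L, seed)
  for (p in colnames(m)) {
    v <- unname(m[1, p])
    fam <- specs$family[match(p, specs$parameter)]
    if (fam == "BETA") v <- min(max(v, 0), 1)
    params <- set_parameter(params, p, v)
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Joint Monte Carlo over all non-FIXED parameters: each draw re-evaluates
#' both the 6-week decision tree and the lifetime Markov comparison on the
#' sampled parameter set. Evaluation uses a compiled representation of the
#' model that is test-verified against the reference implementations.
#'
#' @param params Base `pgx_parameters` object.
#' @param specs Distribution table; defaults to [default_distribution_specs()].
#' @param n Number of draws (>= 1).
#' @param seed Master seed; per-parameter substreams are derived from it.
#' @return Object of class `pgx_psa`: `draws` (per-draw incremental results
#'   and dominance labels), `inputs` (sampled parameter matrix), `summary`
#'   (fraction dominant / cost-effective at the configured WTP for the
#'   short-term and long-term cost endpoints), `wtp`, `specs`, `seed`.
#' @export
run_psa <- function(params, specs = default_distribution_specs(params),
                    n = 1000, seed = 1L) {
  stopifnot(n >= 1)
  unknown <- setdiff(specs$parameter, parameter_table(params)$parameter)
  if (length(unknown)) {
    stop("specs name unknown parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- compile_model(params)
  inputs <- sample_spec_matrix(specs, n, seed)
  setters <- lapply(colnames(inputs), function(p) compiled_setter(params, p))
  names(setters) <- colnames(inputs)
  live <- !vapply(setters, is.null, logical(1))
  wtp <- params$settings$wtp

  cols <- c("delta_cost_short", "delta_p_no_se", "delta_p_any_se",
            "delta_cost_long", "delta_ly", "delta_qaly")
  draws <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  fams <- specs$family[match(colnames(inputs), specs$parameter)]
  for (i in seq_len(n)) {
    cm <- base
    for (j in which(live)) {
      v <- unname(inputs[i, j])
      if (fams[j] == "BETA") v <- min(max(v, 0), 1)
      cm <- setters[[j]](cm, v)
    }
    sp <- eval_short_fast(cm, "PGX"); ss <- eval_short_fast(cm, "SOC")
    lp <- eval_long_fast(cm, "PGX"); ls <- eval_long_fast(cm, "SOC")
    draws[i, ] <- c(sp[["cost"]] - ss[["cost"]],
                    sp[["p_no_se"]] - ss[["p_no_se"]],
                    sp[["p_any_se"]] - ss[["p_any_se"]],
                    lp[["cost"]] - ls[["cost"]],
                    lp[["LY"]] - ls[["LY"]],
                    lp[["QALY"]] - ls[["QALY"]])
  }
  draws <- as.data.frame(draws)
  draws$draw <- seq_len(n)
  draws$label_short <- ifelse(draws$delta_cost_short < 0 & draws$delta_p_no_se > 0,
                              "DOMINANT",
                       ifelse(draws$delta_p_no_se > 0 &
                                draws$delta_cost_short / draws$delta_p_no_se < wtp,
                              "COST_EFFECTIVE", "OTHER"))
  draws$label_long <- ifelse(draws$delta_cost_long < 0 & draws$delta_qaly > 0,
                             "DOMINANT",
                      ifelse(draws$delta_qaly > 0 &
                               draws$delta_cost_long / draws$delta_qaly < wtp,
                             "COST_EFFECTIVE", "OTHER"))
  structure(list(
    draws = draws,
    inputs = inputs,
    summary = list(
      fraction_dominant_short = mean(draws$label_short == "DOMINANT"),
      fraction_cost_effective_short = mean(draws$label_short == "COST_EFFECTIVE"),
      fraction_dominant_long = mean(draws$label_long == "DOMINANT"),
      fraction_cost_effective_long = mean(draws$label_long == "COST_EFFECTIVE"),
      mean_delta_cost_short = mean(draws$delta_cost_short),
      mean_delta_cost_long = mean(draws$delta_cost_long)
    ),
    wtp = wtp, specs = specs, seed = seed
  ), class = "pgx_psa")
}

#' @export
print.pgx_psa <- function(x, ...) {
  cat(sprintf("<pgx_psa> %d draws (seed %d): short-term dominant %.1f%%, long-term dominant %.1f%% at WTP %.0f\n",
              nrow(x$draws), x$seed, 100 * x$summary$fraction_dominant_short,
              100 * x$summary$fraction_dominant_long, x$wtp))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit at each
#' willingness-to-pay value.
#'
#' @param draws A `pgx_psa` object or a data frame of draws.
#' @param wtp_grid Non-empty numeric vector of thresholds.
#' @param effect,cost Column names of the effect and cost increments
#'   (defaults: long-term QALY gain and long-term incremental cost).
#' @return data.frame with columns `wtp`, `probability_acceptable`.
#' @export
ceac <- function(draws, wtp_grid, effect = "delta_qaly", cost = "delta_cost_long") {
  if (inherits(draws, "pgx_psa")) draws <- draws$draws
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty", call. = FALSE)
  if (nrow(draws) == 0) stop("no draws", call. = FALSE)
  de <- draws[[effect]]; dc <- draws[[cost]]
  prob <- vapply(wtp_grid, function(w) mean(nmb(dc, de, w) > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability_acceptable = prob)
}

#' Regression tornado ranking
#'
#' Ordinary least squares of the standardized output on the standardized
#' sampled inputs; parameters are ranked by absolute standardized
#' coefficient. Constant input columns are excluded with a warning.
#'
#' @param psa A `pgx_psa` object, or a list with elements `inputs` (matrix)
#'   and `draws` (data frame).
#' @param output Output column name in `draws` (e.g. `"delta_cost_short"`),
#'   or a numeric vector of length `nrow(inputs)`.
#' @return data.frame with columns `parameter`, `coefficient`, `rank`,
#'   ordered by decreasing |coefficient|.
#' @export
tornado_regression <- function(psa, output = "delta_cost_short") {
  inputs <- psa$inputs
  y <- if (is.character(output)) psa$draws[[output]] else output
  if (ncol(inputs) < 2) stop("need at least 2 varying inputs", call. = FALSE)
  sds <- apply(inputs, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("excluding constant input columns: ",
            paste(colnames(inputs)[const], collapse = ", "), call. = FALSE)
    inputs <- inputs[, !const, drop = FALSE]
  }
  X <- scale(inputs)
  ys <- (y - mean(y)) / stats::sd(y)
  fit <- stats::lm.fit(cbind(1, X), ys)
  coefs <- fit$coefficients[-1]
  ord <- order(abs(coefs), decreasing = TRUE)
  data.frame(parameter = colnames(inputs)[ord],
             coefficient = unname(coefs[ord]),
             rank = seq_along(ord))
}

#' Univariate sensitivity sweep
#'
#' Re-evaluates the model deterministically at `mean * (1 - fraction)` and
#' `mean * (1 + fraction)` for one parameter, everything else at base.
#'
#' @param params A `pgx_parameters` object.
#' @param parameter Identifier from [parameter_table()].
#' @param fraction Relative half-width (default 0.25).
#' @param endpoint One of `"short_saving"`, `"long_saving"`, `"delta_ly"`,
#'   `"delta_qaly"`.
#' @return List with `low`, `high`, `base` endpoint values and the parameter
#'   values used.
#' @export
univariate_sweep <- function(params, parameter, fraction = 0.25,
                             endpoint = c("short_saving", "long_saving",
                                          "delta_ly", "delta_qaly")) {
  endpoint <- match.arg(endpoint)
  base_val <- get_parameter(params, parameter)
  eval_at <- function(v) {
    p2 <- set_parameter(params, parameter, v)
    switch(endpoint,
           short_saving = compare_short_term(p2)$saving,
           long_saving = compare_long_term(p2)$saving,
           delta_ly = compare_long_term(p2)$delta_ly,
           delta_qaly = compare_long_term(p2)$delta_qaly)
  }
  list(parameter = parameter, endpoint = endpoint,
       value_low = base_val * (1 - fraction),
       value_high = base_val * (1 + fraction),
       low = eval_at(base_val * (1 - fraction)),
       high = eval_at(base_val * (1 + fraction)),
       base = eval_at(base_val))
}
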