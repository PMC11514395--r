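#' Specification for the synthetic input generator
#'
#' Controls the random parameter-set generator and the synthetic age-group
#' mortality schedule. The mortality model is Gompertz-like: an annual rate
#' `mortality_base` at `mortality_base_age` doubling every `doubling_years`
#' (set `doubling_years = Inf` for a constant rate). The synthetic schedule
#' is a test stand-in for a real life table, never a substitute for local
#' mortality data.
#'
#' @param seed Integer seed for reproducibility.
#' @param prob_range Range random clinical probabilities are drawn from.
#' @param cost_scale Scale (QAR) of random exponential cost draws.
#' @param utility_range Range for random state utilities.
#' @param mortality_base,mortality_base_age,doubling_years Gompertz-like
#'   parameters of the synthetic mortality schedule.
#' @param mortality_age_range,band_width Age span and band width (years) of
#'   the synthetic age-group table.
#' @param noise_sd Lognormal noise SD applied to synthetic mortality rates
#'   (0 = exact curve).
#' @return List of class `pgx_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, prob_range = c(0.05, 0.95),
                           cost_scale = 1000, utility_range = c(0.3, 0.95),
                           mortality_base = 0.002, mortality_base_age = 48,
                           doubling_years = 8, mortality_age_range = c(45, 85),
                           band_width = 5, noise_sd = 0) {
  stopifnot(prob_range[1] >= 0, prob_range[2] <= 1, prob_range[1] < prob_range[2],
            cost_scale > 0, utility_range[1] >= 0, utility_range[2] <= 1,
            mortality_base > 0, mortality_base <= 1, doubling_years > 0,
            band_width > 0, noise_sd >= 0)
  structure(list(seed = as.integer(seed), prob_range = prob_range,
                 cost_scale = cost_scale, utility_range = utility_range,
                 mortality_base = mortality_base,
                 mortality_base_age = mortality_base_age,
                 doubling_years = doubling_years,
                 mortality_age_range = mortality_age_range,
                 band_width = band_width, noise_sd = noise_sd),
            class = "pgx_synthetic_spec")
}

#' Synthetic age-group mortality table
#'
#' Builds an age-banded annual mortality table (band midpoints against annual
#' rate) from the Gompertz-like model in `spec`, optionally with lognormal
#' noise; rates are clamped to \[0, 1\] and kept strictly increasing with age.
#'
#' @param spec A `pgx_synthetic_spec`.
#' @return data.frame with columns `age_mid`, `rate`.
#' @export
synthetic_mortality_table <- function(spec = synthetic_spec()) {
  ages <- seq(spec$mortality_age_range[1], spec$mortality_age_range[2] - spec$band_width,
              by = spec$band_width)
  mid <- ages + (spec$band_width - 1) / 2
  rate <- spec$mortality_base *
    2^((mid - spec$mortality_base_age) / spec$doubling_years)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    rate <- rate * exp(stats::rnorm(length(rate), 0, spec$noise_sd))
    rate <- cummax(rate) + 1e-9 * seq_along(rate)  # keep strictly increasing
  }
  data.frame(age_mid = mid, rate = pmin(pmax(rate, 0), 1))
}

#' Generate a random valid parameter set
#'
#' Draws a complete model parameterization with the same structure as the
#' packaged default — per-gene prevalence simplexes, clinical probabilities,
#' positive disposition weights, non-negative costs, utilities in \[0, 1\]
#' with non-increasing response utilities over age, long-term transition
#' inputs with feasible row sums — and passes it through the same validator
#' as hand-written configs. Reproducible per seed.
#'
#' @param spec A `pgx_synthetic_spec`.
#' @return A validated `pgx_parameters` object.
#' @export
random_parameter_set <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  params <- load_parameters()
  runi <- function(n, lo, hi) stats::runif(n, lo, hi)

  # per-gene prevalence simplex: positive weights scaled to a random total < 1
  prev <- params$prevalence
  for (g in unique(prev$gene)) {
    i <- which(prev$gene == g & prev$class != "NORMAL")
    w <- stats::rgamma(length(i), shape = 1)
    tot <- runi(1, 0.2, 0.9)
    prev$prevalence[i] <- w / sum(w) * tot
    prev$prevalence[prev$gene == g & prev$class == "NORMAL"] <- 1 - tot
  }
  params$prevalence <- prev

  cl <- params$clinical
  n <- nrow(cl)
  cl$p_response <- runi(n, spec$prob_range[1], spec$prob_range[2])
  cl$p_relapse_given_response <- runi(n, spec$prob_range[1], spec$prob_range[2])
  cl$p_side_effect <- runi(n, spec$prob_range[1], spec$prob_range[2])
  params$clinical <- cl

  dp <- params$disposition
  for (col in c("p_switch", "p_titrate", "p_observe", "p_discontinue",
                "p_suicide_attempt")) {
    dp[[col]] <- runi(nrow(dp), 0.05, 0.8)
  }
  dp$p_suicide_death_given_attempt <- runi(nrow(dp), 0.001, 0.05)
  params$disposition <- dp

  aq <- params$acquisition
  aq$first_line <- stats::rexp(nrow(aq), 1 / (spec$cost_scale / 10))
  aq$increased_dose <- aq$first_line * runi(nrow(aq), 1, 2.5)
  aq$discontinuation <- aq$first_line * runi(nrow(aq), 0.3, 0.7)
  params$acquisition <- aq

  params$costs_short[] <- stats::rexp(length(params$costs_short), 1 / spec$cost_scale)
  params$costs_long[] <- stats::rexp(length(params$costs_long), 1 / spec$cost_scale)

  u <- sort(runi(nrow(params$utilities$response) + 2,
                 spec$utility_range[1], spec$utility_range[2]), decreasing = TRUE)
  params$utilities$response$utility <- u[seq_len(nrow(params$utilities$response))]
  params$utilities$relapse <- u[length(u) - 1]
  params$utilities$no_response <- u[length(u)]

  tr <- params$transitions
  for (i in seq_len(nrow(tr))) {
    exits <- stats::rgamma(3, shape = 1)
    exits <- exits / sum(exits) * runi(1, 0.1, 0.8)  # R-row exits sum < 1
    tr$relapse_onset[i] <- exits[1]
    tr$no_response_onset[i] <- exits[2]
    tr$suicide_death[i] <- exits[3] * 0.05
    tr$relapse_remission[i] <- runi(1, 0.01, 0.5)
    tr$response_return[i] <- runi(1, 0.01, 0.5)
    tr$nonsuicide_death[i] <- runi(1, 0.001, 0.1)
  }
  params$transitions <- tr

  params$markov$discount_rate <- runi(1, 0, 0.05)
  params$mortality <- synthetic_mortality_table(spec)
  validate_parameters(params)
  params
}

#' Multiplicatively perturb a parameter set
#'
#' Every addressable numeric parameter is multiplied by an independent factor
#' in `[1 - epsilon, 1 + epsilon]`; probabilities and utilities are clamped
#' back to \[0, 1\], prevalence simplexes are rescaled if they overflow, and
#' the result is revalidated. `epsilon = 0` returns an identical set.
#'
#' @param params A `pgx_parameters` object.
#' @param epsilon Relative half-width (>= 0).
#' @param seed Integer seed.
#' @return A validated `pgx_parameters` object.
#' @export
perturbed_set <- function(params, epsilon, seed = 1L) {
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (epsilon == 0) return(params)
  set.seed(seed)
  pt <- parameter_table(params)
  fac <- stats::runif(nrow(pt), 1 - epsilon, 1 + epsilon)
  for (i in seq_len(nrow(pt))) {
    v <- pt$value[i] * fac[i]
    if (pt$family[i] %in% c("probability", "utility")) v <- min(max(v, 0), 1)
    params <- set_parameter(params, pt$parameter[i], v)
  }
  prev <- params$prevalence
  for (g in unique(prev$gene)) {
    i <- which(prev$gene == g & prev$class != "NORMAL")
    f <- stats::runif(length(i), 1 - epsilon, 1 + epsilon)
    p <- pmin(pmax(prev$prevalence[i] * f, 0), 1)
    if (sum(p) > 1) p <- p / sum(p)
    prev$prevalence[i] <- p
    prev$prevalence[prev$gene == g & prev$class == "NORMAL"] <- 1 - sum(p)
  }
  params$prevalence <- prev
  # response utilities must stay non-increasing across age bands
  params$utilities$response$utility <-
    sort(params$utilities$response$utility, decreasing = TRUE)
  validate_parameters(params)
  params
}
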