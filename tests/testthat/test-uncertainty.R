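test_that("beta fits are symmetric, mean-exact, and reject overdispersion", {
  ab <- beta_from_mean_ci(0.5, 0.4, 0.6)
  expect_equal(unname(ab["alpha"]), unname(ab["beta"]))
  ab2 <- beta_from_mean_ci(0.37, 0.30, 0.44)
  expect_equal(unname(ab2["alpha"] / sum(ab2)), 0.37, tolerance = 1e-9)
  expect_true(all(ab2 > 0))
  expect_error(beta_from_mean_ci(0.37, 0.0001, 0.9999), "no valid beta")
  expect_error(beta_from_mean_ci(1.2, 0.1, 0.9), "\\(0, 1\\)")
  expect_error(beta_from_mean_ci(0.5, 0.6, 0.9), "lower95")
})

test_that("gamma fits are mean-exact with a guarded degenerate case", {
  ss <- gamma_from_mean_ci(540, 405, 675)
  expect_equal(unname(ss["shape"] * ss["scale"]), 540, tolerance = 1e-9)
  # zero-width interval falls back to the minimum coefficient of variation
  ss0 <- gamma_from_mean_ci(100, 100, 100)
  expect_equal(unname(ss0["shape"] * ss0["scale"]), 100, tolerance = 1e-9)
  expect_equal(unname(sqrt(ss0["shape"]) * ss0["scale"]), 1, tolerance = 1e-9)  # SD = 1% of mean
  expect_error(gamma_from_mean_ci(-5, 1, 2), "> 0")

  set.seed(1)
  ssm <- gamma_from_mean_ci(954, 477, 1431)
  draws <- stats::rgamma(1e6, shape = ssm[["shape"]], scale = ssm[["scale"]])
  expect_lt(abs(mean(draws) - 954) / 954, 0.01)
})

test_that("beta sampling concentrates on the configured mean", {
  ab <- beta_from_mean_ci(0.37, 0.37 * 0.8, 0.37 * 1.2)
  set.seed(2)
  x <- stats::rbeta(1e5, ab[["alpha"]], ab[["beta"]])
  expect_lt(abs(mean(x) - 0.37), 0.005)
})

test_that("parameter sampling is deterministic per seed and fixes what it should", {
  p <- base_params()
  specs <- default_distribution_specs(p)
  expect_true(all(specs$family[grepl("^disposition", specs$parameter)] == "BETA"))
  expect_true(all(specs$family[specs$mean == 0] == "FIXED"))

  all_fixed <- specs; all_fixed$family <- "FIXED"
  expect_identical(sample_parameter_set(p, all_fixed, seed = 5), p)

  s1 <- sample_parameter_set(p, specs, seed = 9)
  s2 <- sample_parameter_set(p, specs, seed = 9)
  expect_identical(s1, s2)
  s3 <- sample_parameter_set(p, specs, seed = 10)
  expect_false(identical(s1, s3))

  bad <- specs[1, ]; bad$parameter <- "clinical.PGX.NOPE.PM.p_response"
  expect_error(sample_parameter_set(p, bad, seed = 1), "unknown parameter")

  pt <- parameter_table(s1)
  probs <- pt$value[pt$family %in% c("probability", "utility")]
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("PSA draws are reproducible, extendable, and base-valued when all fixed", {
  p <- base_params()
  specs <- default_distribution_specs(p)
  a <- run_psa(p, specs, n = 50, seed = 3)
  b <- run_psa(p, specs, n = 50, seed = 3)
  expect_identical(a$draws, b$draws)
  # growing n preserves the earlier draws (counter-based substreams)
  c200 <- run_psa(p, specs, n = 200, seed = 3)
  expect_equal(c200$draws[1:50, names(a$draws)], a$draws, tolerance = 1e-12)

  all_fixed <- specs; all_fixed$family <- "FIXED"
  one <- run_psa(p, all_fixed, n = 1, seed = 1)
  st <- compare_short_term(p); lt <- compare_long_term(p)
  expect_equal(one$draws$delta_cost_short, st$delta_cost, tolerance = 1e-9)
  expect_equal(one$draws$delta_cost_long, lt$delta_cost, tolerance = 1e-9)
  expect_equal(one$draws$delta_ly, lt$delta_ly, tolerance = 1e-12)
  expect_equal(one$draws$delta_qaly, lt$delta_qaly, tolerance = 1e-12)
})

test_that("degenerate specs forcing dominance give a dominant fraction of 1", {
  p <- base_params()
  # guided arm strictly better and cheaper with certainty
  p$costs_short[["genotyping_panel"]] <- 0
  p$clinical$p_side_effect[p$clinical$strategy == "SOC"] <- 0.99
  p$costs_long[["acquisition_PGX"]] <- 1
  specs <- default_distribution_specs(p)
  specs$family <- "FIXED"
  psa <- run_psa(p, specs, n = 5, seed = 1)
  expect_true(all(psa$draws$delta_cost_short < 0))
  expect_equal(psa$summary$fraction_dominant_short, 1)
})

test_that("the acceptability curve matches trivial cases and uses every draw", {
  draws <- data.frame(delta_qaly = c(0.1, 0.2, 0.3), delta_cost_long = c(-10, -20, -5))
  cv <- ceac(draws, c(0, 1e5))
  expect_equal(cv$probability_acceptable, c(1, 1))  # all dominant
  draws2 <- data.frame(delta_qaly = c(0.1, -0.1), delta_cost_long = c(5, -5))
  expect_equal(ceac(draws2, 0)$probability_acceptable, 0.5)  # wtp 0: P(dcost < 0)
  expect_error(ceac(draws2, numeric(0)), "non-empty")
  grid <- seq(0, 1e5, length.out = 7)
  cv3 <- ceac(draws2, grid)
  expect_true(all(cv3$probability_acceptable >= 0 & cv3$probability_acceptable <= 1))
  expect_equal(nrow(cv3), length(grid))
})

test_that("the acceptability curve matches the closed-form bivariate-normal answer", {
  requireNamespace("MASS", quietly = TRUE)
  set.seed(4)
  n <- 1e5
  mu <- c(cost = 1000, eff = 0.05)
  sd_c <- 2000; sd_e <- 0.1; rho <- 0.3
  S <- matrix(c(sd_c^2, rho * sd_c * sd_e, rho * sd_c * sd_e, sd_e^2), 2)
  xy <- MASS::mvrnorm(n, mu, S)
  draws <- data.frame(delta_cost_long = xy[, 1], delta_qaly = xy[, 2])
  grid <- seq(0, 2e5, length.out = 9)
  cv <- ceac(draws, grid)
  analytic <- vapply(grid, function(w) {
    m <- w * mu["eff"] - mu["cost"]
    v <- w^2 * sd_e^2 - 2 * w * rho * sd_c * sd_e + sd_c^2
    stats::pnorm(m / sqrt(v))
  }, numeric(1))
  expect_true(all(abs(cv$probability_acceptable - analytic) < 0.01))
})

test_that("tornado regression recovers a planted linear model", {
  set.seed(6)
  n <- 5000
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  y <- 2 * x1 + 1 * x2 + stats::rnorm(n, sd = 0.5)
  fake <- list(inputs = cbind(a.x1 = x1, b.x2 = x2), draws = data.frame(y = y))
  tor <- tornado_regression(fake, output = y)
  expect_equal(tor$parameter, c("a.x1", "b.x2"))
  expect_equal(tor$rank, c(1, 2))
  expect_equal(tor$coefficient[1] / tor$coefficient[2], 2, tolerance = 0.1)

  # constant columns are dropped with a warning; a single informative input
  # has |standardized coefficient| ~ 1
  y1 <- 3 * x1 + stats::rnorm(n, sd = 1e-3)
  fake2 <- list(inputs = cbind(a.x1 = x1, c.const = rep(1, n), b.x2 = x2),
                draws = NULL)
  expect_warning(tor2 <- tornado_regression(fake2, output = y1), "constant")
  expect_equal(tor2$parameter[1], "a.x1")
  expect_equal(abs(tor2$coefficient[1]), 1, tolerance = 0.01)
})

test_that("the genotyping cost ranks among the short-term saving drivers", {
  p <- base_params()
  psa <- run_psa(p, n = 400, seed = 12)
  tor <- tornado_regression(psa, "delta_cost_short")
  expect_true("costs_short.genotyping_panel" %in% tor$parameter[1:10])
})

test_that("univariate sweeps move only the requested parameter", {
  p <- base_params()
  sw <- univariate_sweep(p, "costs_short.genotyping_panel", 0.25, "short_saving")
  base <- compare_short_term(p)$saving
  g <- get_parameter(p, "costs_short.genotyping_panel")
  expect_equal(sw$base, base)
  # saving is linear in the genotyping cost with slope -1
  expect_equal(sw$low, base + 0.25 * g, tolerance = 1e-9)
  expect_equal(sw$high, base - 0.25 * g, tolerance = 1e-9)
  z <- univariate_sweep(p, "markov.discount_rate", 0, "long_saving")
  expect_equal(z$low, z$base)
  expect_equal(z$high, z$base)
  expect_error(univariate_sweep(p, "not.a.parameter"), "unknown parameter")
})
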