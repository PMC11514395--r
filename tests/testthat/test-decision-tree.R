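test_that("pathways partition the probability space with 18 leaves per cell", {
  p <- base_params()
  for (s in c("PGX", "SOC")) {
    paths <- enumerate_pathways(s, p)
    expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
    per_cell <- table(paste(paths$gene, paths$class))
    expect_true(all(per_cell == 18))
    # leaf grammar: dispositions only on failure outcomes, suicide split only
    # after attempts
    succ <- paths$outcome %in% c("RESPONSE_NO_SE_NO_RELAPSE", "RESPONSE_SE_NO_RELAPSE")
    expect_true(all(is.na(paths$disposition[succ])))
    expect_true(all(!is.na(paths$disposition[!succ])))
    expect_true(all(is.na(paths$suicide_result) ==
                      (is.na(paths$disposition) | paths$disposition != "SUICIDE_ATTEMPT")))
    expect_false("TITRATE" %in% paths$disposition[grepl("RELAPSE$", paths$outcome)])
  }
})

test_that("degenerate probabilities concentrate mass on the expected leaves", {
  p <- base_params()
  p$clinical$p_response <- 1
  p$clinical$p_relapse_given_response <- 0
  paths <- enumerate_pathways("PGX", p)
  pos <- paths[paths$probability > 0, ]
  expect_true(all(pos$outcome %in% c("RESPONSE_NO_SE_NO_RELAPSE",
                                     "RESPONSE_SE_NO_RELAPSE")))
  expect_equal(sum(pos$probability), 1, tolerance = 1e-12)

  p$clinical$p_side_effect <- 0
  out <- strategy_outcomes("PGX", p)
  expect_equal(out$p_success_no_se, 1, tolerance = 1e-12)
})

test_that("pathway costs follow the component rules", {
  p <- base_params()
  # discontinuation: half the first-line course plus a full alternative
  # (SoC CYP2D6 first-line course costs 25)
  disc <- list(strategy = "SOC", gene = "CYP2D6", class = "PM",
               outcome = "NO_RESPONSE", disposition = "DISCONTINUE")
  fixed <- p$costs_short[["lab_screening"]] + p$costs_short[["consultation"]]
  expect_equal(pathway_cost(disc, p), 12.5 + 25 + fixed)

  # observation vs switching differ by exactly the alternative course
  obs <- sw <- disc
  obs$disposition <- "OBSERVE"; sw$disposition <- "SWITCH"
  expect_equal(pathway_cost(sw, p) - pathway_cost(obs, p), 25)

  # a zeroed cost table prices every pathway at zero
  p0 <- p
  p0$costs_short[] <- 0
  p0$acquisition$first_line <- 0
  p0$acquisition$increased_dose <- 0
  p0$acquisition$discontinuation <- 0
  paths <- enumerate_pathways("PGX", p0)
  expect_true(all(paths$cost == 0))

  # missing acquisition entry is a configuration error
  p2 <- p
  p2$acquisition <- p2$acquisition[-1, ]
  expect_error(enumerate_pathways("SOC", p2), "configuration error")
})

test_that("expected cost is the probability-weighted pathway cost sum and is linear in cost entries", {
  p <- base_params()
  out <- strategy_outcomes("PGX", p)
  expect_equal(out$expected_cost,
               sum(out$pathways$probability * out$pathways$cost))
  expect_lte(out$p_success_no_se, out$p_success_any_se)

  # doubling the genotyping cost raises the guided arm's expectation by
  # exactly the original genotyping cost and leaves standard of care alone
  g <- get_parameter(p, "costs_short.genotyping_panel")
  p2 <- set_parameter(p, "costs_short.genotyping_panel", 2 * g)
  expect_equal(strategy_outcomes("PGX", p2)$expected_cost, out$expected_cost + g)
  expect_equal(strategy_outcomes("SOC", p2)$expected_cost,
               strategy_outcomes("SOC", p)$expected_cost)
})

test_that("removing the dose-reduction mapping equalizes acquisition expectations", {
  p <- base_params()
  # same clinical probabilities in both arms, PGx acquisition entries reset
  # to the standard-of-care ones, genotyping priced at zero: expected costs
  # must coincide
  soc_cl <- p$clinical[p$clinical$strategy == "SOC", ]
  pgx_cl <- soc_cl; pgx_cl$strategy <- "PGX"
  p$clinical <- rbind(pgx_cl, soc_cl)
  soc_d <- p$disposition[p$disposition$strategy == "SOC", ]
  pgx_d <- soc_d; pgx_d$strategy <- "PGX"
  p$disposition <- rbind(pgx_d, soc_d)
  soc_aq <- p$acquisition[p$acquisition$strategy == "SOC", ]
  pgx_aq <- soc_aq; pgx_aq$strategy <- "PGX"
  p$acquisition <- rbind(pgx_aq, soc_aq)
  p$costs_short[["genotyping_panel"]] <- 0
  cmp <- compare_short_term(p)
  expect_equal(cmp$delta_cost, 0, tolerance = 1e-9)
  expect_equal(cmp$delta_p_no_se, 0, tolerance = 1e-12)
  expect_equal(cmp$icer_no_se$label, "INDIFFERENT")
})

test_that("counting rescued alternative courses as success keeps endpoints nested", {
  p <- base_params()
  p$settings$count_alternative_success <- TRUE
  for (s in c("PGX", "SOC")) {
    out <- strategy_outcomes(s, p)
    base <- strategy_outcomes(s, base_params())
    expect_gt(out$p_success_no_se, base$p_success_no_se)
    expect_lte(out$p_success_no_se, out$p_success_any_se)
    expect_equal(out$expected_cost, base$expected_cost)  # costs unaffected
  }
})

test_that("a seeded patient-level microsimulation reproduces the tree expectations", {
  p <- base_params()
  for (s in c("PGX", "SOC")) {
    ms <- microsim_short(s, p, n = 2e5, seed = 99)
    out <- strategy_outcomes(s, p)
    expect_lt(abs(ms$p_no_se - out$p_success_no_se), 3 * ms$se_p_no_se)
    expect_lt(abs(ms$p_any_se - out$p_success_any_se), 3 * ms$se_p_any_se)
    expect_lt(abs(ms$cost - out$expected_cost), 3 * ms$se_cost)
  }
})

test_that("the compiled evaluator agrees exactly with the reference tree", {
  for (seed in c(2, 5, 17)) {
    p <- random_parameter_set(synthetic_spec(seed = seed))
    cm <- pgxcea:::compile_model(p)
    for (s in c("PGX", "SOC")) {
      f <- pgxcea:::eval_short_fast(cm, s)
      r <- strategy_outcomes(s, p)
      expect_equal(unname(f[["p_no_se"]]), r$p_success_no_se, tolerance = 1e-12)
      expect_equal(unname(f[["p_any_se"]]), r$p_success_any_se, tolerance = 1e-12)
      expect_equal(unname(f[["cost"]]), r$expected_cost, tolerance = 1e-10)
    }
  }
})

test_that("identical arms are indifferent", {
  p <- base_params()
  for (comp in c("clinical", "disposition", "acquisition")) {
    soc <- p[[comp]][p[[comp]]$strategy == "SOC", ]
    pgx <- soc; pgx$strategy <- "PGX"
    p[[comp]] <- rbind(pgx, soc)
  }
  p$costs_short[["genotyping_panel"]] <- 0
  cmp <- compare_short_term(p)
  expect_equal(cmp$delta_p_no_se, 0)
  expect_equal(cmp$delta_p_any_se, 0)
  expect_equal(cmp$delta_cost, 0, tolerance = 1e-9)
})
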