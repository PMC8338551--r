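test_that("one-way variation honours bounds, sharing and cost/effect separation", {
  cfg <- base_case_fixture()
  base <- compare_strategies(cfg)

  # a bound equal to the base value reproduces the base case
  cfg2 <- cfg
  cfg2$parameters$bodyweight$ci_low <- cfg2$parameters$bodyweight$mean
  noop <- one_way(cfg2, "bodyweight", "low")
  expect_equal(noop$delta_cost, base$delta_cost)
  expect_equal(noop$delta_effect, base$delta_effect)

  # a cost-only parameter never moves the incremental effectiveness
  for (b in c("low", "high")) {
    res <- one_way(cfg, "session_cost_gcsf", b)
    expect_equal(res$delta_effect, base$delta_effect)
    expect_false(res$delta_cost == base$delta_cost)
  }

  # a shared unit cost moves both arms: incremental cost changes only through
  # the difference of the arms' quantities
  res <- one_way(cfg, "missed_session_cost", "high")
  p <- cfg$parameters$missed_session_cost
  expect_equal(res$delta_cost - base$delta_cost,
               (0.48 - 0.95) * (p$ci_high - p$mean), tolerance = 1e-9)

  # the mixture endpoint: no plerixafor in the chemo-free arm
  endpoint <- compare_strategies(cfg, values = c(p_plx_gcsf = 0))
  expect_equal(unname(endpoint$effectiveness[2]), 0.702)

  expect_error(one_way(cfg, "plx_price_per_vial"), "no declared CI")
  expect_error(one_way(cfg, "not_a_parameter"), "unknown parameter")
})

test_that("tornado ordering matches a brute-force enumeration of bound runs", {
  cfg <- tiny_config()
  tor <- tornado(cfg)
  eligible <- c("e_with_plx", "e_without_plx", "p_plx_a", "qty_a", "cost_b")
  expect_setequal(unique(tor$parameter), eligible)
  expect_equal(nrow(tor), 2 * length(eligible))

  base_ratio <- compare_strategies(cfg)$icer_ratio
  # independent oracle: direct evaluation of every bound via value overrides
  brute <- sapply(eligible, function(nm) {
    p <- cfg$parameters[[nm]]
    r <- sapply(c(p$ci_low, p$ci_high), function(v) {
      compare_strategies(cfg, values = stats::setNames(v, nm))$icer_ratio
    })
    max(abs(100 * (r - base_ratio) / abs(base_ratio)))
  })
  expect_identical(unique(tor$parameter),
                   names(sort(brute, decreasing = TRUE)))
  spread <- tapply(abs(tor$pct_deviation), tor$parameter, max)
  expect_equal(as.numeric(spread[names(brute)]), unname(brute),
               tolerance = 1e-9)
})

test_that("a tornado over a single or no uncertain parameter degenerates cleanly", {
  cfg <- tiny_config()
  keep <- "qty_a"
  cfg$parameters <- lapply(cfg$parameters, function(p) {
    if (p$name != keep) { p$ci_low <- NA_real_; p$ci_high <- NA_real_ }
    p
  })
  tor <- tornado(cfg)
  expect_equal(nrow(tor), 2)
  expect_equal(unique(tor$parameter), "qty_a")

  cfg$parameters[[keep]]$ci_low <- NA_real_
  cfg$parameters[[keep]]$ci_high <- NA_real_
  tor0 <- tornado(cfg)
  expect_equal(nrow(tor0), 0)
  expect_named(tor0, c("parameter", "bound", "value", "icer", "icer_ratio",
                       "pct_deviation"))
})

test_that("scenario presets reproduce the published sensitivity table", {
  cfg <- base_case_fixture()

  same <- run_scenario(cfg, "same_effectiveness")
  expect_equal(same$label, "weakly_dominant")
  expect_equal(same$delta_effect, 0)

  rev <- run_scenario(cfg, "reversed_effectiveness")
  expect_true(is.na(rev$label))
  expect_lt(abs(rev$icer - 23049.81), 0.5)

  dh <- run_scenario(cfg, "ctx_day_hospital")
  expect_lt(abs(dh$icer_ratio - 5226.29) / 5226.29, 0.001)
  expect_equal(unname(dh$cost), c(8438.32, 8708.42))

  out <- run_scenario(cfg, "outpatient_apheresis_chemo")
  expect_lt(abs(out$delta_cost - -1102.41), 0.02)
  expect_equal(out$label, "strongly_dominant")

  neu <- run_scenario(cfg, "reversed_neutropenia_setting")
  expect_lt(abs(neu$delta_cost - -1075.03), 0.02)
  expect_equal(neu$label, "strongly_dominant")

  cvc <- run_scenario(cfg, "cvc_for_chemo_free")
  expect_lt(abs(cvc$delta_cost - -1127.81), 0.03)
  expect_equal(cvc$label, "strongly_dominant")

  err <- tryCatch(run_scenario(cfg, "no_such_scenario"),
                  error = conditionMessage)
  expect_match(err, "same_effectiveness")

  tab <- scenarios_table(cfg)
  expect_equal(tab$scenario, scenario_presets())
})

test_that("Monte Carlo with degenerate distributions reduces to the base case", {
  cfg <- degenerate_config()
  psa <- run_psa(cfg, n = 1, seed = 123)
  expect_lt(abs(psa$draws$delta_cost - -1198.59), 0.02)
  expect_equal(psa$draws$delta_effect, 0.05168, tolerance = 1e-9)
  expect_equal(psa$draws$quadrant, "SE")
})

test_that("Monte Carlo runs are reproducible and recover configured means", {
  cfg <- base_case_fixture()
  p1 <- run_psa(cfg, n = 400, seed = 31)
  p2 <- run_psa(cfg, n = 400, seed = 31)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(cfg, n = 400, seed = 32)
  expect_false(identical(p1$draws, p3$draws))

  expect_equal(sum(p1$quadrant_shares), 1)
  expect_equal(p1$n, 400)
  expect_error(run_psa(cfg, n = 0), "n must be")

  psa <- run_psa(cfg, n = 4000, seed = 33)
  se <- stats::sd(psa$draws$delta_effect) / sqrt(psa$n)
  expect_lt(abs(psa$mean_delta_effect - 0.05168), 3 * se)
})

test_that("the acceptability curve matches brute-force counts and its limits", {
  psa <- fake_psa(c(-1, 1, -2), c(0.1, 0.1, -0.1))
  curve <- ceac(psa, c(0, 10, 1e9))
  # lambda 0: the cost-saving fraction, 2 of 3 draws
  expect_equal(curve$p_treatment[curve$lambda == 0], 2 / 3)
  expect_equal(curve$p_comparator[curve$lambda == 0], 1 / 3)
  # very large lambda: the fraction with positive incremental effectiveness
  expect_equal(curve$p_treatment[curve$lambda == 1e9], 2 / 3)
  # probabilities of the two strategies always sum to one
  expect_equal(curve$p_treatment + curve$p_comparator, rep(1, nrow(curve)))
  expect_error(ceac(psa, numeric(0)), "non-empty")
  expect_error(ceac(psa, c(-1, 0)), "lambda")

  # brute-force NMB count at an interior threshold
  lam <- 10
  manual <- mean(lam * psa$draws$delta_effect - psa$draws$delta_cost > 0)
  expect_equal(curve$p_treatment[curve$lambda == lam], manual)
})

test_that("the frontier picks the higher expected NMB and reports the switch point", {
  # mean dC > 0, mean dE > 0: the treatment becomes optimal at
  # lambda* = mean(dC)/mean(dE)
  psa <- fake_psa(c(100, 300), c(0.05, 0.15))   # means 200 and 0.1
  lambdas <- seq(0, 4000, by = 500)
  curve <- ceac(psa, lambdas)
  f <- ceaf(curve, psa)
  expect_equal(f$treatment_optimal_from, 2500)  # first grid point above 2000
  expect_true(all(curve$frontier_strategy[lambdas <= 2000] == "comparator"))
  # ties (lambda exactly 2000) go to the comparator
  expect_equal(curve$frontier_strategy[curve$lambda == 2000], "comparator")
  # frontier probability is always one of the two acceptability values
  expect_true(all(curve$frontier_probability == curve$p_treatment |
                  curve$frontier_probability == curve$p_comparator))

  # single-iteration run: the frontier follows that iteration's preference
  one <- fake_psa(-5, 0.01)
  c1 <- ceac(one, c(0, 1000))
  expect_equal(unique(c1$frontier_strategy), "treatment")

  expect_error(ceaf(curve, fake_psa(1, 1, seed = 99L)), "different runs")
})
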