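test_that("the generator is deterministic and always produces valid configs", {
  a <- random_model_config(generator_spec(seed = 7))
  b <- random_model_config(generator_spec(seed = 7))
  expect_identical(config_digest(a), config_digest(b))
  expect_false(identical(config_digest(a),
                         config_digest(random_model_config(generator_spec(seed = 8)))))

  for (s in 1:40) {
    cfg <- random_model_config(generator_spec(seed = s))
    expect_length(validate_config(cfg), 0)
    # both arms share the effectiveness pair; every payer is represented
    expect_identical(cfg$strategies[[1]]$e_with_plx,
                     cfg$strategies[[2]]$e_with_plx)
    for (s2 in cfg$strategies) {
      expect_setequal(unique(vapply(s2$cost_items, function(it) it$payer,
                                    character(1))), payers())
    }
  }
})

test_that("generated effectiveness obeys the closed-form increment", {
  for (s in 1:40) {
    cfg <- random_model_config(generator_spec(seed = s))
    res <- compare_strategies(cfg)
    p1 <- cfg$parameters[[cfg$strategies[[2]]$p_plx]]$mean
    p2 <- cfg$parameters[[cfg$strategies[[1]]$p_plx]]$mean
    gap <- cfg$parameters$e_with_plx$mean - cfg$parameters$e_without_plx$mean
    expect_lt(abs(res$delta_effect - (p1 - p2) * gap), 1e-12)
  }
})

test_that("generated gamma CIs are exactly invertible by the shape fitter", {
  cfg <- random_model_config(generator_spec(seed = 13, cv = 0.4))
  gammas <- Filter(function(p) p$dist == "gamma", cfg$parameters)
  expect_gt(length(gammas), 0)
  for (p in gammas) {
    f <- fit_shape_to_quantiles(p$mean, p$ci_low, p$ci_high)
    expect_equal(f$par[["shape"]], 6.25, tolerance = 0.02,
                 label = paste("shape recovered for", p$name))
  }
  # a different generating CV round-trips too
  cfg2 <- random_model_config(generator_spec(seed = 13, cv = 0.25))
  p <- Filter(function(p) p$dist == "gamma", cfg2$parameters)[[1]]
  f2 <- fit_shape_to_quantiles(p$mean, p$ci_low, p$ci_high)
  expect_equal(f2$par[["shape"]], 16, tolerance = 0.02)
})

test_that("perturbations satisfy their metamorphic contracts", {
  cfg <- random_model_config(generator_spec(seed = 21))
  base <- compare_strategies(cfg)

  doubled <- compare_strategies(perturb(cfg, "scale_costs", k = 2))
  expect_equal(doubled$delta_cost, 2 * base$delta_cost, tolerance = 1e-9)
  expect_equal(doubled$delta_effect, base$delta_effect)
  if (!is.na(base$icer_ratio)) {
    expect_equal(doubled$icer_ratio, 2 * base$icer_ratio, tolerance = 1e-9)
  }

  common <- compare_strategies(perturb(cfg, "add_common_item", c = 777))
  expect_equal(common$delta_cost, base$delta_cost, tolerance = 1e-9)

  # widening by a factor of one is the identity, including for sampling
  same <- perturb(cfg, "widen_cis", f = 1)
  expect_identical(config_digest(same), config_digest(cfg))
  expect_identical(run_psa(same, 50, seed = 3)$draws,
                   run_psa(cfg, 50, seed = 3)$draws)

  wide <- perturb(cfg, "widen_cis", f = 2)
  p <- Filter(function(q) q$dist == "gamma", cfg$parameters)[[1]]
  q <- wide$parameters[[p$name]]
  expect_equal(q$ci_high - q$mean, 2 * (p$ci_high - p$mean), tolerance = 1e-12)

  expect_error(perturb(cfg, "scale_costs", k = 0), "k must be")
  expect_error(perturb(cfg, "add_common_item", c = -1), "c must be")
  expect_error(perturb(cfg, "widen_cis", f = 0.5), "f must be")
})

test_that("all five dominance labels occur across seeded configurations", {
  labels <- vapply(1:300, function(s) {
    res <- compare_strategies(random_model_config(generator_spec(seed = s)))
    if (is.na(res$label)) "numeric" else res$label
  }, character(1))
  expect_setequal(
    intersect(unique(labels),
              c("strongly_dominant", "strongly_dominated", "weakly_dominant",
                "weakly_dominated", "indeterminate")),
    c("strongly_dominant", "strongly_dominated", "weakly_dominant",
      "weakly_dominated", "indeterminate")
  )
  expect_true("numeric" %in% labels)
})

test_that("infeasible generator settings are rejected", {
  expect_error(generator_spec(p_plx_range = c(0.5, 1.2)), "outside")
  expect_error(generator_spec(n_items = c(5, 2)), "well-ordered")
  expect_error(generator_spec(cv = 0), "cv")
  expect_error(generator_spec(n_items = c(2, 5)), ">= 3")
})
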