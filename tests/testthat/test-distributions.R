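test_that("gamma from mean and CV has exact moments and the reported CIs", {
  d <- gamma_from_mean_cv(2.00, 0.4)
  expect_equal(d$par[["shape"]], 6.25)
  expect_equal(d$par[["scale"]], 0.32)
  expect_equal(d$par[["shape"]] * d$par[["scale"]], 2.00)
  q <- dist_quantile(d, c(0.025, 0.975))
  expect_equal(q, c(0.7527, 3.8461), tolerance = 1e-4)

  # bodyweight row: mean 70 kg, 95% CI (26.34, 134.61)
  d70 <- gamma_from_mean_cv(70, 0.4)
  expect_equal(dist_quantile(d70, c(0.025, 0.975)), c(26.34, 134.61),
               tolerance = 2e-4)

  # degenerate limit: CI collapses onto the mean
  d0 <- gamma_from_mean_cv(5, 1e-5)
  expect_equal(dist_quantile(d0, c(0.025, 0.975)), c(5, 5), tolerance = 1e-3)

  expect_error(gamma_from_mean_cv(0, 0.4), "mean")
  expect_error(gamma_from_mean_cv(2, -1), "cv")
})

test_that("fitting a gamma shape to reported CI bounds recovers the CV-0.4 shape", {
  f1 <- fit_shape_to_quantiles(2.00, 0.75, 3.85)
  expect_equal(f1$par[["shape"]], 6.25, tolerance = 0.1 / 6.25)
  q <- dist_quantile(f1, c(0.025, 0.975))
  expect_lt(max(abs(q - c(0.75, 3.85))), 0.01)

  f2 <- fit_shape_to_quantiles(1.60, 0.60, 3.08)
  expect_equal(f2$par[["shape"]], 6.25, tolerance = 0.1 / 6.25)

  # a reported lower bound of zero forces the shape below one
  f3 <- fit_shape_to_quantiles(0.35, 0.00, 2.04)
  expect_lt(f3$par[["shape"]], 1)

  # mean always preserved exactly
  for (f in list(f1, f2, f3)) {
    expect_equal(f$par[["shape"]] * f$par[["scale"]], f$source_mean)
  }
  expect_error(fit_shape_to_quantiles(5, 0.75, 3.85), "inside")
})

test_that("beta from mean and sd preserves the mean and rejects infeasible sd", {
  d <- beta_from_mean_sd(0.702, 0.05)
  a <- d$par[["alpha"]]; b <- d$par[["beta"]]
  expect_equal(a / (a + b), 0.702)

  tiny <- beta_from_mean_sd(0.5, 1e-4)
  expect_equal(dist_quantile(tiny, c(0.025, 0.975)), c(0.5, 0.5),
               tolerance = 1e-3)

  err <- tryCatch(beta_from_mean_sd(0.9, 0.5), error = conditionMessage)
  expect_match(err, "infeasible")
  expect_match(err, "0.09")  # feasibility bound mean*(1-mean)
})

test_that("quantile/CDF round trip is exact to 1e-10", {
  dists <- list(gamma_from_mean_cv(2, 0.4),
                fit_shape_to_quantiles(0.48, 0.18, 0.92),
                beta_from_mean_sd(0.47, 0.188),
                uniform_dist(1, 3))
  for (d in dists) {
    for (p in c(0.025, 0.5, 0.975)) {
      expect_equal(dist_cdf(d, dist_quantile(d, p)), p, tolerance = 1e-10)
    }
  }
})

test_that("sampling is reproducible, i.i.d. from the family, and mean-recovering", {
  d <- gamma_from_mean_cv(2, 0.4)
  set.seed(11); x1 <- sample_dist(d, 1000)
  set.seed(11); x2 <- sample_dist(d, 1000)
  expect_identical(x1, x2)

  set.seed(12)
  x <- sample_dist(d, 1e5)
  sd_g <- sqrt(6.25) * 0.32
  expect_lt(abs(mean(x) - 2), 3 * sd_g / sqrt(1e5))

  expect_equal(sample_dist(fixed_dist(3.5), 7), rep(3.5, 7))
  expect_error(sample_dist(d, 0), "n")

  # empirical tail quantiles converge to the analytic ones
  expect_equal(unname(stats::quantile(x, c(0.025, 0.975))),
               dist_quantile(d, c(0.025, 0.975)), tolerance = 0.02)
})

test_that("every fixture resource-quantity CI refits to shape 6.25", {
  cfg <- base_case_fixture()
  rows <- c("ctx_days", "apheresis_sessions_gcsf", "apheresis_sessions_ctx",
            "missed_sessions_gcsf", "missed_sessions_ctx", "bodyweight")
  for (nm in rows) {
    p <- cfg$parameters[[nm]]
    f <- fit_shape_to_quantiles(p$mean, p$ci_low, p$ci_high)
    expect_equal(f$par[["shape"]], 6.25, tolerance = 0.15 / 6.25,
                 label = paste("shape for", nm))
  }
})

test_that("per-parameter substreams are independent of the parameter set", {
  cfg <- tiny_config()
  d1 <- sample_params(cfg, 50, seed = 99)
  cfg2 <- cfg
  cfg2$parameters$extra_param <- uncertain_quantity("extra_param", 1,
                                                    dist = "fixed")
  d2 <- sample_params(cfg2, 50, seed = 99)
  for (nm in colnames(d1)) expect_identical(d1[, nm], d2[, nm])

  # fixed families never vary; probability draws stay inside [0, 1]
  cfgb <- base_case_fixture()
  db <- sample_params(cfgb, 200, seed = 5)
  expect_true(all(db[, "plx_price_per_vial"] == 5064.86))
  expect_true(all(db[, "ctx_drug_cost"] == 128.13))
  for (nm in c("p_plx_gcsf", "p_plx_ctx", "e_with_plx", "e_without_plx")) {
    expect_true(all(db[, nm] >= 0 & db[, nm] <= 1))
  }
})

test_that("distribution diagnostics cover every parameter", {
  cfg <- base_case_fixture()
  dg <- dist_diagnostics(cfg)
  expect_setequal(dg$parameter, names(cfg$parameters))
  expect_true(all(dg$family %in% c("gamma", "beta", "bernoulli", "uniform",
                                   "fixed")))
})
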