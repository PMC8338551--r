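# Small hand-built configuration with three uncertain parameters, used for
# brute-force one-way/tornado oracles.
tiny_config <- function() {
  params <- list(
    uncertain_quantity("e_with_plx", 0.8, 0.65, 0.95, "beta", "probability"),
    uncertain_quantity("e_without_plx", 0.6, 0.4, 0.75, "beta", "probability"),
    uncertain_quantity("p_plx_a", 0.5, 0.2, 0.8, "beta", "probability"),
    uncertain_quantity("p_plx_b", 0.1, dist = "fixed", units = "probability"),
    uncertain_quantity("qty_a", 2, 0.75, 3.85, "gamma", "sessions"),
    uncertain_quantity("cost_a", 100, dist = "fixed", units = "EUR"),
    uncertain_quantity("cost_b", 500, 200, 900, "gamma", "EUR")
  )
  names(params) <- vapply(params, function(p) p$name, character(1))
  a <- strategy_definition(
    "arm A",
    list(cost_item("sessions", "apheresis_procedures", "INHS", "qty_a", "cost_a"),
         cost_item("extra", "transportation", "out_of_pocket", character(), "cost_b")),
    "p_plx_a", "e_with_plx", "e_without_plx"
  )
  b <- strategy_definition(
    "arm B",
    list(cost_item("flat", "stem_cell_handling", "INHS", character(), "cost_b")),
    "p_plx_b", "e_with_plx", "e_without_plx"
  )
  model_config(list(a, b), params,
               demographics = list(age = "age", employed_fraction = 0.5,
                                   retirement_age = 70),
               wages = list(gross = 25, net = 15))
}

# Configuration with every distribution degenerate at its mean: Monte Carlo
# reduces to the deterministic base case.
degenerate_config <- function(config = base_case_fixture()) {
  config$parameters <- lapply(config$parameters, function(p) {
    p$dist <- "fixed"
    p
  })
  config
}

# Minimal psa_result wrapper around explicit (delta_cost, delta_effect) draws,
# for brute-force CEAC/CEAF checks.
fake_psa <- function(delta_cost, delta_effect, seed = 0L) {
  n <- length(delta_cost)
  structure(
    list(draws = data.frame(iteration = seq_len(n), delta_cost = delta_cost,
                            delta_effect = delta_effect),
         quadrant_shares = NULL, mean_delta_cost = mean(delta_cost),
         mean_delta_effect = mean(delta_effect), n = n, seed = seed),
    class = "psa_result"
  )
}
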