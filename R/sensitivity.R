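#' @title Sensitivity analyses
#' @description One-way (tornado) analysis over reported 95% CIs or ranges,
#'   named scenario analyses, and probabilistic sensitivity analysis with
#'   cost-effectiveness acceptability curve and frontier.
#' @name sensitivity
NULL

has_interval <- function(p) {
  !is.na(p$ci_low) && !is.na(p$ci_high) && p$ci_high > p$ci_low
}

#' One-way sensitivity analysis for a single parameter
#'
#' Re-evaluates the comparison with one parameter set to the lower or upper
#' limit of its 95% CI (or range), all others at base case. Parameters shared
#' between the arms move both arms simultaneously; arm-specific parameters
#' move only their own arm.
#'
#' @param config a [model_config()] object.
#' @param parameter parameter name; must have a declared interval.
#' @param bound `"low"` or `"high"`.
#' @param ... passed to [compare_strategies()].
#' @return a `cea_result`.
#' @export
one_way <- function(config, parameter, bound = c("low", "high"), ...) {
  bound <- match.arg(bound)
  p <- config$parameters[[parameter]]
  if (is.null(p)) stop("unknown parameter '", parameter, "'", call. = FALSE)
  if (!has_interval(p)) {
    stop("parameter '", parameter, "' has no declared CI or range", call. = FALSE)
  }
  v <- stats::setNames(if (bound == "low") p$ci_low else p$ci_high, parameter)
  compare_strategies(config, values = v, ...)
}

#' Tornado analysis
#'
#' Runs [one_way()] at both bounds for every parameter with a declared
#' interval and reports the percent deviation of the raw ICER ratio from the
#' base-case raw ratio, sorted widest-first (descending maximum absolute
#' deviation per parameter).
#'
#' @param config a [model_config()] object.
#' @param ... passed to [compare_strategies()].
#' @return data.frame of class `tornado_result`: `parameter`, `bound`,
#'   `value`, `icer` (label or formatted number), `icer_ratio`,
#'   `pct_deviation`.
#' @export
tornado <- function(config, ...) {
  base <- compare_strategies(config, ...)
  base_ratio <- base$icer_ratio
  eligible <- Filter(has_interval, config$parameters)
  rows <- lapply(eligible, function(p) {
    do.call(rbind, lapply(c("low", "high"), function(b) {
      res <- one_way(config, p$name, b, ...)
      data.frame(
        parameter = p$name, bound = b,
        value = if (b == "low") p$ci_low else p$ci_high,
        icer = if (is.na(res$label)) format_euro(res$icer_ratio) else res$label,
        icer_ratio = res$icer_ratio,
        pct_deviation = 100 * (res$icer_ratio - base_ratio) / abs(base_ratio),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parameter = character(), bound = character(),
                      value = numeric(), icer = character(),
                      icer_ratio = numeric(), pct_deviation = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (nrow(out)) {
    spread <- tapply(abs(out$pct_deviation), out$parameter, max)
    out <- out[order(-spread[out$parameter], out$parameter, out$bound), ]
    rownames(out) <- NULL
  }
  class(out) <- c("tornado_result", "data.frame")
  out
}

SCENARIO_PRESETS <- c("base", "same_effectiveness", "reversed_effectiveness",
                      "ctx_day_hospital", "reversed_neutropenia_setting",
                      "cvc_for_chemo_free", "outpatient_apheresis_chemo")

#' Scenario sensitivity analysis
#'
#' Evaluates a named structural scenario. Presets:
#' \describe{
#'   \item{base}{the unmodified base case.}
#'   \item{same_effectiveness}{both arms share the treatment's effectiveness
#'     (equal effectiveness; the cheaper arm is weakly dominant).}
#'   \item{reversed_effectiveness}{the arms' effectiveness values are swapped;
#'     reported by default in `"printed"` rounding mode, matching the
#'     published table's arithmetic on rounded increments.}
#'   \item{ctx_day_hospital}{cyclophosphamide administered in the day-hospital
#'     setting; published arm totals 8438.32 (comparator) and 8708.42
#'     (treatment) euro.}
#'   \item{reversed_neutropenia_setting}{inpatient/outpatient management of
#'     febrile neutropenia reversed; comparator total 9114.88 euro.}
#'   \item{cvc_for_chemo_free}{central venous catheter also for
#'     chemotherapy-free patients; treatment total 8110.62 euro.}
#'   \item{outpatient_apheresis_chemo}{outpatient apheresis in the
#'     chemotherapy arm; comparator total 9142.26 euro.}
#' }
#' The cost-override presets carry published arm totals because the underlying
#' tariff compositions are not part of the configuration.
#'
#' @param config a [model_config()] object.
#' @param scenario one of the presets above.
#' @param rounding `NULL` for the preset's default mode, else `"unrounded"`
#'   or `"printed"`.
#' @return a `cea_result` with the scenario recorded in `$scenario`.
#' @export
#' @examples
#' run_scenario(base_case_fixture(), "same_effectiveness")$label
run_scenario <- function(config, scenario, rounding = NULL) {
  if (!scenario %in% SCENARIO_PRESETS) {
    stop("unknown scenario '", scenario, "'; available presets: ",
         paste(SCENARIO_PRESETS, collapse = ", "), call. = FALSE)
  }
  if (is.null(rounding)) {
    rounding <- if (scenario == "reversed_effectiveness") "printed" else "unrounded"
  }
  base <- compare_strategies(config, rounding = rounding)
  costs <- unname(base$cost)
  effects <- unname(base$effectiveness)
  switch(scenario,
    base = NULL,
    same_effectiveness = { effects[1] <- effects[2] },
    reversed_effectiveness = { effects <- rev(effects) },
    ctx_day_hospital = { costs <- c(8438.32, 8708.42) },
    reversed_neutropenia_setting = { costs[1] <- 9114.88 },
    cvc_for_chemo_free = { costs[2] <- 8110.62 },
    outpatient_apheresis_chemo = { costs[1] <- 9142.26 }
  )
  cea_from_arms(c(base$comparator, base$treatment), costs, effects,
                rounding = rounding, scenario = scenario)
}

#' @rdname run_scenario
#' @export
scenario_presets <- function() SCENARIO_PRESETS

#' All scenario presets as one table
#'
#' @param config a [model_config()] object.
#' @return data.frame with one row per preset (base case first).
#' @export
scenarios_table <- function(config) {
  rows <- lapply(SCENARIO_PRESETS, function(sc) {
    as.data.frame(run_scenario(config, sc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of all parameter distributions through the model.
#' Each iteration draws every uncertain parameter from its assigned
#' distribution (deterministic per-parameter substreams derived from the
#' master seed; the shared effectiveness pair is drawn once per iteration and
#' used by both arms; parameters with family `fixed`, including drug
#' acquisition costs and wage rates, stay constant), evaluates both arms, and
#' records the incremental cost, incremental effectiveness and
#' cost-effectiveness-plane quadrant.
#'
#' @param config a [model_config()] object.
#' @param n number of iterations, `>= 1` (published analysis: 10,000).
#' @param seed master integer seed.
#' @param perspective `"societal"` or `"INHS_only"`.
#' @return an object of class `psa_result`: `draws` data.frame (`iteration`,
#'   per-arm costs/effects, `delta_cost`, `delta_effect`, `quadrant`),
#'   `quadrant_shares`, `mean_delta_cost`, `mean_delta_effect`, `n`, `seed`.
#' @export
run_psa <- function(config, n = 10000, seed = 1,
                    perspective = c("societal", "INHS_only")) {
  perspective <- match.arg(perspective)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  draws <- sample_params(config, n, seed)

  arm_matrices <- lapply(config$strategies, function(s) {
    eff <- mixture_effectiveness(draws[, s$p_plx],
                                 draws[, s$e_with_plx],
                                 draws[, s$e_without_plx])
    cost <- numeric(n)
    for (it in s$cost_items) {
      if (perspective == "INHS_only" && it$payer != "INHS") next
      qty <- rep(1, n)
      for (f in it$quantity_factors) qty <- qty * draws[, f]
      cost <- cost + qty * draws[, it$unit_cost]
    }
    list(eff = eff, cost = cost)
  })
  cmp <- arm_matrices[[1]]; trt <- arm_matrices[[2]]
  dc <- trt$cost - cmp$cost
  de <- trt$eff - cmp$eff
  quad <- classify_quadrant(dc, de)
  shares <- vapply(c("NE", "NW", "SE", "SW"),
                   function(q) sum(quad == q) / n, numeric(1))
  structure(
    list(
      draws = data.frame(iteration = seq_len(n),
                         cost_comparator = cmp$cost, cost_treatment = trt$cost,
                         effect_comparator = cmp$eff, effect_treatment = trt$eff,
                         delta_cost = dc, delta_effect = de, quadrant = quad,
                         stringsAsFactors = FALSE),
      quadrant_shares = shares,
      mean_delta_cost = mean(dc), mean_delta_effect = mean(de),
      n = n, seed = as.integer(seed), perspective = perspective,
      comparator = config$strategies[[1]]$name,
      treatment = config$strategies[[2]]$name
    ),
    class = "psa_result"
  )
}

#' Default willingness-to-pay grid
#'
#' 0 to 100,000 euro per successful apheresis in steps of 1,000, always
#' containing the commonly quoted Italian thresholds 25,000 and 40,000.
#'
#' @return numeric vector of lambda values.
#' @export
default_lambda_grid <- function() seq(0, 100000, by = 1000)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability (fraction of Monte
#' Carlo iterations) that the treatment has the higher net monetary benefit —
#' strictly positive incremental NMB, with exact ties credited to the
#' comparator — together with the complementary probability for the
#' comparator, and the frontier strategy (the one with the higher expected
#' NMB; the comparator wins exact ties).
#'
#' @param psa a `psa_result`.
#' @param lambdas non-empty, non-negative threshold grid.
#' @return data.frame of class `ceac_result`: `lambda`, `p_treatment`,
#'   `p_comparator`, `frontier_strategy`, `frontier_probability`.
#' @export
ceac <- function(psa, lambdas = default_lambda_grid()) {
  if (length(lambdas) == 0) stop("lambda grid must be non-empty", call. = FALSE)
  if (any(lambdas < 0)) stop("lambda must be >= 0", call. = FALSE)
  dc <- psa$draws$delta_cost
  de <- psa$draws$delta_effect
  rows <- lapply(lambdas, function(l) {
    inmb <- l * de - dc
    p_trt <- mean(inmb > 0)
    mean_inmb <- l * mean(de) - mean(dc)
    frontier <- if (mean_inmb > 0) "treatment" else "comparator"
    data.frame(lambda = l, p_treatment = p_trt, p_comparator = 1 - p_trt,
               frontier_strategy = frontier,
               frontier_probability = if (frontier == "treatment") p_trt else 1 - p_trt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "psa_id") <- c(n = psa$n, seed = psa$seed)
  class(out) <- c("ceac_result", "data.frame")
  out
}

#' Cost-effectiveness acceptability frontier
#'
#' Annotates an acceptability curve with the optimal strategy per threshold
#' (the argmax of expected net monetary benefit) and reports the smallest grid
#' threshold from which the treatment is optimal (`NA` if never).
#'
#' @param curve a `ceac_result` produced from `psa`.
#' @param psa the `psa_result` the curve was computed from.
#' @return list of class `ceaf_result`: `frontier` (data.frame `lambda`,
#'   `strategy`, `probability`), `treatment_optimal_from`.
#' @export
ceaf <- function(curve, psa) {
  id <- attr(curve, "psa_id")
  if (is.null(id) || id[["n"]] != psa$n || id[["seed"]] != psa$seed) {
    stop("curve and psa come from different runs", call. = FALSE)
  }
  frontier <- data.frame(lambda = curve$lambda,
                         strategy = curve$frontier_strategy,
                         probability = curve$frontier_probability,
                         stringsAsFactors = FALSE)
  opt <- curve$lambda[curve$frontier_strategy == "treatment"]
  structure(
    list(frontier = frontier,
         treatment_optimal_from = if (length(opt)) min(opt) else NA_real_),
    class = "ceaf_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, seed %d (%s perspective)\n",
              x$n, x$seed, x$perspective))
  cat(sprintf("  mean dC %.2f EUR, mean dE %.5f\n",
              x$mean_delta_cost, x$mean_delta_effect))
  cat("  quadrant shares: ",
      paste(sprintf("%s %.2f%%", names(x$quadrant_shares),
                    100 * x$quadrant_shares), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.ceaf_result <- function(x, ...) {
  cat(sprintf("<ceaf_result> treatment optimal from lambda = %s\n",
              format(x$treatment_optimal_from)))
  invisible(x)
}

#' Plot the cost-effectiveness plane of a PSA
#'
#' @param x a `psa_result`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.psa_result <- function(x, ...) {
  graphics::plot(x$draws$delta_effect, x$draws$delta_cost,
                 pch = 16, cex = 0.3, col = "#00000055",
                 xlab = "Incremental effectiveness",
                 ylab = "Incremental cost (EUR)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "red")
  invisible(x)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x a `ceac_result`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.ceac_result <- function(x, ...) {
  graphics::plot(x$lambda, x$p_treatment, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (EUR per successful apheresis)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::lines(x$lambda, x$p_comparator, lty = 2)
  graphics::legend("right", legend = c("treatment", "comparator"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
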