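#' @title Incremental cost-effectiveness arithmetic
#' @description ICER with dominance classification, net monetary benefit and
#'   cost-effectiveness-plane quadrants for a two-strategy comparison
#'   (treatment minus comparator).
#' @name cea_core
NULL

DOMINANCE_LABELS <- c("strongly_dominant", "strongly_dominated",
                      "weakly_dominant", "weakly_dominated", "indeterminate")

ZERO_TOL <- 1e-12

#' ICER and dominance classification
#'
#' Classifies the incremental result on the cost-effectiveness plane. A
#' treatment that saves money and gains effectiveness is strongly dominant;
#' one that costs more and loses effectiveness is strongly dominated; with no
#' effectiveness difference the cheaper strategy is weakly dominant (weakly
#' dominated if more costly); otherwise the numeric ICER applies. The raw
#' quotient `delta_cost / delta_effect` is reported even under dominance.
#' Zero `delta_effect` is detected with tolerance `1e-12`.
#'
#' @param delta_cost incremental cost (treatment minus comparator), euro.
#' @param delta_effect incremental probability of successful apheresis.
#' @return an object of class `icer_result` with fields `delta_cost`,
#'   `delta_effect`, `icer` (number or dominance label), `label` and
#'   `icer_ratio` (raw quotient, `NA` when `delta_effect` is zero).
#' @export
#' @examples
#' icer(-1198.59, 0.05168)  # strongly dominant, ratio about -23192
icer <- function(delta_cost, delta_effect) {
  if (!is.finite(delta_cost) || !is.finite(delta_effect)) {
    stop("delta_cost and delta_effect must be finite", call. = FALSE)
  }
  e_zero <- abs(delta_effect) <= ZERO_TOL
  c_zero <- abs(delta_cost) <= ZERO_TOL
  label <- if (e_zero && c_zero) {
    "indeterminate"
  } else if (e_zero) {
    if (delta_cost < 0) "weakly_dominant" else "weakly_dominated"
  } else if (delta_cost < 0 && delta_effect > 0) {
    "strongly_dominant"
  } else if (delta_cost > 0 && delta_effect < 0) {
    "strongly_dominated"
  } else {
    NA_character_
  }
  ratio <- if (e_zero) NA_real_ else delta_cost / delta_effect
  structure(
    list(delta_cost = delta_cost, delta_effect = delta_effect,
         label = label,
         icer = if (is.na(label)) ratio else label,
         icer_ratio = ratio),
    class = "icer_result"
  )
}

#' Net monetary benefit
#'
#' Converts effectiveness to money at a willingness-to-pay threshold:
#' `lambda * effectiveness - cost`, linear in `lambda` with slope equal to the
#' effectiveness.
#'
#' @param cost strategy cost in euro.
#' @param effectiveness probability of successful apheresis.
#' @param lambda willingness to pay per successful apheresis, `>= 0`.
#' @return an object of class `nmb_value` (fields `lambda`, `value`).
#' @export
#' @examples
#' nmb(8039.85, 0.766, 25000)$value  # 11110.15
nmb <- function(cost, effectiveness, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  structure(list(lambda = lambda, value = lambda * effectiveness - cost),
            class = "nmb_value")
}

#' Cost-effectiveness-plane quadrant
#'
#' `NE`: more costly, more effective; `NW`: more costly, less effective;
#' `SE`: less costly, more effective; `SW`: less costly, less effective.
#' Boundary convention for zero incremental effectiveness (measure-zero in
#' Monte Carlo simulation): the draw is assigned by the sign of the
#' incremental cost, to `SE` if cost-saving and to `NW` otherwise, preserving
#' the identity "cost-effective at lambda 0 iff cost-saving".
#'
#' @param delta_cost incremental cost (vectorized).
#' @param delta_effect incremental effectiveness (vectorized).
#' @return character vector over `{"NE","NW","SE","SW"}`.
#' @export
classify_quadrant <- function(delta_cost, delta_effect) {
  if (any(!is.finite(delta_cost)) || any(!is.finite(delta_effect))) {
    stop("inputs must be finite", call. = FALSE)
  }
  ifelse(delta_effect > 0,
         ifelse(delta_cost > 0, "NE", "SE"),
         ifelse(delta_effect < 0,
                ifelse(delta_cost > 0, "NW", "SW"),
                ifelse(delta_cost < 0, "SE", "NW")))
}

#' Base-case cost-effectiveness comparison
#'
#' Evaluates both arms of a configuration (comparator first, treatment second)
#' and assembles costs, effectiveness, incremental cost and effectiveness, and
#' the classified ICER. With `rounding = "printed"` the increments are rounded
#' to report precision (cost to cents, effectiveness to 3 decimals) before the
#' ratio is taken, reproducing published-table arithmetic; the default divides
#' the unrounded increments.
#'
#' @param config a [model_config()] object.
#' @param values optional named parameter overrides.
#' @param perspective `"societal"` or `"INHS_only"`.
#' @param rounding `"unrounded"` (default) or `"printed"`.
#' @return an object of class `cea_result`.
#' @export
#' @examples
#' compare_strategies(base_case_fixture())
compare_strategies <- function(config, values = NULL,
                               perspective = c("societal", "INHS_only"),
                               rounding = c("unrounded", "printed")) {
  perspective <- match.arg(perspective)
  rounding <- match.arg(rounding)
  vals <- resolve_values(config, if (is.null(values)) NULL else values)
  arms <- lapply(config$strategies, function(s) {
    out <- evaluate_arm(s, config, vals)
    bd <- arm_cost_breakdown(out, s, config, vals)
    list(outcome = out, breakdown = bd, cost = total_cost(bd, perspective))
  })
  cea_from_arms(
    arm_names = vapply(config$strategies, function(s) s$name, character(1)),
    costs = vapply(arms, function(a) a$cost, numeric(1)),
    effects = vapply(arms, function(a) a$outcome$effectiveness, numeric(1)),
    rounding = rounding,
    breakdowns = lapply(arms, function(a) a$breakdown)
  )
}

cea_from_arms <- function(arm_names, costs, effects,
                          rounding = "unrounded", breakdowns = NULL,
                          scenario = NA_character_) {
  dc <- costs[2] - costs[1]
  de <- effects[2] - effects[1]
  if (rounding == "printed") {
    dc <- round(dc, 2)
    de <- round(de, 3)
  }
  ic <- icer(dc, de)
  structure(
    list(comparator = arm_names[1], treatment = arm_names[2],
         cost = stats::setNames(costs, arm_names),
         effectiveness = stats::setNames(effects, arm_names),
         delta_cost = dc, delta_effect = de,
         label = ic$label, icer = ic$icer, icer_ratio = ic$icer_ratio,
         quadrant = classify_quadrant(dc, de),
         rounding = rounding, breakdowns = breakdowns, scenario = scenario),
    class = "cea_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  lab <- if (is.na(x$label)) sprintf("ICER %.2f", x$icer_ratio) else x$label
  cat(sprintf("<icer_result> dC %.2f, dE %.5f: %s", x$delta_cost,
              x$delta_effect, lab))
  if (!is.na(x$label) && !is.na(x$icer_ratio)) {
    cat(sprintf(" (raw ratio %.2f)", x$icer_ratio))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s\n", x$treatment, x$comparator))
  for (nm in names(x$cost)) {
    cat(sprintf("  %-40s cost %9.2f  effectiveness %.3f\n",
                nm, x$cost[[nm]], x$effectiveness[[nm]]))
  }
  lab <- if (is.na(x$label)) sprintf("%.2f EUR per successful apheresis", x$icer)
         else sub("_", " ", x$label)
  cat(sprintf("  dC %.2f EUR, dE %.5f -> %s", x$delta_cost, x$delta_effect, lab))
  if (!is.na(x$label) && !is.na(x$icer_ratio)) {
    cat(sprintf(" (raw ratio %.2f)", x$icer_ratio))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.cea_result <- function(x, ...) {
  data.frame(
    scenario = x$scenario,
    comparator = x$comparator, treatment = x$treatment,
    cost_comparator = unname(x$cost[1]), cost_treatment = unname(x$cost[2]),
    effect_comparator = unname(x$effectiveness[1]),
    effect_treatment = unname(x$effectiveness[2]),
    delta_cost = x$delta_cost, delta_effect = x$delta_effect,
    icer = if (is.na(x$label)) format_euro(x$icer_ratio) else x$label,
    icer_ratio = x$icer_ratio,
    stringsAsFactors = FALSE
  )
}

format_euro <- function(x) sprintf("%.2f", round(x, 2))
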