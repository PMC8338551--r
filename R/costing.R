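#' @title Costing and valuation rules
#' @description Societal-perspective valuation: tariff-derived per-diem costs,
#'   hotel-cost halving to avoid double counting, gross/net wage valuation of
#'   time, and the payer-partitioned cost breakdown of one arm.
#' @name costing
NULL

#' Daily hospitalization cost from a tariff
#'
#' The total daily cost of an inpatient stay, obtained by dividing the
#' admission tariff by the mean length of stay.
#'
#' @param tariff non-negative admission tariff in euro.
#' @param mean_los mean duration of inpatient stay in days, `> 0`.
#' @return cost per inpatient day in euro.
#' @export
#' @examples
#' daily_hospital_cost(422.07, 2.00)  # 211.035 EUR/day
daily_hospital_cost <- function(tariff, mean_los) {
  if (any(tariff < 0)) stop("tariff must be non-negative", call. = FALSE)
  if (any(mean_los <= 0)) stop("mean_los must be > 0", call. = FALSE)
  tariff / mean_los
}

#' Hotel cost of a hospital stay
#'
#' When the clinical procedure included in a tariff is costed separately, the
#' tariff is halved so that only the hotel component of the stay is retained
#' (avoids double counting); otherwise the full tariff applies.
#'
#' @param tariff non-negative tariff in euro.
#' @param itemized_separately logical flag: is the procedure costed on its own?
#' @return euro amount.
#' @export
hotel_cost <- function(tariff, itemized_separately) {
  if (any(tariff < 0)) stop("tariff must be non-negative", call. = FALSE)
  ifelse(itemized_separately, tariff / 2, tariff)
}

#' Hourly rate for valuing a patient's time
#'
#' Working patients' lost hours are valued at the gross wage (net wage plus
#' income taxes and social-security contributions), blended with the net wage
#' for the non-employed fraction; patients at or above the retirement age are
#' assumed to substitute leisure for work, valued (like caregiver time) at the
#' take-home (net) wage.
#'
#' @param wages list with `gross` and `net` hourly rates in euro.
#' @param employed_fraction fraction of patients in employment.
#' @param age patient age in years.
#' @param retirement_age age from which leisure substitutes for work.
#' @return an hourly rate in euro.
#' @export
blended_time_rate <- function(wages, employed_fraction = 0.5, age = 0,
                              retirement_age = 70) {
  if (age >= retirement_age) {
    wages$net
  } else {
    employed_fraction * wages$gross + (1 - employed_fraction) * wages$net
  }
}

#' Monetary value of time
#'
#' Hours times an hourly rate. Productivity losses use the gross (blended)
#' wage rate; informal care and leisure time use the net wage rate — the
#' caller selects the applicable rate, e.g. via [blended_time_rate()].
#'
#' @param hours non-negative hours.
#' @param rate hourly rate in euro.
#' @param kind `"productivity"` or `"informal_or_leisure"` (documents which
#'   valuation rule the rate implements).
#' @return euro amount.
#' @export
#' @examples
#' time_cost(11.47, 21.72, "productivity")  # about 249 EUR
time_cost <- function(hours, rate, kind = c("productivity", "informal_or_leisure")) {
  kind <- match.arg(kind)
  if (any(hours < 0) || any(rate < 0)) {
    stop("hours and rate must be non-negative", call. = FALSE)
  }
  hours * rate
}

#' Payer-partitioned cost breakdown of one arm
#'
#' One row per cost item with its expected quantity, unit cost and expected
#' cost (quantity times unit cost), plus subtotals by payer and by category.
#' The payer subtotals partition the overall total exactly.
#'
#' @param outcome an `arm_outcome` from [evaluate_arm()] (its per-item
#'   quantities are used).
#' @param strategy the corresponding [strategy_definition()].
#' @param config the enclosing [model_config()].
#' @param values optional named value overrides, as used for `outcome`.
#' @return an object of class `cost_breakdown` with fields `arm`, `rows`
#'   (data.frame), `by_payer`, `by_category` and `total`.
#' @export
#' @examples
#' cfg <- base_case_fixture()
#' bd <- arm_cost_breakdown(strategy = cfg$strategies[[2]], config = cfg)
#' total_cost(bd, "societal")
arm_cost_breakdown <- function(outcome = NULL, strategy, config, values = NULL) {
  if (is.null(outcome)) outcome <- evaluate_arm(strategy, config, values)
  vals <- if (is.numeric(values) && !is.null(names(values)) &&
              length(values) == length(config$parameters)) {
    values
  } else {
    resolve_values(config, values)
  }
  items <- strategy$cost_items
  n <- length(items)
  rows <- data.frame(
    item = vapply(items, function(it) it$label, character(1)),
    category = vapply(items, function(it) it$category, character(1)),
    payer = vapply(items, function(it) it$payer, character(1)),
    quantity = if (n) unname(outcome$quantities) else numeric(0),
    unit_cost = vapply(items, function(it) vals[[it$unit_cost]], numeric(1)),
    stringsAsFactors = FALSE
  )
  rows$cost <- rows$quantity * rows$unit_cost
  if (any(rows$cost < 0)) {
    stop("negative resolved cost for item '",
         rows$item[which(rows$cost < 0)[1]], "'", call. = FALSE)
  }
  by_payer <- vapply(PAYERS, function(p) sum(rows$cost[rows$payer == p]), numeric(1))
  cats <- unique(rows$category)
  by_category <- vapply(cats, function(ct) sum(rows$cost[rows$category == ct]),
                        numeric(1))
  structure(
    list(arm = strategy$name, rows = rows, by_payer = by_payer,
         by_category = by_category, total = sum(rows$cost)),
    class = "cost_breakdown"
  )
}

#' Total cost of a breakdown under a perspective
#'
#' @param breakdown a `cost_breakdown`.
#' @param perspective `"societal"` (all payers: INHS + out-of-pocket + patient
#'   and caregiver time) or `"INHS_only"` (third-party payer only).
#' @return euro amount.
#' @export
total_cost <- function(breakdown, perspective = c("societal", "INHS_only")) {
  perspective <- match.arg(perspective)
  switch(perspective,
         societal = breakdown$total,
         INHS_only = unname(breakdown$by_payer[["INHS"]]))
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> %s\n", x$arm))
  cat(sprintf("  INHS %.2f | out-of-pocket %.2f | patient time %.2f\n",
              x$by_payer[["INHS"]], x$by_payer[["out_of_pocket"]],
              x$by_payer[["patient_time"]]))
  cat(sprintf("  overall %.2f EUR\n", x$total))
  invisible(x)
}

#' @export
as.data.frame.cost_breakdown <- function(x, ...) {
  out <- x$rows
  out$arm <- x$arm
  out[, c("arm", "category", "item", "payer", "quantity", "unit_cost", "cost")]
}
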