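#' @title Model parameter and configuration types
#' @description Constructors and validation for the declarative model
#'   configuration: uncertain quantities, payer-tagged cost items, strategy
#'   definitions and the two-strategy model configuration.
#' @name parameters
NULL

SCHEMA_VERSION <- "1.0"

DIST_FAMILIES <- c("gamma", "beta", "bernoulli", "uniform", "fixed")

COST_CATEGORIES <- c(
  "mobilization_drugs", "mobilization_admin", "full_blood_count",
  "central_venous_catheter", "febrile_neutropenia", "transfusions",
  "apheresis_procedures", "missed_apheresis", "stem_cell_handling",
  "transportation", "parking", "productivity_loss", "informal_care"
)

PAYERS <- c("INHS", "out_of_pocket", "patient_time")

#' Create an uncertain model parameter
#'
#' A parameter of the cost-effectiveness model: a mean value, an optional 95%
#' confidence interval, and the distribution family used to propagate its
#' uncertainty in probabilistic sensitivity analysis.
#'
#' @param name identifier, unique within a configuration.
#' @param mean non-negative base-case value, in the declared units.
#' @param ci_low,ci_high optional 95% CI (or range) bounds; `NA` if undeclared.
#' @param dist one of `"gamma"`, `"beta"`, `"bernoulli"`, `"uniform"`, `"fixed"`.
#' @param units free-text units (e.g. `"EUR"`, `"sessions"`, `"probability"`).
#' @return an object of class `uncertain_quantity`.
#' @export
#' @examples
#' uncertain_quantity("apheresis_sessions", 2, 0.75, 3.85, "gamma", "sessions")
uncertain_quantity <- function(name, mean, ci_low = NA_real_, ci_high = NA_real_,
                               dist = "fixed", units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean)) {
    stop("mean of '", name, "' must be a single number", call. = FALSE)
  }
  if (!dist %in% DIST_FAMILIES) {
    stop("unknown distribution family '", dist, "' for parameter '", name,
         "' (expected one of ", paste(DIST_FAMILIES, collapse = ", "), ")",
         call. = FALSE)
  }
  structure(
    list(name = name, mean = as.numeric(mean),
         ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
         dist = dist, units = units),
    class = "uncertain_quantity"
  )
}

#' Create a cost item
#'
#' One row of an arm's cost table. The expected quantity is the product of the
#' referenced factor means (an empty factor list means quantity one) and the
#' expected cost is that product times the referenced unit cost.
#'
#' @param label free-text item label.
#' @param category one of the recognised cost categories (see
#'   [cost_categories()]).
#' @param payer `"INHS"`, `"out_of_pocket"` or `"patient_time"`.
#' @param quantity_factors character vector of parameter names whose product is
#'   the expected quantity.
#' @param unit_cost name of the parameter holding the unit cost in euro.
#' @return an object of class `cost_item`.
#' @export
cost_item <- function(label, category, payer, quantity_factors = character(),
                      unit_cost) {
  if (!category %in% COST_CATEGORIES) {
    stop("unknown cost category '", category, "'", call. = FALSE)
  }
  if (!payer %in% PAYERS) stop("unknown payer '", payer, "'", call. = FALSE)
  structure(
    list(label = label, category = category, payer = payer,
         quantity_factors = as.character(quantity_factors),
         unit_cost = unit_cost),
    class = "cost_item"
  )
}

#' Recognised cost categories and payers
#' @return character vector of category (or payer) codes.
#' @export
cost_categories <- function() COST_CATEGORIES

#' @rdname cost_categories
#' @export
payers <- function() PAYERS

#' Define one mobilization strategy
#'
#' An arm of the decision tree: its cost items plus the effectiveness triple
#' (probability of on-demand plerixafor, success probability with and without
#' plerixafor). The two effectiveness parameters are shared between the arms of
#' one configuration; the plerixafor probability is arm-specific.
#'
#' @param name arm label.
#' @param cost_items list of [cost_item()] objects.
#' @param p_plx name of the on-demand plerixafor probability parameter.
#' @param e_with_plx,e_without_plx names of the shared success-probability
#'   parameters (with / without plerixafor).
#' @return an object of class `strategy_definition`.
#' @export
strategy_definition <- function(name, cost_items, p_plx, e_with_plx,
                                e_without_plx) {
  stopifnot(is.list(cost_items))
  structure(
    list(name = name, cost_items = cost_items, p_plx = p_plx,
         e_with_plx = e_with_plx, e_without_plx = e_without_plx),
    class = "strategy_definition"
  )
}

#' Assemble a model configuration
#'
#' @param strategies list of exactly two [strategy_definition()] objects,
#'   comparator first, treatment second.
#' @param parameters named list of [uncertain_quantity()] objects (names must
#'   match each parameter's own name).
#' @param demographics list with `age` (parameter name), `employed_fraction`
#'   and `retirement_age`.
#' @param wages list with hourly `gross` and `net` wage rates in euro.
#' @param currency_year text tag for the price year, e.g. `"EUR2019"`.
#' @param schema_version configuration schema version string.
#' @return an object of class `model_config`.
#' @export
model_config <- function(strategies, parameters, demographics, wages,
                         currency_year = "EUR2019",
                         schema_version = SCHEMA_VERSION) {
  if (is.null(names(parameters)) || any(!nzchar(names(parameters)))) {
    names(parameters) <- vapply(parameters, function(p) p$name, character(1))
  }
  cfg <- structure(
    list(schema_version = schema_version, currency_year = currency_year,
         demographics = demographics, wages = wages,
         parameters = parameters, strategies = strategies),
    class = "model_config"
  )
  cfg
}

param_names_used <- function(strategy) {
  unique(c(
    strategy$p_plx, strategy$e_with_plx, strategy$e_without_plx,
    unlist(lapply(strategy$cost_items, function(it) {
      c(it$quantity_factors, it$unit_cost)
    }))
  ))
}

#' Validate a model configuration
#'
#' Checks every type invariant and returns the violations found (an empty
#' character vector means the configuration is valid). Violations are returned,
#' not raised, so a configuration can be inspected incrementally.
#'
#' @param config a [model_config()] object.
#' @return character vector of violation messages, each naming the offending
#'   parameter or item and the rule broken.
#' @export
#' @examples
#' length(validate_config(base_case_fixture())) == 0
validate_config <- function(config) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)

  if (!inherits(config, "model_config")) {
    return("not a model_config object")
  }
  if (length(config$strategies) != 2L) {
    add(sprintf("configuration must have exactly two strategies, found %d",
                length(config$strategies)))
  }
  ef <- config$demographics$employed_fraction
  if (is.null(ef) || !is.numeric(ef) || ef < 0 || ef > 1) {
    add("demographics.employed_fraction: must lie in [0, 1]")
  }

  for (p in config$parameters) {
    nm <- p$name
    if (!p$dist %in% DIST_FAMILIES) {
      add(sprintf("%s: unknown distribution family '%s'", nm, p$dist))
    }
    if (is.na(p$mean) || p$mean < 0) {
      add(sprintf("%s: mean must be a non-negative number", nm))
    }
    has_ci <- !is.na(p$ci_low) && !is.na(p$ci_high)
    if (has_ci && (p$ci_low > p$mean || p$mean > p$ci_high)) {
      add(sprintf("%s: CI must satisfy ci_low <= mean <= ci_high", nm))
    }
    if (has_ci && p$ci_low < 0) {
      add(sprintf("%s: ci_low must be non-negative", nm))
    }
    if (p$dist %in% c("beta", "bernoulli")) {
      if (p$mean < 0 || p$mean > 1) {
        add(sprintf("%s: %s mean must lie in [0, 1]", nm, p$dist))
      }
      if (has_ci && (p$ci_low < 0 || p$ci_high > 1)) {
        add(sprintf("%s: %s CI bounds must lie in [0, 1]", nm, p$dist))
      }
    }
  }

  pnames <- names(config$parameters)
  for (s in config$strategies) {
    for (ref in c(p_plx = s$p_plx, e_with_plx = s$e_with_plx,
                  e_without_plx = s$e_without_plx)) {
      if (!ref %in% pnames) {
        add(sprintf("strategy '%s': unresolved parameter reference '%s'",
                    s$name, ref))
      }
    }
    for (it in s$cost_items) {
      for (ref in c(it$quantity_factors, it$unit_cost)) {
        if (!ref %in% pnames) {
          add(sprintf("strategy '%s', item '%s': unresolved parameter reference '%s'",
                      s$name, it$label, ref))
        }
      }
    }
  }

  if (length(config$strategies) == 2L) {
    s1 <- config$strategies[[1]]; s2 <- config$strategies[[2]]
    if (!identical(s1$e_with_plx, s2$e_with_plx) ||
        !identical(s1$e_without_plx, s2$e_without_plx)) {
      add("effectiveness parameters e_with_plx/e_without_plx must be shared between the two strategies")
    }
  }
  v
}

#' @export
print.uncertain_quantity <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (%.4g, %.4g)", x$ci_low, x$ci_high)
  cat(sprintf("<uncertain_quantity> %s = %.6g%s [%s] %s\n",
              x$name, x$mean, ci, x$dist, x$units))
  invisible(x)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> schema %s, %s\n", x$schema_version, x$currency_year))
  cat(sprintf("  strategies : %s (comparator) vs %s (treatment)\n",
              x$strategies[[1]]$name, x$strategies[[2]]$name))
  cat(sprintf("  parameters : %d\n", length(x$parameters)))
  n_items <- vapply(x$strategies, function(s) length(s$cost_items), integer(1))
  cat(sprintf("  cost items : %d / %d\n", n_items[1], n_items[2]))
  invisible(x)
}
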