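#' @title Decision-tree arm evaluation
#' @description Expected resource quantities and the plerixafor-weighted
#'   probability of a successful 4e6 CD34+/kg apheresis for one mobilization
#'   strategy. The tree's chance nodes (on-demand plerixafor, febrile
#'   neutropenia, transfusions) enter costs through their expectations, which
#'   is exact because all downstream costs are linear in the event quantities.
#' @name decision_model
NULL

check_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  }
}

#' Plerixafor-weighted probability of successful apheresis
#'
#' Mixture of the success probabilities with and without on-demand plerixafor,
#' weighted by the probability that plerixafor is administered:
#' `p_plx * e_with + (1 - p_plx) * e_without`, returned unrounded.
#'
#' @param p_plx probability of administering on-demand plerixafor.
#' @param e_with,e_without probability of a successful 4e6 CD34+ apheresis
#'   with / without plerixafor.
#' @return the mixture probability (vectorized over its arguments).
#' @export
#' @examples
#' mixture_effectiveness(0.47, 0.838, 0.702)  # 0.76592
#' mixture_effectiveness(0.09, 0.838, 0.702)  # 0.71424
mixture_effectiveness <- function(p_plx, e_with, e_without) {
  check_prob(p_plx, "p_plx")
  check_prob(e_with, "e_with")
  check_prob(e_without, "e_without")
  p_plx * e_with + (1 - p_plx) * e_without
}

#' Expectation of a Bernoulli-gated amount
#'
#' Expected value of a resource consumed only when an event occurs: the event
#' probability times the amount used given the event (e.g. on-demand
#' plerixafor vials).
#'
#' @param p_event event probability.
#' @param amount_if_event non-negative amount conditional on the event.
#' @return `p_event * amount_if_event`.
#' @export
#' @examples
#' expected_quantity(0.47, 1.51)  # 0.7097 vials per patient
expected_quantity <- function(p_event, amount_if_event) {
  check_prob(p_event, "p_event")
  if (any(!is.finite(amount_if_event)) || any(amount_if_event < 0)) {
    stop("amount_if_event must be non-negative", call. = FALSE)
  }
  p_event * amount_if_event
}

#' Resolve parameter values for evaluation
#'
#' Base-case parameter means, optionally overridden (used by one-way and
#' scenario analyses and by per-iteration Monte Carlo draws).
#'
#' @param config a [model_config()] object.
#' @param overrides named numeric vector of replacement values.
#' @return named numeric vector of parameter values.
#' @export
resolve_values <- function(config, overrides = NULL) {
  vals <- vapply(config$parameters, function(p) p$mean, numeric(1))
  if (!is.null(overrides) && length(overrides)) {
    unknown <- setdiff(names(overrides), names(vals))
    if (length(unknown)) {
      stop("unresolved parameter reference: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    vals[names(overrides)] <- overrides
  }
  vals
}

#' Evaluate one arm of the decision tree
#'
#' Computes the arm's effectiveness via [mixture_effectiveness()] and the
#' expected quantity of every cost item (the product of its resolved quantity
#' factors; one for items without factors). Deterministic for fixed inputs and
#' linear in each quantity factor.
#'
#' @param strategy a [strategy_definition()].
#' @param config the enclosing [model_config()].
#' @param values optional named value overrides (see [resolve_values()]).
#' @return an object of class `arm_outcome` with fields `strategy`,
#'   `effectiveness` and `quantities` (named by item label).
#' @export
#' @examples
#' cfg <- base_case_fixture()
#' evaluate_arm(cfg$strategies[[2]], cfg)$effectiveness  # 0.76592
evaluate_arm <- function(strategy, config, values = NULL) {
  vals <- if (is.numeric(values) && !is.null(names(values)) &&
              length(values) == length(config$parameters)) {
    values
  } else {
    resolve_values(config, values)
  }
  refs <- param_names_used(strategy)
  missing <- setdiff(refs, names(vals))
  if (length(missing)) {
    stop("unresolved parameter reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eff <- mixture_effectiveness(vals[[strategy$p_plx]],
                               vals[[strategy$e_with_plx]],
                               vals[[strategy$e_without_plx]])
  q <- vapply(strategy$cost_items, function(it) {
    if (length(it$quantity_factors) == 0L) 1 else prod(vals[it$quantity_factors])
  }, numeric(1))
  names(q) <- vapply(strategy$cost_items, function(it) it$label, character(1))
  if (any(q < 0)) stop("negative expected quantity", call. = FALSE)
  structure(
    list(strategy = strategy$name, effectiveness = eff, quantities = q),
    class = "arm_outcome"
  )
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome> %s\n  effectiveness %.5f, %d cost items\n",
              x$strategy, x$effectiveness, length(x$quantities)))
  invisible(x)
}
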