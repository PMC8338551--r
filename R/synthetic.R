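#' @title Synthetic configuration generator
#' @description Random, valid model configurations with the statistical
#'   structure the analysis assumes — gamma resource quantities with CIs
#'   derived from their own fitted distribution, beta probabilities, optional
#'   Bernoulli-gated (composite) items, payer-partitioned cost items and a
#'   shared effectiveness pair — so every stage of the pipeline is testable on
#'   data with a known ground truth.
#' @name synthetic
NULL

#' Generator settings
#'
#' @param seed integer seed; the same spec always yields the same
#'   configuration.
#' @param n_items integer range (min, max) of cost items per arm, min `>= 3`
#'   so every payer is represented.
#' @param cv coefficient of variation for generated gamma quantities.
#' @param p_plx_range range for the arm-specific plerixafor probabilities.
#' @param eff_without_range range for the shared baseline success probability.
#' @param eff_gap_range range for the effectiveness gap `e_with - e_without`.
#' @param p_zero_gap probability of generating an exactly zero effectiveness
#'   gap (exercises the weak-dominance labels).
#' @param p_mirror probability of generating two identical arms (exercises the
#'   indeterminate label).
#' @param quantity_range range of expected resource quantities.
#' @param unit_cost_range range of unit costs in euro.
#' @param wage_range range for the gross hourly wage.
#' @param composite_items include Bernoulli-gated (event x amount) items?
#' @return a `generator_spec` object.
#' @export
generator_spec <- function(seed = 1, n_items = c(3L, 8L), cv = 0.4,
                           p_plx_range = c(0.05, 0.80),
                           eff_without_range = c(0.30, 0.90),
                           eff_gap_range = c(-0.15, 0.15),
                           p_zero_gap = 0.20, p_mirror = 0.12,
                           quantity_range = c(0.1, 10),
                           unit_cost_range = c(10, 3000),
                           wage_range = c(10, 40),
                           composite_items = TRUE) {
  ranges <- list(n_items = n_items, p_plx_range = p_plx_range,
                 eff_without_range = eff_without_range,
                 eff_gap_range = eff_gap_range,
                 quantity_range = quantity_range,
                 unit_cost_range = unit_cost_range, wage_range = wage_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop("range '", nm, "' must be well-ordered", call. = FALSE)
    }
  }
  if (cv <= 0) stop("cv must be > 0", call. = FALSE)
  if (n_items[1] < 3L) stop("n_items minimum must be >= 3", call. = FALSE)
  for (p in c(p_plx_range, eff_without_range)) {
    if (p < 0 || p > 1) stop("probability range outside [0, 1]", call. = FALSE)
  }
  if (p_zero_gap < 0 || p_zero_gap > 1 || p_mirror < 0 || p_mirror > 1) {
    stop("p_zero_gap and p_mirror must lie in [0, 1]", call. = FALSE)
  }
  structure(c(list(seed = as.integer(seed), cv = cv, p_zero_gap = p_zero_gap,
                   p_mirror = p_mirror, composite_items = composite_items),
              ranges),
            class = "generator_spec")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

synth_gamma_param <- function(name, mean, cv, units = "") {
  shape <- 1 / cv^2
  ci <- stats::qgamma(c(0.025, 0.975), shape, scale = mean / shape)
  uncertain_quantity(name, mean, ci[1], ci[2], "gamma", units)
}

synth_beta_param <- function(name, mean) {
  d <- beta_from_mean_sd(mean, beta_sd_convention(mean))
  uncertain_quantity(name, mean, d$source_ci[1], d$source_ci[2], "beta",
                     "probability")
}

#' Generate a random, valid model configuration
#'
#' The generated configuration always passes [validate_config()]: two
#' strategies sharing the effectiveness pair, at least one cost item per payer
#' in each arm, gamma quantity CIs computed from the generating distribution
#' at full precision (so [fit_shape_to_quantiles()] inverts them), beta
#' probabilities at the dispersion convention. With the configured
#' probabilities the generator emits an exactly-zero effectiveness gap or two
#' mirrored arms, so that all five dominance labels occur across many seeds.
#'
#' @param spec a [generator_spec()].
#' @return a [model_config()] object.
#' @export
#' @examples
#' cfg <- random_model_config(generator_spec(seed = 42))
#' validate_config(cfg)
random_model_config <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_local_seed(spec$seed, {
    params <- list()
    add_param <- function(p) params[[p$name]] <<- p

    e_wo <- round(stats::runif(1, spec$eff_without_range[1],
                               spec$eff_without_range[2]), 4)
    gap <- if (stats::runif(1) < spec$p_zero_gap) 0 else {
      round(stats::runif(1, spec$eff_gap_range[1], spec$eff_gap_range[2]), 4)
    }
    e_w <- min(max(e_wo + gap, 0.02), 0.98)
    add_param(synth_beta_param("e_without_plx", e_wo))
    add_param(synth_beta_param("e_with_plx", e_w))

    mirror <- stats::runif(1) < spec$p_mirror

    make_arm <- function(arm) {
      p_plx_name <- paste0("p_plx_", arm)
      add_param(synth_beta_param(
        p_plx_name,
        round(stats::runif(1, spec$p_plx_range[1], spec$p_plx_range[2]), 4)
      ))
      k <- sample(seq(spec$n_items[1], spec$n_items[2]), 1L)
      payer_seq <- c(PAYERS, sample(PAYERS, max(0L, k - 3L), replace = TRUE))
      items <- vector("list", k)
      for (i in seq_len(k)) {
        qname <- sprintf("%s_qty_%d", arm, i)
        uname <- sprintf("%s_cost_%d", arm, i)
        add_param(synth_gamma_param(
          qname, round(stats::runif(1, spec$quantity_range[1],
                                    spec$quantity_range[2]), 3),
          spec$cv, units = "units"))
        add_param(synth_gamma_param(
          uname, round(stats::runif(1, spec$unit_cost_range[1],
                                    spec$unit_cost_range[2]), 2),
          spec$cv, units = "EUR"))
        factors <- qname
        if (spec$composite_items && stats::runif(1) < 0.3) {
          bname <- sprintf("%s_event_%d", arm, i)
          add_param(uncertain_quantity(bname,
                                       round(stats::runif(1, 0.1, 0.9), 3),
                                       0, 1, "bernoulli", "probability"))
          factors <- c(bname, qname)
        }
        items[[i]] <- cost_item(sprintf("%s item %d", arm, i),
                                category = sample(COST_CATEGORIES, 1L),
                                payer = payer_seq[i],
                                quantity_factors = factors,
                                unit_cost = uname)
      }
      strategy_definition(paste("strategy", arm), items, p_plx_name,
                          "e_with_plx", "e_without_plx")
    }

    comparator <- make_arm("cmp")
    treatment <- if (mirror) {
      strategy_definition("strategy trt (mirrored)", comparator$cost_items,
                          comparator$p_plx, "e_with_plx", "e_without_plx")
    } else {
      make_arm("trt")
    }

    add_param(uncertain_quantity("age", round(stats::runif(1, 40, 75), 2),
                                 dist = "fixed", units = "years"))
    gross <- round(stats::runif(1, spec$wage_range[1], spec$wage_range[2]), 2)
    model_config(
      strategies = list(comparator, treatment),
      parameters = params,
      demographics = list(age = "age", employed_fraction = 0.5,
                          retirement_age = 70),
      wages = list(gross = gross, net = round(0.55 * gross, 2)),
      currency_year = "EURsynthetic"
    )
  })
}

unit_cost_names <- function(config) {
  unique(unlist(lapply(config$strategies, function(s) {
    vapply(s$cost_items, function(it) it$unit_cost, character(1))
  })))
}

#' Metamorphic perturbations of a configuration
#'
#' Returns a modified copy used to assert metamorphic properties of the
#' pipeline:
#' \describe{
#'   \item{scale_costs}{multiplies every unit-cost parameter (mean and CI) by
#'     `k > 0`; incremental cost and raw ICER scale by `k`, incremental
#'     effectiveness is unchanged.}
#'   \item{add_common_item}{appends a fixed-cost item of `c >= 0` euro to both
#'     arms; incremental cost is unchanged.}
#'   \item{widen_cis}{scales every declared CI about its mean by `f >= 1`
#'     (clamped to the distribution's support); `f = 1` is the identity.}
#' }
#'
#' @param config a [model_config()] object.
#' @param rule one of `"scale_costs"`, `"add_common_item"`, `"widen_cis"`.
#' @param k,c,f rule parameters (see above).
#' @return a modified [model_config()].
#' @export
perturb <- function(config, rule = c("scale_costs", "add_common_item", "widen_cis"),
                    k = 1, c = 0, f = 1) {
  rule <- match.arg(rule)
  switch(rule,
    scale_costs = {
      if (!is.numeric(k) || k <= 0) stop("k must be > 0", call. = FALSE)
      for (nm in unit_cost_names(config)) {
        p <- config$parameters[[nm]]
        p$mean <- p$mean * k
        p$ci_low <- p$ci_low * k
        p$ci_high <- p$ci_high * k
        config$parameters[[nm]] <- p
      }
      config
    },
    add_common_item = {
      if (!is.numeric(c) || c < 0) stop("c must be >= 0", call. = FALSE)
      nm <- "common_item_cost"
      config$parameters[[nm]] <- uncertain_quantity(nm, c, dist = "fixed",
                                                    units = "EUR")
      item <- cost_item("common fixed item", "transportation", "INHS",
                        character(), nm)
      config$strategies <- lapply(config$strategies, function(s) {
        s$cost_items <- c(s$cost_items, list(item))
        s
      })
      config
    },
    widen_cis = {
      if (!is.numeric(f) || f < 1) stop("f must be >= 1", call. = FALSE)
      if (f == 1) return(config)
      config$parameters <- lapply(config$parameters, function(p) {
        if (!is.na(p$ci_low) && !is.na(p$ci_high)) {
          lo <- max(0, p$mean + f * (p$ci_low - p$mean))
          hi <- p$mean + f * (p$ci_high - p$mean)
          if (p$dist %in% c("beta", "bernoulli")) hi <- min(1, hi)
          p$ci_low <- lo
          p$ci_high <- hi
        }
        p
      })
      config
    }
  )
}
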