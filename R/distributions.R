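#' @title Parameter distributions
#' @description Parameterize gamma, beta, Bernoulli, uniform and degenerate
#'   distributions from reported means and 95% confidence intervals, and sample
#'   them reproducibly for probabilistic sensitivity analysis.
#' @name distributions
NULL

new_fitted_dist <- function(family, par, source_mean, source_ci = c(NA_real_, NA_real_),
                            residual = NA_real_) {
  structure(
    list(family = family, par = par, source_mean = source_mean,
         source_ci = source_ci, residual = residual),
    class = "fitted_dist"
  )
}

#' Gamma distribution from mean and coefficient of variation
#'
#' Moment parameterization: `shape = 1/cv^2`, `scale = mean * cv^2`, so the
#' distribution mean equals the input mean exactly. A constant CV of 0.4
#' (shape 6.25) reproduces the model's printed 95% CIs for resource-quantity
#' parameters with strictly positive lower bounds.
#'
#' @param mean positive distribution mean.
#' @param cv positive coefficient of variation (sd/mean).
#' @return a `fitted_dist` object of family `"gamma"`.
#' @export
#' @examples
#' d <- gamma_from_mean_cv(2, 0.4)   # shape 6.25, scale 0.32
#' dist_quantile(d, c(0.025, 0.975)) # about (0.75, 3.85)
gamma_from_mean_cv <- function(mean, cv) {
  if (!is.numeric(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.numeric(cv) || cv <= 0) stop("cv must be > 0", call. = FALSE)
  shape <- 1 / cv^2
  scale <- mean * cv^2
  new_fitted_dist("gamma", c(shape = shape, scale = scale), mean,
                  c(stats::qgamma(0.025, shape, scale = scale),
                    stats::qgamma(0.975, shape, scale = scale)))
}

#' Fit a gamma shape to reported 95% CI bounds
#'
#' Holds the mean fixed and finds the shape minimizing the sum of squared
#' relative errors of the 2.5% and 97.5% quantiles against the reported bounds
#' (relative to the bound itself, or to the mean where the bound is zero).
#' The fitted scale is `mean / shape`, so the mean is preserved exactly.
#'
#' @param mean positive distribution mean, inside `(ci_low, ci_high)`.
#' @param ci_low,ci_high reported 95% CI bounds, `0 <= ci_low < ci_high`.
#' @return a `fitted_dist` with the converged fit residual in `$residual`.
#' @export
#' @examples
#' fit_shape_to_quantiles(2.00, 0.75, 3.85)$par[["shape"]] # about 6.25
fit_shape_to_quantiles <- function(mean, ci_low, ci_high) {
  if (!is.numeric(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (is.na(ci_low) || is.na(ci_high) || ci_low < 0 || ci_high <= ci_low) {
    stop("require 0 <= ci_low < ci_high", call. = FALSE)
  }
  if (mean <= ci_low || mean >= ci_high) {
    stop("mean must lie strictly inside (ci_low, ci_high)", call. = FALSE)
  }
  obj <- function(log_shape) {
    shape <- exp(log_shape)
    scale <- mean / shape
    q <- stats::qgamma(c(0.025, 0.975), shape, scale = scale)
    d_lo <- if (ci_low > 0) ci_low else mean
    ((q[1] - ci_low) / d_lo)^2 + ((q[2] - ci_high) / ci_high)^2
  }
  opt <- stats::optimize(obj, interval = c(log(1e-4), log(1e6)), tol = 1e-12)
  shape <- exp(opt$minimum)
  if (shape <= 0 || !is.finite(opt$objective)) {
    stop("no positive-shape gamma fit bracketed for mean ", mean, call. = FALSE)
  }
  scale <- mean / shape
  new_fitted_dist("gamma", c(shape = shape, scale = scale), mean,
                  c(ci_low, ci_high), residual = opt$objective)
}

#' Beta distribution from mean and standard deviation
#'
#' Moment parameterization: with `nu = mean*(1-mean)/sd^2 - 1`,
#' `alpha = mean*nu` and `beta = (1-mean)*nu`; the mean is preserved exactly.
#'
#' @param mean probability in (0, 1).
#' @param sd positive standard deviation; must satisfy
#'   `sd^2 < mean * (1 - mean)`.
#' @return a `fitted_dist` object of family `"beta"`.
#' @export
beta_from_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("mean must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  bound <- mean * (1 - mean)
  if (sd^2 >= bound) {
    stop(sprintf("infeasible sd: need sd^2 < mean*(1-mean) = %.6g (sd < %.6g)",
                 bound, sqrt(bound)), call. = FALSE)
  }
  nu <- bound / sd^2 - 1
  a <- mean * nu
  b <- (1 - mean) * nu
  new_fitted_dist("beta", c(alpha = a, beta = b), mean,
                  c(stats::qbeta(0.025, a, b), stats::qbeta(0.975, a, b)))
}

#' Degenerate, Bernoulli and uniform distributions
#'
#' @param mean the constant value (degenerate) returned by every draw.
#' @return a `fitted_dist` object.
#' @export
fixed_dist <- function(mean) {
  new_fitted_dist("fixed", c(value = mean), mean, c(mean, mean))
}

#' @rdname fixed_dist
#' @param p Bernoulli success probability.
#' @export
bernoulli_dist <- function(p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  new_fitted_dist("bernoulli", c(p = p), p, c(0, 1))
}

#' @rdname fixed_dist
#' @param lo,hi uniform bounds, `lo <= hi`.
#' @export
uniform_dist <- function(lo, hi) {
  if (lo > hi) stop("require lo <= hi", call. = FALSE)
  new_fitted_dist("uniform", c(lo = lo, hi = hi), (lo + hi) / 2, c(lo, hi))
}

#' Quantiles and CDF of a fitted distribution
#'
#' @param dist a `fitted_dist` object.
#' @param p probabilities (for quantiles) .
#' @return numeric vector of quantiles or CDF values.
#' @export
dist_quantile <- function(dist, p) {
  switch(dist$family,
    gamma = stats::qgamma(p, dist$par[["shape"]], scale = dist$par[["scale"]]),
    beta = stats::qbeta(p, dist$par[["alpha"]], dist$par[["beta"]]),
    bernoulli = stats::qbinom(p, 1L, dist$par[["p"]]),
    uniform = stats::qunif(p, dist$par[["lo"]], dist$par[["hi"]]),
    fixed = rep(dist$par[["value"]], length(p))
  )
}

#' @rdname dist_quantile
#' @param q quantile values (for the CDF).
#' @export
dist_cdf <- function(dist, q) {
  switch(dist$family,
    gamma = stats::pgamma(q, dist$par[["shape"]], scale = dist$par[["scale"]]),
    beta = stats::pbeta(q, dist$par[["alpha"]], dist$par[["beta"]]),
    bernoulli = stats::pbinom(q, 1L, dist$par[["p"]]),
    uniform = stats::punif(q, dist$par[["lo"]], dist$par[["hi"]]),
    fixed = as.numeric(q >= dist$par[["value"]])
  )
}

#' Draw i.i.d. samples from a fitted distribution
#'
#' Draws are taken from the current RNG stream; use [param_subseed()] /
#' `set.seed()` for reproducible per-parameter substreams.
#'
#' @param dist a `fitted_dist` object.
#' @param n number of draws, `n >= 1`.
#' @return numeric vector of length `n`.
#' @export
sample_dist <- function(dist, n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  switch(dist$family,
    gamma = stats::rgamma(n, dist$par[["shape"]], scale = dist$par[["scale"]]),
    beta = stats::rbeta(n, dist$par[["alpha"]], dist$par[["beta"]]),
    bernoulli = stats::rbinom(n, 1L, dist$par[["p"]]),
    uniform = stats::runif(n, dist$par[["lo"]], dist$par[["hi"]]),
    fixed = rep(dist$par[["value"]], n)
  )
}

#' Dispersion convention for probability parameters
#'
#' Standard deviation assigned to a beta-distributed probability when only its
#' mean is reported: `0.4 * min(mean, 1 - mean)`, capped at 95% of the
#' feasibility bound `sqrt(mean * (1 - mean))`. Mirrors the constant CV 0.4
#' used for resource quantities while keeping the beta unimodal near either
#' boundary.
#'
#' @param mean probability in (0, 1).
#' @return a standard deviation.
#' @export
beta_sd_convention <- function(mean) {
  min(0.4 * min(mean, 1 - mean), 0.95 * sqrt(mean * (1 - mean)))
}

#' Distribution assigned to an uncertain quantity
#'
#' Maps a model parameter to its sampling distribution: `fixed` parameters are
#' degenerate at the mean; `gamma` parameters are fitted to their declared CI
#' (or use CV 0.4 when no CI is declared); `beta` probabilities use the
#' [beta_sd_convention()]; `bernoulli` and `uniform` map directly. Parameters
#' with mean 0 or probabilities at 0/1 degenerate to their mean.
#'
#' @param param an [uncertain_quantity()] object.
#' @return a `fitted_dist` object.
#' @export
param_dist <- function(param) {
  m <- param$mean
  has_ci <- !is.na(param$ci_low) && !is.na(param$ci_high) &&
    param$ci_high > param$ci_low
  switch(param$dist,
    fixed = fixed_dist(m),
    bernoulli = bernoulli_dist(m),
    uniform = if (has_ci) uniform_dist(param$ci_low, param$ci_high) else fixed_dist(m),
    gamma = {
      if (m <= 0) {
        fixed_dist(m)
      } else if (has_ci && m > param$ci_low && m < param$ci_high) {
        fit_shape_to_quantiles(m, param$ci_low, param$ci_high)
      } else {
        gamma_from_mean_cv(m, 0.4)
      }
    },
    beta = {
      if (m <= 0 || m >= 1) fixed_dist(m) else beta_from_mean_sd(m, beta_sd_convention(m))
    }
  )
}

#' Deterministic per-parameter random substream seed
#'
#' Derives a sub-seed from a master seed and a parameter name, so that adding
#' or removing a parameter does not perturb the draws of any other parameter.
#'
#' @param seed master integer seed.
#' @param name parameter name.
#' @return an integer seed below 2^31 - 1.
#' @export
param_subseed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
  as.integer((h + as.numeric(seed) %% 2147483629) %% 2147483629)
}

#' Sample every uncertain parameter of a configuration
#'
#' Draws `n` values for each parameter from its assigned distribution using a
#' deterministic per-parameter substream derived from the master seed. The
#' caller's RNG state is left untouched.
#'
#' @param config a [model_config()] object.
#' @param n number of draws per parameter.
#' @param seed master integer seed.
#' @return numeric matrix, `n` rows, one named column per parameter.
#' @export
sample_params <- function(config, n, seed) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  pnames <- names(config$parameters)
  out <- matrix(NA_real_, nrow = n, ncol = length(pnames),
                dimnames = list(NULL, pnames))
  for (nm in pnames) {
    d <- param_dist(config$parameters[[nm]])
    set.seed(param_subseed(seed, nm))
    out[, nm] <- sample_dist(d, n)
  }
  out
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat(sprintf("<fitted_dist> %s(%s), mean %.6g, 95%% CI (%.6g, %.6g)\n",
              x$family,
              paste(sprintf("%s=%.6g", names(x$par), x$par), collapse = ", "),
              x$source_mean, x$source_ci[1], x$source_ci[2]))
  invisible(x)
}

#' Fitted-distribution diagnostics for a configuration
#'
#' @param config a [model_config()] object.
#' @return data.frame with one row per parameter: family, fitted parameters
#'   and the fit residual (NA where no fit was needed).
#' @export
dist_diagnostics <- function(config) {
  rows <- lapply(config$parameters, function(p) {
    d <- param_dist(p)
    data.frame(parameter = p$name, family = d$family,
               par1 = unname(d$par[1]),
               par2 = if (length(d$par) > 1) unname(d$par[2]) else NA_real_,
               fit_residual = d$residual,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
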