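#' Method-of-moments fit of a Beta distribution
#'
#' Solves for the shape parameters of a Beta distribution with the given mean
#' and standard deviation. Feasibility requires `sd^2 < mean * (1 - mean)`;
#' several published MS inputs sit close to this boundary (standard deviations
#' equal to their means), which is why quantile-based rather than
#' normal-approximation intervals are the package default for sensitivity
#' analysis.
#'
#' @param mean Mean of the distribution, strictly inside (0, 1).
#' @param sd Standard deviation, with `0 < sd^2 < mean * (1 - mean)`.
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @examples
#' beta_moments(0.5, sqrt(1 / 12)) # uniform: alpha = beta = 1
#' beta_moments(0.0755, 0.0755)
#' @export
beta_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (mean <= 0 || mean >= 1)
    stop("beta_moments: mean must lie strictly in (0, 1), got ", mean)
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean))
    stop("beta_moments: infeasible sd for mean ", mean,
         " (need 0 < sd^2 < mean*(1-mean) = ", signif(mean * (1 - mean), 6), ")")
  k <- mean * (1 - mean) / v - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Method-of-moments fit of a Gamma distribution
#'
#' Returns shape and scale such that `shape * scale = mean` and
#' `shape * scale^2 = sd^2`.
#'
#' @param mean Positive mean (THB for cost parameters).
#' @param sd Positive standard deviation.
#' @return Named numeric vector with elements `shape` and `scale`.
#' @examples
#' gamma_moments(1, 1) # exponential
#' gamma_moments(8236, 1647)
#' @export
gamma_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (mean <= 0 || sd <= 0)
    stop("gamma_moments: mean and sd must be positive")
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' 95% interval of a fitted parameter distribution
#'
#' Quantile interval (2.5th/97.5th percentile by default) of the Beta or Gamma
#' distribution fitted to a parameter's mean and SD by the method of moments.
#' Fixed parameters return a degenerate interval at the mean. The
#' normal-approximation alternative (`method = "normal"`) truncates to the
#' distribution's support, which matters for the inputs whose SD equals the
#' mean.
#'
#' @param spec A parameter specification as stored in [rrms_parameters()]
#'   (list with `family`, `mean`, `sd`), or the name of one together with
#'   `params`.
#' @param level Interval coverage, default 0.95.
#' @param method `"quantile"` (fitted-distribution percentiles, default) or
#'   `"normal"` (mean +/- z*sd truncated to support).
#' @return Named numeric vector `c(low, high)`.
#' @export
param_ci <- function(spec, level = 0.95, method = c("quantile", "normal")) {
  method <- match.arg(method)
  stopifnot(is.list(spec), level > 0, level < 1)
  a <- (1 - level) / 2
  if (spec$family == "fixed" || spec$sd == 0)
    return(c(low = spec$mean, high = spec$mean))
  if (method == "normal") {
    z <- stats::qnorm(1 - a)
    lo <- spec$mean - z * spec$sd
    hi <- spec$mean + z * spec$sd
    if (spec$family == "beta") {
      lo <- max(lo, 0); hi <- min(hi, 1)
    } else {
      lo <- max(lo, 0)
    }
    return(c(low = lo, high = hi))
  }
  if (spec$family == "beta") {
    sh <- beta_moments(spec$mean, spec$sd)
    c(low = stats::qbeta(a, sh["alpha"], sh["beta"]),
      high = stats::qbeta(1 - a, sh["alpha"], sh["beta"]))
  } else {
    sh <- gamma_moments(spec$mean, spec$sd)
    c(low = stats::qgamma(a, shape = sh["shape"], scale = sh["scale"]),
      high = stats::qgamma(1 - a, shape = sh["shape"], scale = sh["scale"]))
  }
}

## Draw n values from the fitted distribution of one spec.
draw_spec <- function(spec, n) {
  if (spec$family == "fixed" || spec$sd == 0) return(rep(spec$mean, n))
  if (spec$family == "beta") {
    sh <- beta_moments(spec$mean, spec$sd)
    stats::rbeta(n, sh["alpha"], sh["beta"])
  } else {
    sh <- gamma_moments(spec$mean, spec$sd)
    stats::rgamma(n, shape = sh["shape"], scale = sh["scale"])
  }
}
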