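#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full model twice per parameter -- once at each bound of its
#' 95% interval, all other inputs at base case -- and records the change in
#' the chosen outcome for a strategy pair. Probability and utility intervals
#' come from the fitted Beta/Gamma quantiles ([param_ci()]); the monthly drug
#' costs use +/- 20% of the base case, the range conventionally examined for
#' drug acquisition prices.
#'
#' Because the incremental cost of a dominant comparison is negative, the
#' ICER is sign-unstable there; the default outcome is therefore the
#' incremental net monetary benefit at the configured willingness-to-pay
#' threshold, with `outcome = "icer"` available when the ratio is
#' well-defined.
#'
#' @param params An [rrms_parameters()] object.
#' @param target_params Character vector of parameter names to vary; default
#'   all parameters.
#' @param outcome `"nmb"` (incremental net monetary benefit, default) or
#'   `"icer"`.
#' @param strategy,reference The compared pair, default biosimilar vs best
#'   supportive care.
#' @param wtp Willingness-to-pay threshold for the NMB outcome; defaults to
#'   the settings value.
#' @return A data.frame of class `rrms_owsa`, one row per parameter
#'   (`parameter`, `low_input`, `high_input`, `outcome_low`, `outcome_high`,
#'   `spread`), sorted by decreasing spread. The base-case outcome is stored
#'   as attribute `base_outcome`.
#' @export
owsa <- function(params, target_params = NULL,
                 outcome = c("nmb", "icer"),
                 strategy = "biosimilar", reference = "bsc",
                 wtp = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(params, "rrms_parameters"))
  target_params <- target_params %||% names(params$specs)
  unknown <- setdiff(target_params, names(params$specs))
  if (length(unknown))
    stop("owsa: unknown parameter(s): ", paste(unknown, collapse = ", "))
  wtp <- wtp %||% params$settings$wtp
  pct20 <- c("c_rituximab_month", "c_biosimilar_month")

  eval_outcome <- function(values) {
    m <- rrms_cua(params, strategies_run = c(reference, strategy),
                  reference = reference, values = values)
    r <- m$results[[strategy]]; ref <- m$results[[reference]]
    if (outcome == "nmb")
      nmb(r$total_cost - ref$total_cost, r$total_qaly - ref$total_qaly, wtp)
    else
      (r$total_cost - ref$total_cost) / (r$total_qaly - ref$total_qaly)
  }
  base_outcome <- eval_outcome(NULL)

  rows <- lapply(target_params, function(nm) {
    spec <- params$specs[[nm]]
    bounds <- if (nm %in% pct20) {
      c(low = 0.8 * spec$mean, high = 1.2 * spec$mean)
    } else {
      param_ci(spec, method = params$settings$ci_method)
    }
    out_lo <- eval_outcome(stats::setNames(bounds[["low"]], nm))
    out_hi <- eval_outcome(stats::setNames(bounds[["high"]], nm))
    data.frame(parameter = nm,
               low_input = bounds[["low"]], high_input = bounds[["high"]],
               outcome_low = out_lo, outcome_high = out_hi,
               spread = abs(out_hi - out_lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rrms_owsa", "data.frame")
  attr(out, "base_outcome") <- base_outcome
  attr(out, "outcome") <- outcome
  out
}

#' @export
plot.rrms_owsa <- function(x, n_top = 10, ...) {
  d <- utils::head(x[x$spread > 0, ], n_top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_outcome")
  lo <- pmin(d$outcome_low, d$outcome_high) - base
  hi <- pmax(d$outcome_low, d$outcome_high) - base
  graphics::par(mar = c(5, 12, 2, 2))
  graphics::plot(NULL, xlim = range(c(lo, hi)), ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = paste("Change in", toupper(attr(x, "outcome"))),
                 ylab = "", main = "One-way sensitivity analysis", ...)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1, cex.axis = 0.7)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue")
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' Draws every non-fixed parameter independently from its method-of-moments
#' Beta or Gamma fit. Identical seeds give identical draws.
#'
#' @param params An [rrms_parameters()] object.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param as `"matrix"` (default; an `n_draws` x parameters data.frame of
#'   sampled values) or `"parameters"` (list of `rrms_parameters` objects
#'   with means replaced by the draws).
#' @return See `as`.
#' @export
sample_psa <- function(params, n_draws, seed = 1L, as = c("matrix", "parameters")) {
  as <- match.arg(as)
  stopifnot(inherits(params, "rrms_parameters"), n_draws >= 1)
  set.seed(as.integer(seed))
  draws <- as.data.frame(lapply(params$specs, draw_spec, n = n_draws))
  if (as == "matrix") return(draws)
  lapply(seq_len(n_draws), function(i) {
    p <- params
    for (nm in names(p$specs)) p$specs[[nm]]$mean <- draws[i, nm]
    p
  })
}

#' Probabilistic sensitivity analysis
#'
#' Runs the full model once per Monte-Carlo parameter draw and per strategy,
#' recording total discounted cost and QALYs. The transition-matrix
#' conventions (including the calibrated EDSS 6.0-7.5 death probability,
#' which is a fixed input) are held at their configured values.
#'
#' @param params An [rrms_parameters()] object.
#' @param n_draws Number of draws; defaults to `settings$psa_draws` (1,000).
#' @param seed Integer seed.
#' @param strategies_run Strategies to evaluate per draw.
#' @return A data.frame of class `rrms_psa` in long format: `draw`,
#'   `strategy`, `cost`, `qaly`. The draw matrix is stored as attribute
#'   `draws`.
#' @export
run_psa <- function(params, n_draws = NULL, seed = 1L,
                    strategies_run = strategies()) {
  stopifnot(inherits(params, "rrms_parameters"))
  n_draws <- as.integer(n_draws %||% params$settings$psa_draws)
  draws <- sample_psa(params, n_draws, seed)
  res <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    vals <- unlist(draws[i, ])
    m <- rrms_cua(params, strategies_run = strategies_run,
                  reference = strategies_run[1], values = vals)
    res[[i]] <- data.frame(draw = i,
                           strategy = strategies_run,
                           cost = vapply(m$results, `[[`, numeric(1), "total_cost"),
                           qaly = vapply(m$results, `[[`, numeric(1), "total_qaly"),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("rrms_psa", "data.frame")
  attr(out, "draws") <- draws
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy is
#' cost-effective: the fraction of Monte-Carlo draws in which it attains the
#' strictly highest net monetary benefit (exact ties split equally, a
#' measure-zero event under continuous sampling). Probabilities sum to 1 at
#' every threshold.
#'
#' @param psa An `rrms_psa` object from [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay values (THB/QALY); default 0
#'   to 500,000 in steps of 10,000.
#' @return A data.frame of class `rrms_ceac`: `wtp` plus one probability
#'   column per strategy.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 500000, by = 10000)) {
  stopifnot(inherits(psa, "data.frame"), nrow(psa) >= 1, length(wtp_grid) >= 1)
  strat <- unique(psa$strategy)
  cost <- stats::xtabs(cost ~ draw + strategy, psa)[, strat, drop = FALSE]
  qaly <- stats::xtabs(qaly ~ draw + strategy, psa)[, strat, drop = FALSE]
  n <- nrow(cost)
  probs <- t(vapply(wtp_grid, function(w) {
    b <- nmb(cost, qaly, w)
    best <- b == apply(b, 1, max)
    colSums(best / rowSums(best)) / n
  }, numeric(length(strat))))
  out <- data.frame(wtp = wtp_grid, probs)
  names(out) <- c("wtp", strat)
  class(out) <- c("rrms_ceac", "data.frame")
  out
}

#' @export
plot.rrms_ceac <- function(x, ...) {
  strat <- setdiff(names(x), "wtp")
  graphics::matplot(x$wtp, as.matrix(x[strat]), type = "l", lty = 1, lwd = 2,
                    xlab = "Willingness to pay (THB/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("right", legend = vapply(strat, strategy_label, ""),
                   col = seq_along(strat), lty = 1, bty = "n")
  invisible(x)
}
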