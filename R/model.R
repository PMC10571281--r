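#' Run the RRMS cost-utility model
#'
#' The central entry point: builds the strategy transition matrices, runs the
#' cohort traces over the configured horizon, accrues discounted costs,
#' life-years and QALYs, and assembles the incremental cost-effectiveness
#' table against the reference strategy.
#'
#' @param params An [rrms_parameters()] object (defaults to the published
#'   Thai RRMS inputs).
#' @param strategies_run Strategy codes to evaluate; default all three.
#' @param reference Comparator for incremental results, default `"bsc"`.
#' @param initial Initial occupancy vector (default: whole cohort newly
#'   diagnosed in EDSS 0.0-2.5).
#' @param values Optional named parameter-value vector overriding the means
#'   (used internally by the sensitivity analyses).
#' @return An object of class `rrms_cua` with elements `params`, `matrices`,
#'   `traces`, `results` (list of `rrms_result`), and `icer` (the
#'   [icer_table()]). Methods: `print`, `summary`, `plot`, `simulate`,
#'   `as.data.frame`.
#' @examples
#' m <- rrms_cua(rrms_parameters(horizon_cycles = 240))
#' m
#' @export
rrms_cua <- function(params = rrms_parameters(),
                     strategies_run = strategies(),
                     reference = "bsc",
                     initial = c(1, 0, 0, 0, 0, 0, 0),
                     values = NULL) {
  stopifnot(inherits(params, "rrms_parameters"))
  strategies_run <- match.arg(strategies_run, strategies(), several.ok = TRUE)
  if (!reference %in% strategies_run)
    stop("rrms_cua: reference strategy must be among those run")
  p <- params
  if (!is.null(values)) {
    for (nm in names(values)) p$specs[[nm]]$mean <- values[[nm]]
  }
  h <- p$settings$horizon_cycles
  matrices <- lapply(stats::setNames(strategies_run, strategies_run),
                     function(s) transition_matrix(p, s))
  traces <- lapply(matrices, run_cohort, initial = initial, horizon_cycles = h)
  results <- lapply(strategies_run, function(s) accrue(traces[[s]], p, s))
  structure(list(params = params,
                 matrices = matrices,
                 traces = traces,
                 results = stats::setNames(results, strategies_run),
                 icer = icer_table(results, reference)),
            class = "rrms_cua")
}

#' @export
print.rrms_cua <- function(x, ...) {
  st <- x$params$settings
  cat(sprintf("RRMS cost-utility model: %d strategies, %d monthly cycles, discount %g%%/%g%%\n\n",
              length(x$results), st$horizon_cycles,
              100 * st$discount_cost_annual, 100 * st$discount_outcome_annual))
  print(format_icer(x$icer, st$thb_per_usd), row.names = FALSE)
  invisible(x)
}

## Table-2-style display frame (THB with USD in parentheses).
format_icer <- function(icer, fx) {
  thb_usd <- function(v) ifelse(is.na(v), "",
                                sprintf("%s (%s)", format(round(v), big.mark = ",", trim = TRUE),
                                        format(round(v / fx), big.mark = ",", trim = TRUE)))
  ratio <- function(v, lab) ifelse(lab != "", lab,
                                   ifelse(is.na(v), "",
                                          format(round(v), big.mark = ",", trim = TRUE)))
  data.frame(strategy = vapply(icer$strategy, strategy_label, ""),
             total_cost = thb_usd(icer$total_cost),
             LYs = sprintf("%.2f", icer$total_ly),
             QALYs = sprintf("%.2f", icer$total_qaly),
             inc_cost = thb_usd(icer$inc_cost),
             inc_LYs = ifelse(is.na(icer$inc_ly), "", sprintf("%.2f", icer$inc_ly)),
             inc_QALYs = ifelse(is.na(icer$inc_qaly), "", sprintf("%.2f", icer$inc_qaly)),
             ICER_per_LY = ratio(icer$icer_ly, icer$icer_ly_label),
             ICER_per_QALY = ratio(icer$icer_qaly, icer$icer_qaly_label),
             stringsAsFactors = FALSE)
}

#' @export
summary.rrms_cua <- function(object, ...) {
  st <- object$params$settings
  cat("Base-case cost-effectiveness results (reference: ",
      strategy_label(attr(object$icer, "reference")), ")\n\n", sep = "")
  print(format_icer(object$icer, st$thb_per_usd), row.names = FALSE)
  cat("\nCost breakdown (THB, discounted):\n")
  bk <- t(vapply(object$results, `[[`, numeric(6), "cost_breakdown"))
  print(round(bk))
  wtp <- st$wtp
  n <- vapply(object$results, function(r) nmb(r$total_cost, r$total_qaly, wtp), numeric(1))
  cat(sprintf("\nNet monetary benefit at WTP %s THB/QALY:\n", format(wtp, big.mark = ",")))
  print(round(n))
  invisible(object)
}

#' @export
as.data.frame.rrms_cua <- function(x, ...) as.data.frame(x$icer)

#' Plot method for the cost-utility model
#'
#' `type = "trace"` draws the state-occupancy curves of one strategy over
#' time; `type = "survival"` overlays the alive proportion for all
#' strategies.
#'
#' @param x An `rrms_cua` object.
#' @param type `"trace"` or `"survival"`.
#' @param strategy Strategy to plot for `type = "trace"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rrms_cua <- function(x, type = c("trace", "survival"), strategy = "bsc", ...) {
  type <- match.arg(type)
  yrs <- (seq_len(nrow(x$traces[[1]])) - 1) / 12
  if (type == "trace") {
    tr <- x$traces[[strategy]]
    graphics::matplot(yrs, tr, type = "l", lty = 1, lwd = 2,
                      xlab = "Years", ylab = "State occupancy",
                      main = strategy_label(strategy), ...)
    graphics::legend("right", legend = names(health_states()),
                     col = seq_len(7), lty = 1, cex = 0.7, bty = "n")
  } else {
    alive <- vapply(x$traces, function(tr) 1 - tr[, "dead"],
                    numeric(nrow(x$traces[[1]])))
    graphics::matplot(yrs, alive, type = "l", lty = 1, lwd = 2,
                      xlab = "Years", ylab = "Proportion alive", ...)
    graphics::legend("bottomleft", legend = vapply(names(x$traces), strategy_label, ""),
                     col = seq_along(x$traces), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate patient-level trajectories from the fitted model
#'
#' Draws individual state sequences from one strategy's transition matrix --
#' the microsimulation counterpart of the cohort trace (see
#' [simulate_patients()]).
#'
#' @param object An `rrms_cua` object.
#' @param nsim Number of patients.
#' @param seed Integer seed for reproducibility.
#' @param strategy Strategy whose matrix is simulated, default `"bsc"`.
#' @param ... Unused.
#' @return An `rrms_microsim` object.
#' @importFrom stats simulate
#' @export
simulate.rrms_cua <- function(object, nsim = 1000, seed = 1L, strategy = "bsc", ...) {
  simulate_patients(object$matrices[[strategy]], n = nsim,
                    horizon_cycles = object$params$settings$horizon_cycles,
                    seed = seed)
}
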