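#' Discount factor for a monthly cycle
#'
#' Continuous-compounding convention on annual rates applied at monthly
#' resolution: `(1 + rate)^(-cycle / 12)`. Cycle 0 is undiscounted.
#'
#' @param cycle Cycle index (0-based), months.
#' @param annual_rate Annual discount rate, >= 0.
#' @return Discount factor in (0, 1].
#' @examples
#' discount_factor(12, 0.03) # one year: 1 / 1.03
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(annual_rate < 0)) stop("discount_factor: negative rate")
  if (any(cycle < 0)) stop("discount_factor: negative cycle")
  (1 + annual_rate)^(-cycle / 12)
}

## Per-cycle cost vectors by state and component for one strategy.
## Components: drug, admin, opd, relapse, nonmedical, adverse_events.
state_cost_components <- function(pv, strategy, settings) {
  treated <- strategy != "bsc"
  drug <- switch(strategy,
                 bsc = 0,
                 rituximab = pv[["c_rituximab_month"]],
                 biosimilar = pv[["c_biosimilar_month"]])
  on_treatment <- c(1, 1, 1, 1, 0, 0, 0) * as.numeric(treated)
  opd <- c(pv[["c_opd_edss0"]], pv[["c_opd_edss0"]],
           pv[["c_opd_edss3"]], pv[["c_opd_edss3"]],
           pv[["c_opd_edss6"]], pv[["c_opd_edss8"]], 0)
  relapse <- c(0, pv[["c_relapse_edss0"]], 0, pv[["c_relapse_edss3"]], 0, 0, 0)
  if (isTRUE(settings$late_relapse_costs)) {
    ## Relapses still occur from EDSS 6.0-7.5 / 8.0-9.5 clinically even though
    ## the model carries no relapse state there; charge the expected monthly
    ## relapse management cost (see methods vignette).
    relapse[5] <- pv[["p_relapse"]] * pv[["c_relapse_edss6"]]
    relapse[6] <- pv[["p_relapse"]] * pv[["c_relapse_edss8"]]
  }
  nonmed <- c(pv[["c_nonmed_edss0"]], pv[["c_nonmed_edss0"]],
              pv[["c_nonmed_edss3"]], pv[["c_nonmed_edss3"]],
              pv[["c_nonmed_edss6"]], pv[["c_nonmed_edss8"]], 0)
  ae_month <- (pv[["p_infusion_reaction"]] * pv[["c_infusion_reaction"]] +
               pv[["p_minor_infection"]]  * pv[["c_minor_infection"]] +
               pv[["p_agranulocytosis"]]  * pv[["c_agranulocytosis"]] +
               pv[["p_pneumonia"]]        * pv[["c_pneumonia"]]) / 12
  list(drug = drug * on_treatment,
       admin = pv[["c_admin_month"]] * on_treatment,
       opd = opd,
       relapse = relapse,
       nonmedical = nonmed,
       adverse_events = ae_month * on_treatment)
}

state_utilities <- function(pv) {
  c(pv[["u_edss0"]], pv[["u_relapse0"]], pv[["u_edss3"]], pv[["u_relapse3"]],
    pv[["u_edss6"]], pv[["u_edss8"]], 0)
}

#' Accrue discounted costs, life-years and QALYs along a cohort trace
#'
#' For each cycle the state-occupancy row is multiplied by the per-cycle
#' state costs (OPD medical, direct non-medical, relapse management in
#' relapse states, and -- under treated strategies while the cohort is below
#' EDSS 6.0 -- drug, administration and expected adverse-event costs) and by
#' the per-cycle utility (annual utility / 12). Costs are discounted at the
#' cost rate, outcomes at the outcome rate; cycle contributions use the
#' occupancy at the start of each cycle (rows 1..horizon of the trace), or
#' the mean of start and end occupancy when `settings$half_cycle` is enabled.
#'
#' @param trace A cohort trace from [run_cohort()].
#' @param params The parameter set used to build the trace's matrix.
#' @param strategy Strategy the trace belongs to; defaults to the trace's own
#'   strategy attribute.
#' @param values Optional named vector of parameter values overriding the
#'   parameter means (used by the probabilistic sensitivity analysis).
#' @return An object of class `rrms_result`: list with `strategy`,
#'   `total_cost` (THB), `total_ly`, `total_qaly` (both discounted), and
#'   `cost_breakdown` by component (drug, admin, opd, relapse, nonmedical,
#'   adverse_events), which sums to `total_cost`.
#' @examples
#' p <- rrms_parameters(horizon_cycles = 120)
#' tr <- run_cohort(transition_matrix(p, "bsc"), horizon_cycles = 120)
#' accrue(tr, p)$total_qaly
#' @export
accrue <- function(trace, params, strategy = NULL, values = NULL) {
  stopifnot(inherits(trace, "rrms_trace") || is.matrix(trace),
            inherits(params, "rrms_parameters"))
  strategy <- strategy %||% attr(trace, "strategy")
  if (is.null(strategy)) stop("accrue: strategy not given and not stored on trace")
  if (!strategy %in% strategies()) stop("accrue: unknown strategy '", strategy, "'")
  st <- params$settings
  pv <- values %||% param_means(params)
  h <- nrow(trace) - 1L
  occ <- trace[seq_len(h), , drop = FALSE]
  if (isTRUE(st$half_cycle))
    occ <- (occ + trace[seq_len(h) + 1L, , drop = FALSE]) / 2
  cyc <- 0:(h - 1L)
  dfc <- discount_factor(cyc, st$discount_cost_annual)
  dfe <- discount_factor(cyc, st$discount_outcome_annual)
  dfl <- if (isTRUE(st$discount_ly)) dfe else rep(1, h)

  comp <- state_cost_components(pv, strategy, st)
  breakdown <- vapply(comp, function(cs) sum((occ %*% cs) * dfc), numeric(1))
  alive <- c(rep(1 / 12, 6), 0)
  u_cyc <- state_utilities(pv) / 12

  structure(list(strategy = strategy,
                 total_cost = sum(breakdown),
                 total_ly = sum((occ %*% alive) * dfl),
                 total_qaly = sum((occ %*% u_cyc) * dfe),
                 cost_breakdown = breakdown),
            class = "rrms_result")
}

#' @export
print.rrms_result <- function(x, ...) {
  cat(sprintf("%s: cost %s THB, %.2f LYs, %.2f QALYs (discounted)\n",
              strategy_label(x$strategy),
              format(round(x$total_cost), big.mark = ","),
              x$total_ly, x$total_qaly))
  invisible(x)
}

#' Incremental cost-effectiveness table with dominance handling
#'
#' Computes incremental cost, life-years and QALYs of each strategy against
#' the reference, and the corresponding ICERs. A strategy that is cheaper and
#' more effective is labelled `"Dominant"`; costlier and less effective,
#' `"Dominated"`; a zero incremental effect with nonzero incremental cost
#' yields `NA` (undefined ratio).
#'
#' @param results List of `rrms_result` objects (one per strategy).
#' @param reference Strategy code used as comparator, default `"bsc"`.
#' @return A data.frame of class `rrms_icer` with one row per strategy:
#'   totals, incrementals, `icer_qaly`, `icer_ly` (numeric) and
#'   `icer_qaly_label`, `icer_ly_label` (character, dominance labels where the
#'   ratio is not reported).
#' @export
icer_table <- function(results, reference = "bsc") {
  stopifnot(length(results) >= 1)
  codes <- vapply(results, `[[`, "", "strategy")
  if (!reference %in% codes) stop("icer_table: reference '", reference, "' absent")
  names(results) <- codes
  ref <- results[[reference]]

  one_ratio <- function(dc, de) {
    if (dc > 0 && de < 0) return(list(value = NA_real_, label = "Dominated"))
    if (dc < 0 && de > 0) return(list(value = NA_real_, label = "Dominant"))
    if (de == 0) return(list(value = NA_real_,
                             label = if (dc == 0) "" else "Undefined"))
    list(value = dc / de, label = "")
  }

  rows <- lapply(results, function(r) {
    dc <- r$total_cost - ref$total_cost
    dly <- r$total_ly - ref$total_ly
    dq <- r$total_qaly - ref$total_qaly
    is_ref <- identical(r$strategy, reference)
    rq <- one_ratio(dc, dq); rl <- one_ratio(dc, dly)
    data.frame(strategy = r$strategy,
               total_cost = r$total_cost,
               total_ly = r$total_ly,
               total_qaly = r$total_qaly,
               inc_cost = if (is_ref) NA_real_ else dc,
               inc_ly = if (is_ref) NA_real_ else dly,
               inc_qaly = if (is_ref) NA_real_ else dq,
               icer_qaly = if (is_ref) NA_real_ else rq$value,
               icer_ly = if (is_ref) NA_real_ else rl$value,
               icer_qaly_label = if (is_ref) "" else rq$label,
               icer_ly_label = if (is_ref) "" else rl$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("rrms_icer", "data.frame")
  attr(out, "reference") <- reference
  out
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`: the valuation that ranks strategies on a common THB
#' scale; the strategy with the highest net monetary benefit at a
#' willingness-to-pay threshold is the cost-effective one.
#'
#' @param cost Total cost, THB.
#' @param qaly Total QALYs.
#' @param wtp Willingness to pay, THB per QALY (>= 0).
#' @return Net monetary benefit in THB (vectorised).
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("nmb: negative willingness to pay")
  wtp * qaly - cost
}
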