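#' Population inputs for the budget-impact analysis
#'
#' The Thai MS population served by the reimbursement scheme: prevalent
#' patients at baseline, stable yearly incidence, and the programme coverage
#' rate.
#'
#' @param prevalent Prevalent patients at the start of fiscal year 1
#'   (default 572).
#' @param incident New cases entering at the start of every fiscal year
#'   (default 51).
#' @param coverage Proportion of eligible patients treated (default 0.90).
#' @param years Projection length in fiscal years (default 5).
#' @return A validated list of class `rrms_population`.
#' @export
population_inputs <- function(prevalent = 572, incident = 51,
                              coverage = 0.9, years = 5L) {
  if (prevalent < 0 || incident < 0) stop("population counts must be >= 0")
  if (coverage < 0 || coverage > 1) stop("coverage must lie in [0, 1]")
  if (years < 1) stop("years must be >= 1")
  structure(list(prevalent = prevalent, incident = incident,
                 coverage = coverage, years = as.integer(years)),
            class = "rrms_population")
}

## Undiscounted annual cost stream per patient over `years` fiscal years,
## from the Markov trace of one strategy, restricted to the requested
## components. Non-medical costs never enter (government perspective).
annual_cost_stream <- function(params, strategy, years, components,
                               initial = c(1, 0, 0, 0, 0, 0, 0)) {
  comp_names <- switch(components,
                       treatment_only = c("drug", "admin", "adverse_events"),
                       all_direct_medical = c("drug", "admin", "opd", "relapse",
                                              "adverse_events"),
                       stop("unknown budget components '", components, "'"))
  h <- years * 12L
  tr <- run_cohort(transition_matrix(params, strategy), initial = initial,
                   horizon_cycles = h)
  pv <- param_means(params)
  comp <- state_cost_components(pv, strategy, params$settings)
  cs <- Reduce(`+`, comp[comp_names])
  monthly <- as.vector(tr[seq_len(h), , drop = FALSE] %*% cs)
  as.vector(tapply(monthly, rep(seq_len(years), each = 12L), sum))
}

## Alive proportion per fiscal year (mean over the year's months).
annual_alive <- function(params, strategy, years,
                         initial = c(1, 0, 0, 0, 0, 0, 0)) {
  h <- years * 12L
  tr <- run_cohort(transition_matrix(params, strategy), initial = initial,
                   horizon_cycles = h)
  alive <- 1 - tr[seq_len(h), "dead"]
  as.vector(tapply(alive, rep(seq_len(years), each = 12L), mean))
}

#' Per-year treated patient counts
#'
#' Fiscal year 1 treats `coverage * (prevalent + incident)` patients; each
#' later year adds `coverage * incident` new patients to the surviving pool
#' (survival from the treated Markov trace; incidence assumed stable).
#'
#' @param pop A [population_inputs()] object.
#' @param params Parameter set used for the survival trace.
#' @param strategy Treated strategy, default `"biosimilar"`.
#' @return Numeric vector of treated counts per fiscal year.
#' @export
project_population <- function(pop = population_inputs(),
                               params = rrms_parameters(),
                               strategy = "biosimilar") {
  stopifnot(inherits(pop, "rrms_population"))
  surv <- annual_alive(params, strategy, pop$years)
  vapply(seq_len(pop$years), function(y) {
    entrants <- c(pop$prevalent + pop$incident,
                  rep(pop$incident, y - 1L))          # cohorts by entry year
    ages <- y - seq_along(entrants) + 1L              # years since entry
    pop$coverage * sum(entrants * surv[ages])
  }, numeric(1))
}

#' Five-year budget-impact projection
#'
#' Projects the incremental government budget of adopting a treated strategy
#' for the national MS population, fiscal year by fiscal year, with no
#' discounting. Cohorts (the prevalent pool plus one incident cohort per
#' year) are aged along the treated and untreated Markov traces; covered
#' patients follow the treated trace, the remainder best supportive care in
#' both scenarios, so the incremental budget is
#' `coverage * sum over cohorts of (treated - untreated annual cost)`.
#'
#' `components = "treatment_only"` (default) counts the costs the programme
#' itself reimburses -- drug, administration and adverse-event management.
#' `components = "all_direct_medical"` additionally nets the OPD and relapse
#' medical costs saved by treatment; see the methods vignette for the
#' calibration of this choice. Direct non-medical costs never enter a budget
#' figure (government perspective).
#'
#' @param params An [rrms_parameters()] object.
#' @param pop A [population_inputs()] object.
#' @param strategy Treated strategy, default `"biosimilar"`.
#' @param components Cost components, see Details.
#' @param initial Initial state distribution of entering patients (default:
#'   all newly diagnosed in EDSS 0.0-2.5; a different prevalent-pool mix can
#'   be supplied).
#' @return A data.frame of class `rrms_budget`: `fiscal_year`,
#'   `treated_count`, `cost_with`, `cost_without`, `incremental_thb`,
#'   `incremental_usd`.
#' @examples
#' budget_impact(rrms_parameters())
#' @export
budget_impact <- function(params = rrms_parameters(),
                          pop = population_inputs(),
                          strategy = "biosimilar",
                          components = c("treatment_only", "all_direct_medical"),
                          initial = c(1, 0, 0, 0, 0, 0, 0)) {
  components <- match.arg(components)
  stopifnot(inherits(params, "rrms_parameters"), inherits(pop, "rrms_population"))
  years <- pop$years
  s_trt <- annual_cost_stream(params, strategy, years, components, initial)
  s_bsc <- annual_cost_stream(params, "bsc", years, components, initial)
  treated <- project_population(pop, params, strategy)

  per_year <- function(stream, y) {
    entrants <- c(pop$prevalent + pop$incident, rep(pop$incident, y - 1L))
    ages <- y - seq_along(entrants) + 1L
    sum(entrants * stream[ages])
  }
  cost_with <- cost_without <- numeric(years)
  for (y in seq_len(years)) {
    cost_with[y] <- pop$coverage * per_year(s_trt, y) +
      (1 - pop$coverage) * per_year(s_bsc, y)
    cost_without[y] <- per_year(s_bsc, y)
  }
  inc <- cost_with - cost_without
  out <- data.frame(fiscal_year = seq_len(years),
                    treated_count = treated,
                    cost_with = cost_with,
                    cost_without = cost_without,
                    incremental_thb = inc,
                    incremental_usd = inc / params$settings$thb_per_usd)
  class(out) <- c("rrms_budget", "data.frame")
  attr(out, "components") <- components
  out
}

#' @export
print.rrms_budget <- function(x, ...) {
  cat("Budget impact (", attr(x, "components"), ", undiscounted)\n", sep = "")
  d <- x
  d$treated_count <- round(d$treated_count)
  for (cl in c("cost_with", "cost_without", "incremental_thb", "incremental_usd"))
    d[[cl]] <- format(round(d[[cl]]), big.mark = ",")
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}
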