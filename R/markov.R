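#' Health states of the RRMS Markov model
#'
#' Seven states: four living EDSS severity bands, relapse states attached to
#' the two mildest bands, and an absorbing death state. Disability is
#' irreversible: no transition may lower the EDSS band.
#'
#' @return Character vector of state codes, named by display label.
#' @export
health_states <- function() {
  c("EDSS 0.0-2.5"         = "edss0",
    "Relapse EDSS 0.0-2.5" = "rel0",
    "EDSS 3.0-5.5"         = "edss3",
    "Relapse EDSS 3.0-5.5" = "rel3",
    "EDSS 6.0-7.5"         = "edss6",
    "EDSS 8.0-9.5"         = "edss8",
    "Dead"                 = "dead")
}

#' Treatment strategies
#'
#' `bsc` is best supportive care (no disease-modifying therapy). `rituximab`
#' and `biosimilar` share identical transitions (equal efficacy is assumed)
#' and differ only in the monthly drug cost.
#'
#' @return Character vector of strategy codes, named by display label.
#' @export
strategies <- function() {
  c("Best supportive care" = "bsc",
    "Rituximab"            = "rituximab",
    "Rituximab biosimilar" = "biosimilar")
}

strategy_label <- function(strategy) {
  s <- strategies()
  names(s)[match(strategy, s)]
}

## Monthly relapse probability for a strategy, honouring the configured
## interpretation of the treated relapse parameter.
relapse_prob <- function(pv, strategy, settings) {
  if (strategy == "bsc") return(pv[["p_relapse"]])
  if (settings$relapse_effect == "relative_risk")
    pv[["p_relapse"]] * pv[["relapse_effect_rtx"]]
  else
    pv[["relapse_effect_rtx"]]
}

#' Build the monthly transition matrix for one strategy
#'
#' Under best supportive care all rows use the untreated transition
#' probabilities. Under rituximab or its biosimilar, the EDSS 0.0-2.5 and
#' 3.0-5.5 rows use the treated progression probabilities and the treated
#' relapse probability (by default the untreated probability multiplied by
#' the relative risk 0.4220); treatment stops on reaching EDSS 6.0-7.5, so
#' rows from that state onward are identical to best supportive care. Relapse
#' states return to their parent band after one cycle
#' (`relapse_return = "one_cycle"`) or with the relapse probability itself
#' (`"symmetric"`), carry the band's death probability, and -- when
#' `relapse_progression` is enabled (default) -- may progress to the next
#' band at the band's progression probability. Death is absorbing and the
#' diagonal absorbs the remaining mass.
#'
#' @param params An [rrms_parameters()] object.
#' @param strategy One of `"bsc"`, `"rituximab"`, `"biosimilar"`.
#' @return A 7x7 row-stochastic matrix of class `rrms_matrix` with state
#'   codes as dimnames and the strategy stored as an attribute.
#' @examples
#' P <- transition_matrix(rrms_parameters(), "bsc")
#' rowSums(P)
#' @export
transition_matrix <- function(params, strategy = strategies()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "rrms_parameters"))
  pv <- param_means(params)
  st <- params$settings
  treated <- strategy != "bsc"

  prel <- relapse_prob(pv, strategy, st)
  p03 <- if (treated) pv[["p_prog_rtx_0to3"]] else pv[["p_edss3"]]
  p36 <- if (treated) pv[["p_prog_rtx_3to6"]] else pv[["p_edss6"]]

  s <- unname(health_states())
  P <- matrix(0, 7, 7, dimnames = list(s, s))

  fill_row <- function(P, from, to, p) {
    P[from, to] <- p
    off <- sum(P[from, setdiff(s, from)])
    if (off > 1 + 1e-12)
      stop("transition_matrix: outgoing probabilities from '", from,
           "' sum to ", signif(off, 6), " > 1")
    P[from, from] <- 1 - off
    P
  }

  P <- fill_row(P, "edss0", c("rel0", "edss3", "dead"),
                c(prel, p03, pv[["p_death_edss0"]]))
  P <- fill_row(P, "edss3", c("rel3", "edss6", "dead"),
                c(prel, p36, pv[["p_death_edss3"]]))
  P <- fill_row(P, "edss6", c("edss8", "dead"),
                c(pv[["p_edss8"]], pv[["p_death_edss6"]]))
  P <- fill_row(P, "edss8", "dead", pv[["p_edss10"]])
  P["dead", "dead"] <- 1

  ## relapse rows: return to parent band, band death risk, optional progression
  ret0 <- if (st$relapse_return == "one_cycle") 1 - pv[["p_death_edss0"]] else prel
  ret3 <- if (st$relapse_return == "one_cycle") 1 - pv[["p_death_edss3"]] else prel
  pr0 <- if (isTRUE(st$relapse_progression)) p03 else 0
  pr3 <- if (isTRUE(st$relapse_progression)) p36 else 0
  if (st$relapse_return == "one_cycle") {
    ret0 <- ret0 - pr0
    ret3 <- ret3 - pr3
  }
  P <- fill_row(P, "rel0", c("edss0", "edss3", "dead"),
                c(ret0, pr0, pv[["p_death_edss0"]]))
  P <- fill_row(P, "rel3", c("edss3", "edss6", "dead"),
                c(ret3, pr3, pv[["p_death_edss3"]]))

  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    stop("transition_matrix: entries outside [0, 1]")
  P <- pmin(pmax(P, 0), 1)
  structure(P, class = c("rrms_matrix", "matrix", "array"), strategy = strategy)
}

#' Propagate a cohort through the Markov model
#'
#' Left-multiplies the occupancy row vector by the transition matrix once per
#' cycle. Row `t + 1` of the returned trace is the state distribution after
#' `t` cycles; row 1 is the initial distribution.
#'
#' @param matrix A transition matrix from [transition_matrix()] (any 7x7
#'   row-stochastic matrix is accepted).
#' @param initial Initial occupancy vector summing to 1; default places the
#'   whole cohort, newly diagnosed, in EDSS 0.0-2.5.
#' @param horizon_cycles Number of monthly cycles to run.
#' @return A `(horizon_cycles + 1) x 7` matrix of class `rrms_trace`.
#' @examples
#' P <- transition_matrix(rrms_parameters(), "bsc")
#' tr <- run_cohort(P, horizon_cycles = 120)
#' tr[121, "dead"]
#' @export
run_cohort <- function(matrix,
                       initial = c(1, 0, 0, 0, 0, 0, 0),
                       horizon_cycles = 720L) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 7, ncol(matrix) == 7,
            length(initial) == 7, horizon_cycles >= 1)
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-10))
    stop("run_cohort: matrix is not row-stochastic")
  if (abs(sum(initial) - 1) > 1e-10)
    stop("run_cohort: initial distribution must sum to 1")
  h <- as.integer(horizon_cycles)
  tr <- base::matrix(0, h + 1L, 7L,
                     dimnames = list(NULL, colnames(matrix) %||% unname(health_states())))
  tr[1L, ] <- initial
  M <- unclass(matrix)
  for (t in seq_len(h)) tr[t + 1L, ] <- tr[t, ] %*% M
  structure(tr, class = c("rrms_trace", "matrix", "array"),
            strategy = attr(matrix, "strategy"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
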