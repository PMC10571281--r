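#' Simulate individual patient trajectories
#'
#' The brute-force counterpart of the cohort engine: each patient's next
#' state is drawn from their current state's transition-matrix row. By the
#' law of large numbers the empirical state frequencies converge on the
#' cohort trace, which is the basis of the engine-validation tests. Sampling
#' is vectorised cycle by cycle from a single seeded stream, so results are
#' reproducible for a given `(seed, n, horizon)`.
#'
#' @param matrix A 7x7 row-stochastic transition matrix.
#' @param n Number of patients.
#' @param horizon_cycles Number of monthly cycles.
#' @param seed Integer seed.
#' @param initial Initial state distribution patients are drawn from.
#' @return An object of class `rrms_microsim`: an `n x (horizon_cycles + 1)`
#'   integer matrix of state indices (1..7 in the order of
#'   [health_states()]), with the matrix and seed as attributes.
#' @export
simulate_patients <- function(matrix, n, horizon_cycles = 360L, seed = 1L,
                              initial = c(1, 0, 0, 0, 0, 0, 0)) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 7, ncol(matrix) == 7, n >= 1)
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-10))
    stop("simulate_patients: matrix is not row-stochastic")
  h <- as.integer(horizon_cycles)
  set.seed(as.integer(seed))
  states <- base::matrix(0L, nrow = n, ncol = h + 1L)
  states[, 1L] <- sample.int(7L, n, replace = TRUE, prob = initial)
  M <- unclass(matrix)
  for (t in seq_len(h)) {
    cur <- states[, t]
    nxt <- cur
    for (s in which(tabulate(cur, 7L)[1:6] > 0L)) {
      idx <- which(cur == s)
      nxt[idx] <- sample.int(7L, length(idx), replace = TRUE, prob = M[s, ])
    }
    states[, t + 1L] <- nxt
  }
  structure(states, class = c("rrms_microsim", "matrix", "array"),
            matrix = M, seed = as.integer(seed))
}

#' @export
print.rrms_microsim <- function(x, ...) {
  cat(sprintf("Microsimulation: %d patients x %d cycles; %.1f%% dead at end\n",
              nrow(x), ncol(x) - 1L, 100 * mean(x[, ncol(x)] == 7L)))
  invisible(x)
}

#' Maximum-likelihood transition-probability estimates from trajectories
#'
#' Per-cycle transition frequencies: transitions observed along each
#' permissible arrow divided by patient-cycles at risk in the source state.
#' States never visited have undefined (NA) outgoing estimates and are
#' reported in the `undefined` element.
#'
#' @param trajectories An `rrms_microsim` object (or integer state matrix).
#' @return List with `phat` (7x7 estimated transition matrix, rows with zero
#'   exposure all NA), `exposure` (patient-cycles at risk per state), and
#'   `undefined` (state codes with zero exposure).
#' @export
estimate_transitions <- function(trajectories) {
  stopifnot(is.matrix(trajectories), ncol(trajectories) >= 2)
  s <- unname(health_states())
  from <- as.vector(trajectories[, -ncol(trajectories)])
  to <- as.vector(trajectories[, -1L])
  counts <- base::matrix(0, 7, 7, dimnames = list(s, s))
  tab <- table(factor(from, levels = 1:7), factor(to, levels = 1:7))
  counts[] <- as.numeric(tab)
  exposure <- rowSums(counts)
  phat <- counts / ifelse(exposure > 0, exposure, NA_real_)
  list(phat = phat,
       exposure = stats::setNames(exposure, s),
       undefined = s[exposure == 0])
}

#' Compare a cohort trace with microsimulated trajectories
#'
#' Per-cycle maximum absolute deviation between the empirical state
#' frequencies of the trajectories and the cohort-trace occupancy. For
#' trajectories generated from the same matrix as the trace, the deviation is
#' bounded by Monte-Carlo error (about `4 * sqrt(p(1-p)/n)` per cell).
#'
#' @param trace An `rrms_trace` from [run_cohort()].
#' @param trajectories An `rrms_microsim` with the same horizon.
#' @return Numeric vector, length `horizon + 1`: max absolute occupancy
#'   deviation at each cycle.
#' @export
compare_cohort_microsim <- function(trace, trajectories) {
  stopifnot(is.matrix(trace), is.matrix(trajectories))
  if (nrow(trace) != ncol(trajectories))
    stop("compare_cohort_microsim: horizon mismatch (trace ", nrow(trace) - 1L,
         " vs trajectories ", ncol(trajectories) - 1L, " cycles)")
  n <- nrow(trajectories)
  vapply(seq_len(nrow(trace)), function(t) {
    freq <- tabulate(trajectories[, t], 7L) / n
    max(abs(freq - trace[t, ]))
  }, numeric(1))
}

#' Mean undiscounted cost and QALYs per simulated patient
#'
#' Accrues the same per-cycle state costs and utilities as [accrue()] along
#' each simulated trajectory, without discounting -- used to validate cohort
#' accrual against the microsimulation.
#'
#' @param trajectories An `rrms_microsim` object.
#' @param params Parameter set.
#' @param strategy Strategy whose cost structure applies.
#' @return List with `mean_cost`, `mean_qaly`, and per-patient vectors
#'   `cost`, `qaly`.
#' @export
microsim_outcomes <- function(trajectories, params, strategy = "bsc") {
  stopifnot(is.matrix(trajectories), inherits(params, "rrms_parameters"))
  pv <- param_means(params)
  cs <- Reduce(`+`, state_cost_components(pv, strategy, params$settings))
  uu <- state_utilities(pv) / 12
  occ <- trajectories[, -ncol(trajectories), drop = FALSE]  # state during cycle
  cost <- rowSums(base::matrix(cs[occ], nrow = nrow(occ)))
  qaly <- rowSums(base::matrix(uu[occ], nrow = nrow(occ)))
  list(mean_cost = mean(cost), mean_qaly = mean(qaly), cost = cost, qaly = qaly)
}
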