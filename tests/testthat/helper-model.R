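## Shared fixtures: a short-horizon parameter set for fast model runs, and a
## toy absorbing-chain matrix with known closed-form behaviour.

short_params <- function(...) rrms_parameters(horizon_cycles = 120L, ...)

state_codes <- unname(rrmscea::health_states())

## 7x7 matrix: stay in state 1 w.p. `stay`, otherwise die; all other living
## states jump straight to death. Occupancy of state 1 at cycle t = stay^t.
toy_decay_matrix <- function(stay = 0.9) {
  M <- matrix(0, 7, 7, dimnames = list(state_codes, state_codes))
  M[1, 1] <- stay
  M[1, 7] <- 1 - stay
  for (s in 2:6) M[s, 7] <- 1
  M[7, 7] <- 1
  M
}

identity_matrix7 <- function() {
  M <- diag(7)
  dimnames(M) <- list(state_codes, state_codes)
  M
}

all_dead_matrix <- function() {
  M <- matrix(0, 7, 7, dimnames = list(state_codes, state_codes))
  M[, 7] <- 1
  M
}

## Parameter set in which every input is degenerate at its mean, so
## probabilistic draws must reproduce the base case exactly.
all_fixed_params <- function(params = rrms_parameters()) {
  for (nm in names(params$specs)) {
    params$specs[[nm]]$family <- "fixed"
    params$specs[[nm]]$sd <- 0
  }
  params
}
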