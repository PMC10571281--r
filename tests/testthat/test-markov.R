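test_that("transition matrices are row-stochastic with the permitted arrow set", {
  p <- rrms_parameters()
  for (s in strategies()) {
    for (ret in c("one_cycle", "symmetric")) {
      for (prog in c(TRUE, FALSE)) {
        P <- transition_matrix(rrms_parameters(relapse_return = ret,
                                               relapse_progression = prog), s)
        expect_equal(unname(rowSums(P)), rep(1, 7), tolerance = 1e-12)
        expect_true(all(P >= 0 & P <= 1))
        ## death absorbing
        expect_equal(unname(P["dead", ]), c(0, 0, 0, 0, 0, 0, 1))
        ## irreversible disability: no backward EDSS movement
        expect_identical(unname(P["edss3", c("edss0", "rel0")]), c(0, 0))
        expect_identical(unname(P["edss6", c("edss0", "rel0", "edss3", "rel3")]),
                         rep(0, 4))
        expect_identical(unname(P["edss8", c("edss0", "rel0", "edss3", "rel3", "edss6")]),
                         rep(0, 5))
        ## no relapse entry from EDSS >= 6 (relapse diminished there)
        expect_identical(unname(P[c("edss6", "edss8"), c("rel0", "rel3")]),
                         matrix(0, 2, 2))
      }
    }
  }
})

test_that("base-case entries match the published transition inputs", {
  p <- rrms_parameters()
  P <- transition_matrix(p, "bsc")
  expect_equal(P["edss0", "edss3"], 0.0075)
  expect_equal(P["edss0", "rel0"], 0.0755)
  expect_equal(P["edss3", "edss6"], 0.0079)
  expect_equal(P["edss6", "edss8"], 0.0018)
  expect_equal(P["edss8", "dead"], 0.0017)
  expect_equal(P["edss0", "dead"], 0.0009)

  R <- transition_matrix(p, "rituximab")
  ## treated relapse probability under the relative-risk convention
  expect_equal(R["edss0", "rel0"], 0.0755 * 0.4220)
  expect_equal(R["edss0", "edss3"], 0.0041)
  expect_equal(R["edss3", "edss6"], 0.0041)
  ## treatment stops at EDSS 6: later rows identical to BSC
  expect_equal(R["edss6", ], P["edss6", ])
  expect_equal(R["edss8", ], P["edss8", ])

  ## biosimilar transitions identical to originator (equal efficacy)
  B <- transition_matrix(p, "biosimilar")
  expect_equal(unclass(B), unclass(R), ignore_attr = TRUE)

  ## literal-probability reading available by configuration
  L <- transition_matrix(rrms_parameters(relapse_effect = "probability"),
                         "rituximab")
  expect_equal(L["edss0", "rel0"], 0.4220)
})

test_that("relapse-state rows follow the configured return convention", {
  one <- transition_matrix(rrms_parameters(relapse_return = "one_cycle",
                                           relapse_progression = FALSE), "bsc")
  expect_equal(one["rel0", "edss0"], 1 - 0.0009)
  expect_equal(one["rel0", "dead"], 0.0009)
  sym <- transition_matrix(rrms_parameters(relapse_return = "symmetric",
                                           relapse_progression = FALSE), "bsc")
  expect_equal(sym["rel0", "edss0"], 0.0755)
  expect_equal(sym["rel0", "rel0"], 1 - 0.0755 - 0.0009)
})

test_that("overloaded rows are rejected with the offending state named", {
  bad <- rrms_parameters(p_relapse = list(mean = 0.6, sd = 0.1),
                         p_edss3 = list(mean = 0.3, sd = 0.05),
                         p_death_edss0 = list(mean = 0.2, sd = 0.05))
  expect_error(transition_matrix(bad, "bsc"), "edss0")
})

test_that("cohort propagation has the exact closed-form behaviour on toys", {
  ## identity: nothing moves
  tr <- run_cohort(identity_matrix7(), horizon_cycles = 10)
  expect_true(all(tr[, 1] == 1))

  ## immediate absorption
  tr <- run_cohort(all_dead_matrix(), horizon_cycles = 5)
  expect_equal(tr[2:6, 7], rep(1, 5))

  ## geometric decay: occupancy of the start state is 0.9^t
  tr <- run_cohort(toy_decay_matrix(0.9), horizon_cycles = 50)
  expect_equal(tr[, 1], 0.9^(0:50), tolerance = 1e-12)
})

test_that("traces conserve probability and mortality is monotone", {
  p <- rrms_parameters()
  for (s in strategies()) {
    tr <- run_cohort(transition_matrix(p, s), horizon_cycles = 720)
    expect_lt(max(abs(rowSums(tr) - 1)), 1e-10)
    expect_true(all(diff(tr[, "dead"]) >= -1e-15))
    expect_true(all(tr >= -1e-15))
  }
})

test_that("treatment delays severe disability at every cycle", {
  ## cumulative occupancy of EDSS >= 6 under rituximab never exceeds BSC
  p <- rrms_parameters()
  severe <- function(s) {
    tr <- run_cohort(transition_matrix(p, s), horizon_cycles = 720)
    cumsum(tr[, "edss6"] + tr[, "edss8"])
  }
  expect_true(all(severe("rituximab") <= severe("bsc") + 1e-12))
})

test_that("invalid inputs to run_cohort are rejected", {
  M <- identity_matrix7()
  expect_error(run_cohort(M, initial = rep(1, 7)), "sum to 1")
  M[1, 1] <- 0.5
  expect_error(run_cohort(M), "row-stochastic")
})
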