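test_that("discount factors follow the monthly compounding convention", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_identical(discount_factor(137, 0), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(6, 0.03), 1.03^(-0.5), tolerance = 1e-12)
  expect_error(discount_factor(1, -0.01), "negative")
})

test_that("single-cycle accrual reproduces the published unit inputs", {
  ## one cycle fully in EDSS 0.0-2.5, BSC, no discounting:
  ## cost = OPD + non-medical, QALY = utility / 12
  p <- rrms_parameters(discount_cost_annual = 0, discount_outcome_annual = 0)
  tr <- run_cohort(transition_matrix(p, "bsc"), horizon_cycles = 1)
  tr[2, ] <- tr[1, ]  # isolate one cycle of pure EDSS0 occupancy
  r <- accrue(tr, p, "bsc")
  expect_equal(r$total_cost, 1317.70 + 2686.70, tolerance = 1e-9)
  expect_equal(r$total_qaly, 0.600 / 12, tolerance = 1e-12)
  expect_equal(r$total_ly, 1 / 12, tolerance = 1e-12)
})

test_that("an extinct cohort accrues nothing", {
  p <- rrms_parameters()
  tr <- run_cohort(all_dead_matrix(), horizon_cycles = 12)
  tr[1, ] <- c(0, 0, 0, 0, 0, 0, 1)  # already dead at baseline
  r <- accrue(tr, p, "bsc")
  expect_identical(r$total_cost, 0)
  expect_identical(r$total_qaly, 0)
  expect_identical(r$total_ly, 0)
})

test_that("discounted life-years match the closed-form monthly annuity", {
  ## immortal, immobile cohort: LY = sum_{t=0}^{359} (1/12) 1.03^(-t/12)
  p <- rrms_parameters(horizon_cycles = 360)
  tr <- run_cohort(identity_matrix7(), horizon_cycles = 360)
  r <- accrue(tr, p, "bsc")
  ratio <- 1.03^(-1 / 12)
  annuity <- (1 / 12) * (1 - ratio^360) / (1 - ratio)
  expect_equal(r$total_ly, annuity, tolerance = 1e-10)
  expect_equal(r$total_qaly, 0.600 * annuity, tolerance = 1e-10)
})

test_that("cost breakdown sums to the total and responds to unit costs", {
  p <- short_params()
  for (s in strategies()) {
    tr <- run_cohort(transition_matrix(p, s), horizon_cycles = 120)
    r <- accrue(tr, p, s)
    expect_equal(sum(r$cost_breakdown), r$total_cost, tolerance = 1e-6)
    expect_true(all(r$cost_breakdown >= 0))
    expect_lte(r$total_qaly, r$total_ly)
  }
  ## raising any unit cost weakly raises total cost, holding the trace fixed
  tr <- run_cohort(transition_matrix(p, "rituximab"), horizon_cycles = 120)
  base <- accrue(tr, p, "rituximab")$total_cost
  for (nm in grep("^c_", names(p$specs), value = TRUE)) {
    up <- rrmscea:::param_means(p)
    up[nm] <- up[nm] * 1.5
    expect_gte(accrue(tr, p, "rituximab", values = up)$total_cost, base)
  }
})

test_that("discounting monotonicity holds component-wise", {
  p0 <- rrms_parameters(discount_cost_annual = 0, discount_outcome_annual = 0)
  p3 <- rrms_parameters()
  for (s in strategies()) {
    tr <- run_cohort(transition_matrix(p3, s), horizon_cycles = 720)
    r0 <- accrue(tr, p0, s)
    r3 <- accrue(tr, p3, s)
    expect_true(all(r3$cost_breakdown <= r0$cost_breakdown + 1e-9))
    expect_lte(r3$total_qaly, r0$total_qaly)
    expect_lte(r3$total_ly, r0$total_ly)
  }
})

test_that("originator and biosimilar differ only in the drug component", {
  m <- rrms_cua(short_params())
  rtx <- m$results$rituximab
  bio <- m$results$biosimilar
  expect_equal(rtx$total_ly, bio$total_ly, tolerance = 1e-12)
  expect_equal(rtx$total_qaly, bio$total_qaly, tolerance = 1e-12)
  nondrug <- setdiff(names(rtx$cost_breakdown), "drug")
  expect_equal(rtx$cost_breakdown[nondrug], bio$cost_breakdown[nondrug],
               tolerance = 1e-9)
  expect_gt(rtx$cost_breakdown[["drug"]], bio$cost_breakdown[["drug"]])
})

test_that("dominance labels cover all four sign quadrants", {
  mk <- function(strategy, cost, qaly, ly = qaly) {
    structure(list(strategy = strategy, total_cost = cost, total_ly = ly,
                   total_qaly = qaly, cost_breakdown = c(drug = cost)),
              class = "rrms_result")
  }
  ref <- mk("bsc", 100, 10)
  ## costlier & more effective -> ratio
  t1 <- icer_table(list(ref, mk("rituximab", 150, 12)), "bsc")
  expect_equal(t1$icer_qaly[2], 25)
  expect_identical(t1$icer_qaly_label[2], "")
  ## cheaper & more effective -> Dominant
  t2 <- icer_table(list(ref, mk("rituximab", 80, 12)), "bsc")
  expect_identical(t2$icer_qaly_label[2], "Dominant")
  expect_true(is.na(t2$icer_qaly[2]))
  ## costlier & less effective -> Dominated
  t3 <- icer_table(list(ref, mk("rituximab", 150, 8)), "bsc")
  expect_identical(t3$icer_qaly_label[2], "Dominated")
  ## cheaper & less effective -> ratio (south-west quadrant)
  t4 <- icer_table(list(ref, mk("rituximab", 80, 8)), "bsc")
  expect_equal(t4$icer_qaly[2], 10)
  ## identical results -> undefined but unlabelled
  t5 <- icer_table(list(ref, mk("rituximab", 100, 10)), "bsc")
  expect_true(is.na(t5$icer_qaly[2]))
  expect_identical(t5$icer_qaly_label[2], "")
  ## zero effect difference with cost difference -> flagged undefined
  t6 <- icer_table(list(ref, mk("rituximab", 150, 10)), "bsc")
  expect_identical(t6$icer_qaly_label[2], "Undefined")
})

test_that("QALYs never exceed the best-utility bound", {
  m <- rrms_cua(short_params())
  for (r in m$results)
    expect_lte(r$total_qaly, 0.600 * r$total_ly + 1e-12)
})
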