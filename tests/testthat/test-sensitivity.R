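test_that("net monetary benefit has the defining algebraic behaviour", {
  expect_identical(nmb(5000, 2, 0), -5000)
  expect_identical(nmb(160000, 1, 160000), 0)
  expect_error(nmb(1, 1, -5), "negative")

  ## the incremental NMB of two strategies changes sign exactly at the ICER
  m <- rrms_cua(short_params())
  r <- m$results$rituximab; ref <- m$results$bsc
  icer <- (r$total_cost - ref$total_cost) / (r$total_qaly - ref$total_qaly)
  dn <- function(w) nmb(r$total_cost, r$total_qaly, w) -
    nmb(ref$total_cost, ref$total_qaly, w)
  expect_lt(dn(icer * 0.99), 0)
  expect_gt(dn(icer * 1.01), 0)
  expect_equal(dn(icer), 0, tolerance = 1e-6)
})

test_that("one-way sensitivity analysis ranks and bounds correctly", {
  p <- rrms_parameters()
  tor <- owsa(p)
  expect_s3_class(tor, "rrms_owsa")
  ## sorted by decreasing spread
  expect_true(all(diff(tor$spread) <= 1e-9))
  ## drug cost varied +/- 20% of base case
  row <- tor[tor$parameter == "c_biosimilar_month", ]
  expect_equal(row$low_input, 0.8 * 2967)
  expect_equal(row$high_input, 1.2 * 2967)
  ## the untreated relapse probability is among the most influential inputs
  expect_true("p_relapse" %in% tor$parameter[1:2])
  ## a parameter entering neither compared strategy is inert
  expect_equal(tor$spread[tor$parameter == "c_rituximab_month"], 0)
  ## base-case outcome lies within the bound outcomes for the top parameter
  top <- tor[1, ]
  expect_true(attr(tor, "base_outcome") >= min(top$outcome_low, top$outcome_high) &&
              attr(tor, "base_outcome") <= max(top$outcome_low, top$outcome_high))
  expect_error(owsa(p, target_params = "nope"), "unknown")
})

test_that("probabilistic draws are reproducible and honour distributions", {
  p <- rrms_parameters()
  d1 <- sample_psa(p, 50, seed = 99)
  d2 <- sample_psa(p, 50, seed = 99)
  expect_identical(d1, d2)
  d3 <- sample_psa(p, 50, seed = 100)
  expect_false(identical(d1, d3))
  ## fixed parameters never vary
  expect_true(all(d1$p_death_edss6 == 0.0013))
  ## supports respected
  probs <- grep("^(p_|u_|relapse_effect)", names(d1), value = TRUE)
  expect_true(all(d1[probs] >= 0 & d1[probs] <= 1))
  expect_true(all(d1[grep("^c_", names(d1))] > 0))

  ## degenerate sampling: all-fixed parameter set reproduces the base case
  pf <- all_fixed_params(p)
  df <- sample_psa(pf, 5, seed = 1)
  expect_true(all(vapply(names(df), function(nm)
    all(df[[nm]] == p$specs[[nm]]$mean), logical(1))))

  ## law of large numbers on the relapse probability
  big <- sample_psa(p, 100000, seed = 3)
  expect_lt(abs(mean(big$p_relapse) - 0.0755), 3 * 0.0755 / sqrt(100000))

  ## parameter-set form carries the draws into the specs
  ps <- sample_psa(p, 50, seed = 99, as = "parameters")
  expect_length(ps, 50)
  expect_equal(ps[[2]]$specs$p_relapse$mean, d1$p_relapse[2])
})

test_that("acceptability curves are normalised, reproducible and sensible", {
  p <- short_params()
  psa <- run_psa(p, n_draws = 200, seed = 7)
  psa2 <- run_psa(p, n_draws = 200, seed = 7)
  expect_identical(psa, psa2)   # bit-identical under a fixed seed

  grid <- seq(0, 500000, by = 50000)
  cc <- ceac(psa, grid)
  expect_identical(cc$wtp, grid)
  probs <- as.matrix(cc[setdiff(names(cc), "wtp")])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(cc)), tolerance = 1e-12)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_identical(ceac(psa, grid), cc)

  ## single draw gives an indicator curve
  one <- ceac(psa[psa$draw == 1, ], c(0, 160000))
  expect_true(all(as.matrix(one[, -1]) %in% c(0, 1)))

  ## at WTP 0 the cheapest strategy per draw wins
  cc0 <- ceac(psa, 0)
  cheapest <- tapply(seq_len(nrow(psa)), psa$draw, function(i)
    psa$strategy[i][which.min(psa$cost[i])])
  expect_equal(unname(unlist(cc0[1, names(table(cheapest))])),
               unname(as.vector(table(cheapest) / 200)))

  ## the biosimilar curve trends upward with WTP (it gains QALYs and, in most
  ## draws, saves cost); allow Monte-Carlo wiggle
  expect_true(all(diff(cc$biosimilar) >= -0.05))
  expect_gte(cc$biosimilar[nrow(cc)], cc$biosimilar[1])
})

test_that("PSA means converge to the base case where the model is linear", {
  ## Costs and utilities enter accrual linearly: holding transitions fixed,
  ## the PSA mean must match the deterministic result within Monte-Carlo
  ## error. Transition probabilities enter nonlinearly (matrix powers), so
  ## the full PSA mean carries a genuine convexity bias, bounded below.
  p <- short_params()
  pl <- all_fixed_params(p)
  for (nm in grep("^(c_|u_)", names(pl$specs), value = TRUE)) {
    pl$specs[[nm]] <- p$specs[[nm]]        # only costs/utilities vary
  }
  psa <- run_psa(pl, n_draws = 400, seed = 21, strategies_run = c("bsc", "biosimilar"))
  m <- rrms_cua(pl, strategies_run = c("bsc", "biosimilar"))
  for (s in c("bsc", "biosimilar")) {
    d <- psa[psa$strategy == s, ]
    expect_lt(abs(mean(d$cost) - m$results[[s]]$total_cost),
              3 * stats::sd(d$cost) / sqrt(nrow(d)))
    expect_lt(abs(mean(d$qaly) - m$results[[s]]$total_qaly),
              3 * stats::sd(d$qaly) / sqrt(nrow(d)))
  }

  ## full sampling: document the convexity bias rather than pretend it away --
  ## means stay within 10% of the deterministic base case
  psa_full <- run_psa(p, n_draws = 400, seed = 22, strategies_run = c("bsc", "biosimilar"))
  mfull <- rrms_cua(p, strategies_run = c("bsc", "biosimilar"))
  for (s in c("bsc", "biosimilar")) {
    d <- psa_full[psa_full$strategy == s, ]
    expect_lt(abs(mean(d$cost) / mfull$results[[s]]$total_cost - 1), 0.10)
    expect_lt(abs(mean(d$qaly) / mfull$results[[s]]$total_qaly - 1), 0.10)
  }
})
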