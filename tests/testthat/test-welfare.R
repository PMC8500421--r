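test_that("CRRA utility, shadow value, and their special cases", {
  expect_equal(crra_utility(1000, 2), -0.001)
  expect_equal(crra_utility(7, 0), 7)
  expect_equal(crra_utility(1, 1), 0)
  expect_error(crra_utility(0, 2), "positive wealth")
  expect_error(crra_utility(c(1, -3), 2), "state\\(s\\) 2")

  expect_equal(shadow_value(1, 3.7), 1)
  expect_equal(shadow_value(0.5, 2) / shadow_value(1, 2), 4)
  expect_equal(shadow_value(c(2, 9), 0), c(1, 1))
})

test_that("expected utility weights states and certainty equivalent inverts", {
  expect_equal(expected_utility(c(1, 0.5), 2, c(0.5, 0.5)), -1.5)
  expect_equal(expected_utility(3, 2), crra_utility(3, 2))
  expect_equal(expected_utility(c(2, 4), 0), 3)
  expect_error(expected_utility(c(1, 2), 2, c(0.7, 0.7)), "sum to 1")

  expect_equal(certainty_equivalent(-1.5, 2), 2 / 3)
  expect_equal(certainty_equivalent(5, 0), 5)
  for (rho in c(0, 0.5, 1, 2, 3)) {
    k <- 0.87
    expect_equal(certainty_equivalent(crra_utility(k, rho), rho), k,
                 tolerance = 1e-10)
  }
  expect_error(certainty_equivalent(1.5, 2), "outside the attainable")
})

test_that("certainty equivalent obeys Jensen and homotheticity", {
  set.seed(12)
  k <- stats::runif(50, 0.3, 1.2)
  expect_equal(certainty_equivalent(expected_utility(k, 0), 0), mean(k))
  for (rho in c(0.5, 1, 2)) {
    ce <- certainty_equivalent(expected_utility(k, rho), rho)
    expect_lt(ce, mean(k))
    ce_scaled <- certainty_equivalent(expected_utility(1000 * k, rho), rho)
    expect_equal(ce_scaled, 1000 * ce, tolerance = 1e-10)
  }
})

test_that("insurance benefit and RIB sign conventions", {
  expect_equal(insurance_benefit(-1.2, -1.2), 0)
  expect_equal(rib(0.5, 1), 0.5)
  expect_equal(rib(0, 2), 0)
  expect_error(rib(0.5, 0), "RIB undefined")
  expect_error(rib(0.5, -1), "RIB undefined")
})

test_that("payout classification follows the shortfall rule exhaustively", {
  t <- contract_terms()  # insured value $1000
  expect_equal(as.character(classify_payouts(0, 0, t)), "TN")
  expect_equal(as.character(classify_payouts(250, 50, t)),
               "FN_intermediate")  # s = 0.20
  expect_equal(as.character(classify_payouts(0, 80, t)), "FP")
  expect_equal(as.character(classify_payouts(100, 100, t)), "FN_small")
  expect_equal(as.character(classify_payouts(400, 50, t)), "FN_severe")
  expect_equal(as.character(classify_payouts(150, 60, t)), "FN_small")

  set.seed(13)
  ip <- stats::runif(200, 0, 500) * stats::rbinom(200, 1, 0.5)
  ij <- stats::runif(200, 0, 500) * stats::rbinom(200, 1, 0.5)
  cls <- classify_payouts(ip, ij, t)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), 200L)  # partition: every record in one class
})

test_that("a perfect index has RIB exactly 1; a dead contract exactly 0", {
  d <- simulate_seasons(scenario_config(seed = 7))
  ev <- evaluate_contract(d, predictions = d$mortality)
  expect_identical(ev$welfare$RIB, 1)
  expect_gt(ev$welfare$IBhat_P, 0)

  # constant prediction below the trigger: no payouts, no premium, RIB 0
  ev0 <- evaluate_contract(d, predictions = rep(0.1, nrow(d)))
  expect_equal(ev0$pricing$premium_index, 0)
  expect_equal(ev0$welfare$RIB, 0)
})

test_that("an anti-correlated index harms the insured (RIB < 0)", {
  d <- simulate_seasons(scenario_config(seed = 21))
  # pay out most when losses are smallest
  anti <- sort(d$mortality, decreasing = TRUE)[rank(d$mortality,
                                                    ties.method = "first")]
  ev <- evaluate_contract(d, predictions = anti)
  expect_lt(ev$welfare$RIB, 0)
})

test_that("RIB is invariant to the currency scale of the insured unit", {
  d <- simulate_seasons(scenario_config(seed = 3))
  d <- zscore_index(d, "ndvi")
  f <- loss_model(mortality ~ z_ndvi, d, kind = "sm")
  r1 <- evaluate_contract(d, model = f,
                          terms = contract_terms(tlu_value = 1000))
  r2 <- evaluate_contract(d, model = f,
                          terms = contract_terms(tlu_value = 1e6))
  expect_equal(r1$welfare$RIB, r2$welfare$RIB, tolerance = 1e-10)
  expect_equal(r2$welfare$CE_N, 1000 * r1$welfare$CE_N, tolerance = 1e-9)
})

test_that("risk-neutral fair insurance is welfare neutral", {
  d <- simulate_seasons(scenario_config(seed = 5))
  ev <- evaluate_contract(d, predictions = d$mortality,
                          terms = contract_terms(markup = 0), rho = 0)
  expect_lt(abs(ev$welfare$IB_P), 1e-12)
})

test_that("the Taylor decomposition converges quadratically in scale", {
  d <- simulate_seasons(scenario_config(seed = 9))
  ev <- evaluate_contract(d, predictions = d$mortality)
  scale_eval <- function(ev, s) {
    ev$records$wealth_j <- ev$records$wealth_n +
      s * (ev$records$wealth_j - ev$records$wealth_n)
    ev$records$delta <- s * ev$records$delta
    ev
  }
  dec1 <- decompose_ib(scale_eval(ev, 0.01))
  dec2 <- decompose_ib(scale_eval(ev, 0.005))
  expect_lt(abs(dec1$approx_error) / abs(dec1$exact_ib), 0.05)
  # absolute error is O(scale^2): halving the scale quarters it
  expect_lte(abs(dec2$approx_error), 0.35 * abs(dec1$approx_error))

  # zero-transfer contract decomposes to exactly zero
  ev0 <- evaluate_contract(d, predictions = rep(0, nrow(d)))
  dec0 <- decompose_ib(ev0)
  expect_equal(dec0$total, 0)
  # per-state contributions are Delta * lambda * weight by construction
  dec <- decompose_ib(ev)
  expect_equal(dec$rows$contribution,
               dec$rows$delta * dec$rows$lambda * dec$rows$weight)
})

test_that("wealth guard rejects ruinous states unless floored", {
  d <- simulate_seasons(scenario_config(seed = 2))
  d$mortality[1] <- 1  # total herd loss: zero uninsured wealth
  expect_error(evaluate_contract(d, predictions = d$mortality),
               "positive wealth")
  ev <- evaluate_contract(d, predictions = d$mortality, wealth_floor = 10)
  expect_true(is.finite(ev$welfare$RIB))
})

test_that("RIB is stable across risk aversion including the log branch", {
  d <- simulate_seasons(scenario_config(seed = 4))
  d <- zscore_index(d, "ndvi")
  f <- loss_model(mortality ~ z_ndvi, d, kind = "sm")
  sw <- rho_sweep(d, model = f, rho_grid = c(0, 0.5, 0.999, 1, 1.001, 2, 3))
  expect_equal(nrow(sw), 7L)
  # rho = 0 with a markup: insurance is a pure cost, RIB undefined
  expect_true(is.na(sw$RIB[sw$rho == 0]))
  expect_lt(sw$IB_P[sw$rho == 0], 0)
  # no discontinuity at the log-utility branch: the rho = 1 value sits
  # between its close neighbours
  r <- sw$RIB[match(c(0.999, 1, 1.001), sw$rho)]
  expect_true(r[2] >= min(r[c(1, 3)]) - 1e-6 &&
                r[2] <= max(r[c(1, 3)]) + 1e-6)

  # the perfect contract scores 1 wherever perfect insurance helps
  swp <- rho_sweep(d, predictions = d$mortality,
                   rho_grid = c(0.5, 1, 2, 3))
  defined <- !is.na(swp$RIB)
  expect_true(all(swp$RIB[defined] == 1))
  expect_true(all(defined[swp$rho >= 1]))
})
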