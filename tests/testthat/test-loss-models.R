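test_that("linear fit recovers exact lines and matches closed-form OLS", {
  z <- c(-2, -1, 0, 1, 2)
  d <- data.frame(z = z, mortality = 0.2 - 0.1 * z)
  f <- loss_model(mortality ~ z, d, kind = "lm")
  expect_equal(unname(coef(f)), c(0.2, -0.1), tolerance = 1e-12)
  expect_lt(f$sse, 1e-24)

  expect_error(loss_model(mortality ~ z,
                          data.frame(z = rep(1, 5), mortality = 1:5 / 10),
                          kind = "lm"),
               "constant")

  set.seed(42)
  z <- stats::rnorm(240)
  d <- data.frame(z = z,
                  mortality = pmin(pmax(
                    0.2 - 0.08 * z + stats::rnorm(240, 0, 0.05), 0), 1))
  f <- loss_model(mortality ~ z, d, kind = "lm")
  orc <- oracle_ols(d$z, d$mortality)
  expect_equal(coef(f), orc, tolerance = 1e-10)
  expect_lt(abs(coef(f)[["slope"]] - (-0.08)), 0.02)
})

test_that("cutoff-restricted fits equal OLS on the subset", {
  set.seed(7)
  z <- stats::rnorm(50) - 2       # all below zero cutoff
  d <- data.frame(z = z, mortality = pmin(pmax(0.3 - 0.12 * z, 0), 1))
  f0 <- loss_model(mortality ~ z, d, kind = "lm0")
  expect_equal(coef(f0), coef(loss_model(mortality ~ z, d, kind = "lm")))

  # exact recovery on the z < -0.5 subset
  set.seed(8)
  z <- stats::rnorm(80)
  M <- ifelse(z < -0.5, 0.3 - 0.12 * z, stats::runif(80, 0, 0.1))
  d <- data.frame(z = z, mortality = M)
  f5 <- loss_model(mortality ~ z, d, kind = "lm5")
  expect_equal(unname(coef(f5)), c(0.3, -0.12), tolerance = 1e-12)
  expect_equal(f5$n_fit, sum(z < -0.5))

  # cutoff below the data: error that reports the count
  expect_error(loss_model(mortality ~ z, d, kind = "lm",
                          cutoff = min(z) - 1),
               "only 0 observation")

  # an infinite cutoff is an unrestricted fit
  expect_equal(coef(loss_model(mortality ~ z, d, kind = "lm",
                               cutoff = Inf)),
               coef(loss_model(mortality ~ z, d, kind = "lm")))
})

test_that("segmented fit recovers a noiseless hinge exactly", {
  d <- make_hinge_data(n = 80, psi = -1, b0 = 0.1, slope = 0.25, seed = 3)
  f <- loss_model(mortality ~ z, d, kind = "sm")
  expect_lt(abs(f$psi - (-1)), 1e-6)
  expect_equal(coef(f)[["slope"]], -0.25, tolerance = 1e-5)
  expect_equal(coef(f)[["slope_change"]], 0.25, tolerance = 1e-5)
  expect_lt(f$sse, 1e-10)
})

test_that("segmented model nests the linear model", {
  # exactly linear data: no SSE improvement, no slope change
  set.seed(9)
  z <- stats::rnorm(40)
  d <- data.frame(z = z, mortality = pmin(pmax(0.2 - 0.05 * z, 0), 1))
  fsm <- loss_model(mortality ~ z, d, kind = "sm")
  flm <- loss_model(mortality ~ z, d, kind = "lm")
  expect_lt(fsm$sse, flm$sse + 1e-9)
  expect_lt(abs(coef(fsm)[["slope_change"]]), 1e-6)

  # property: SSE(sm) <= SSE(lm) on noisy data too
  for (s in 1:5) {
    d <- make_hinge_data(n = 60, noise_sd = 0.05, seed = s)
    fsm <- loss_model(mortality ~ z, d, kind = "sm")
    flm <- loss_model(mortality ~ z, d, kind = "lm")
    expect_lt(fsm$sse, flm$sse + 1e-9)
  }
})

test_that("segmented fit agrees with the exhaustive grid oracle", {
  for (s in 1:5) {
    d <- make_hinge_data(n = 120, noise_sd = 0.05, seed = s)
    f <- loss_model(mortality ~ z, d, kind = "sm")
    orc <- oracle_seg_grid(d$z, d$mortality)
    # the package refines beyond the grid, so it can only do better
    expect_lte(f$sse, orc$sse + 1e-9)
    # and the refined breakpoint stays within one grid cell of the oracle
    spacing <- diff(sort(unique(d$z)))
    expect_lte(abs(f$psi - orc$psi), max(spacing))
  }
})

test_that("quantile fit reaches the vertex optimum and balances residuals", {
  # exact line: optimal for any tau with zero objective
  z <- seq(-2, 2, length.out = 20)
  d <- data.frame(z = z, mortality = pmin(pmax(0.3 - 0.1 * z, 0), 1))
  f <- loss_model(mortality ~ z, d, kind = "qr", tau = 0.77)
  expect_lt(f$objective, 1e-10)
  expect_equal(unname(coef(f)), c(0.3, -0.1), tolerance = 1e-6)

  for (s in 1:5) {
    set.seed(s)
    n <- 40
    z <- stats::rnorm(n)
    M <- pmin(pmax(0.2 - 0.08 * z + stats::rnorm(n, 0, 0.05), 0), 1)
    d <- data.frame(z = z, mortality = M)
    for (tau in c(0.5, 0.77)) {
      f <- loss_model(mortality ~ z, d, kind = "qr", tau = tau)
      orc <- oracle_qr_vertex(z, M, tau)
      expect_lt(abs(f$objective - orc$obj), 1e-8)
      frac_below <- mean(M < predict(f, d, clip = FALSE))
      expect_lte(abs(frac_below - tau), 2 / n)
    }
  }
})

test_that("one-sided positive outliers raise the upper-quantile intercept", {
  set.seed(10)
  n <- 100
  z <- stats::rnorm(n)
  M <- pmin(pmax(0.15 - 0.05 * z + stats::rnorm(n, 0, 0.02), 0), 1)
  M[1:30] <- pmin(M[1:30] + stats::runif(30, 0.2, 0.4), 1)  # disease years
  d <- data.frame(z = z, mortality = M)
  fq <- loss_model(mortality ~ z, d, kind = "qr", tau = 0.77)
  fl <- loss_model(mortality ~ z, d, kind = "lm")
  expect_gt(coef(fq)[["intercept"]], coef(fl)[["intercept"]])
})

test_that("predictions are the piecewise response clipped to [0, 1]", {
  d <- make_hinge_data(n = 40, seed = 2)
  f <- loss_model(mortality ~ z, d, kind = "sm")
  # plug-in on a hand-built model: flat above the break
  f$coefficients <- c(intercept = 0.1, slope = -0.25, slope_change = 0.25)
  f$psi <- -1
  expect_equal(predict(f, 0), 0.35)
  expect_equal(predict(f, -1), 0.1 + 0.25)
  expect_equal(predict(f, -10), 1)            # deep drought: clipped high
  f$coefficients["intercept"] <- -0.5
  expect_equal(predict(f, -0.9), 0)           # clipped low
  expect_true(all(predict(f, seq(-50, 50, by = 0.5)) >= 0 &
                  predict(f, seq(-50, 50, by = 0.5)) <= 1))
})

test_that("goodness of fit matches hand-computed R2 and RMSE", {
  z <- c(-2, -1, 0, 1)
  d <- data.frame(z = z, mortality = 0.2 - 0.1 * z)
  f <- loss_model(mortality ~ z, d, kind = "lm")
  g <- goodness_of_fit(f, d)
  expect_equal(g$r_squared, 1)
  expect_equal(g$rmse, 0)

  # hand arithmetic on a 4-point toy set with a fixed (not refit) line
  f$coefficients <- c(intercept = 0.2, slope = -0.1)
  d2 <- data.frame(z = c(-1, 0, 1, 2), mortality = c(0.35, 0.15, 0.1, 0.05))
  pred <- 0.2 - 0.1 * d2$z                 # 0.30 0.20 0.10 0.00
  sse <- sum((d2$mortality - pred)^2)      # 0.0025+0.0025+0+0.0025
  sst <- sum((d2$mortality - mean(d2$mortality))^2)
  g2 <- goodness_of_fit(f, d2)
  expect_equal(g2$r_squared, 1 - sse / sst)
  expect_equal(g2$rmse, sqrt(sse / 4))

  d3 <- data.frame(z = 1:4, mortality = rep(0.2, 4))
  expect_error(goodness_of_fit(f, d3), "SST = 0")
})
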