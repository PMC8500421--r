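test_that("the sweep covers the factorial and flags a perfect index", {
  d <- simulate_seasons(scenario_config(seed = 1))
  d$rain <- d$ndvi * 0.8 + 0.1  # affine twin: same z-scores
  sw <- rib_sweep(d, indices = c("ndvi", "rain"), kinds = c("lm", "sm"))
  expect_s3_class(sw, "rib_sweep")
  expect_equal(nrow(sw), 4L)
  expect_true(all(is.na(sw$error)))
  # affine-equivalent indices give identical results kind by kind
  a <- sw[sw$index == "ndvi", ]; a <- a[order(a$kind), ]
  b <- sw[sw$index == "rain", ]; b <- b[order(b$kind), ]
  expect_equal(a$RIB, b$RIB, tolerance = 1e-9)

  # an index equal to observed mortality yields a perfect contract
  d$oracle <- d$mortality
  sw2 <- rib_sweep(d, indices = "oracle", kinds = "lm",
                   standardize = FALSE)
  expect_equal(sw2$RIB[1], 1, tolerance = 1e-9)
})

test_that("sweeps are order independent and record per-row failures", {
  d <- simulate_seasons(scenario_config(seed = 2))
  sw1 <- rib_sweep(d, indices = "ndvi", kinds = c("lm", "sm", "qr"))
  perm <- sample(nrow(d))
  sw2 <- rib_sweep(d[perm, ], indices = "ndvi",
                   kinds = c("lm", "sm", "qr"))
  o1 <- sw1[order(sw1$kind), ]; o2 <- sw2[order(sw2$kind), ]
  expect_equal(o1$RIB, o2$RIB, tolerance = 1e-6)
  expect_equal(o1$r_squared, o2$r_squared, tolerance = 1e-6)

  # a constant column cannot be standardized: recorded, not fatal
  d$flat <- 1
  sw3 <- rib_sweep(d, indices = c("ndvi", "flat"), kinds = "lm")
  expect_true(any(!is.na(sw3$error)))
  expect_true(any(is.na(sw3$error)))
})

test_that("R-squared and RIB are correlated but rank differently", {
  d <- simulate_matched_indices(scenario_config(seed = 3))
  d$z_clean <- attr(d, "latent_z")
  sw <- rib_sweep(d, indices = c("z_clean", "z_noisy_high", "z_noisy_low"),
                  kinds = c("lm", "lm0", "lm5", "sm"),
                  standardize = FALSE)
  ok <- !is.na(sw$RIB)
  expect_gte(sum(ok), 10)
  expect_gt(stats::cor(sw$r_squared[ok], sw$RIB[ok], method = "spearman"),
            0)
  # at least one pair is ranked differently by the two criteria
  disc <- outer(sw$r_squared[ok], sw$r_squared[ok], ">") &
    outer(sw$RIB[ok], sw$RIB[ok], "<")
  expect_true(any(disc))
})

test_that("cross-validation is seeded, pools every record, and is honest", {
  # noiseless data linear in the latent anomaly: out-of-fold fit is
  # essentially perfect
  d <- simulate_seasons(scenario_config(noise_sd = 0, shock_prob = 0,
                                        base_mortality = 0.3,
                                        slope_below = 0.05,
                                        slope_above = -0.05, seed = 30))
  d$z <- attr(d, "latent_z")  # mortality = 0.25 - 0.05 z exactly
  cv <- kfold_cv(d, index = "z", kind = "lm", k = 5, seed = 99,
                 standardize = FALSE)
  expect_gt(cv$r_squared, 0.999)
  cv2 <- kfold_cv(d, index = "z", kind = "lm", k = 5, seed = 99,
                  standardize = FALSE)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$RIB, cv2$RIB)
  expect_false(anyNA(cv$predictions))
  expect_equal(sort(unique(cv$folds)), 1:5)

  # leave-one-out pools n predictions
  d30 <- d[1:30, ]
  loo <- kfold_cv(d30, index = "z", kind = "lm", k = 30, seed = 1,
                  standardize = FALSE)
  expect_equal(length(loo$predictions), 30L)
  expect_false(anyNA(loo$predictions))
})

test_that("location-blocked folds keep blocks intact", {
  d <- simulate_seasons(scenario_config(seed = 6))
  cv <- kfold_cv(d, index = "ndvi", kind = "lm", k = 5, seed = 2,
                 block_by = "location")
  split_ok <- tapply(cv$folds, d$location,
                     function(f) length(unique(f)) == 1L)
  expect_true(all(split_ok))
})
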