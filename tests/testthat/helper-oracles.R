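# Independent oracles used to verify the fitting code.  These deliberately
# avoid the package's own code paths: closed-form OLS, an exhaustive grid
# search for the segmented breakpoint, and an exhaustive vertex search for
# the quantile fit.

# closed-form simple OLS: slope = cov(z, M) / var(z)
oracle_ols <- function(z, M) {
  b1 <- sum((z - mean(z)) * (M - mean(M))) / sum((z - mean(z))^2)
  b0 <- mean(M) - b1 * mean(z)
  c(intercept = b0, slope = b1)
}

# exhaustive breakpoint grid: every observed z value with >= min_seg points
# on each side, plain lm() per candidate
oracle_seg_grid <- function(z, M, min_seg = 3L) {
  cand <- sort(unique(z))
  cand <- cand[vapply(cand, function(p) {
    sum(z <= p) >= min_seg && sum(z > p) >= min_seg
  }, logical(1))]
  best <- list(sse = Inf, psi = NA_real_)
  for (p in cand) {
    hinge <- pmax(z - p, 0)
    f <- stats::lm(M ~ z + hinge)
    sse <- sum(stats::resid(f)^2)
    if (sse < best$sse) best <- list(sse = sse, psi = p)
  }
  best
}

# exhaustive vertex search: the optimal tau-quantile line interpolates two
# observations; enumerate all pairs
oracle_qr_vertex <- function(z, M, tau) {
  n <- length(z)
  check <- function(u) sum(u * (tau - (u < 0)))
  best <- list(obj = Inf, b = c(NA, NA))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (z[i] == z[j]) next
      s <- (M[i] - M[j]) / (z[i] - z[j])
      b0 <- M[i] - s * z[i]
      o <- check(M - b0 - s * z)
      if (o < best$obj) best <- list(obj = o, b = c(b0, s))
    }
  }
  best
}

# hinge-response season data on a known latent z (noise-free unless stated)
make_hinge_data <- function(n = 60, psi = -1, b0 = 0.1, slope = 0.25,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  M <- b0 + slope * pmax(psi - z, 0) + stats::rnorm(n, 0, noise_sd)
  data.frame(z = z, mortality = pmin(pmax(M, 0), 1))
}

# minimal season table for io / zscore tests
make_season_df <- function(values, location = "a",
                           season = rep(c("LRLD", "SRSD"),
                                        length.out = length(values))) {
  data.frame(location = location,
             year = 2008L + (seq_along(values) - 1L) %/% 2L,
             season = season,
             mortality = 0.1,
             idx = values,
             stringsAsFactors = FALSE)
}
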