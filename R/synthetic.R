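#' Configure a synthetic mortality/index scenario
#'
#' Defines the study conditions emulated by [simulate_seasons()]: a
#' sub-location by season survey panel (default 15 locations, 8 years,
#' two herding seasons per year, i.e. 240 location-seasons) in which mean
#' mortality responds piecewise-linearly to a latent standardized forage
#' index — declining as the index falls below a breakpoint near
#' `z = -1`, essentially flat above it — plus additive observation noise
#' and occasional index-independent disease shocks.  The defaults target
#' the marginal features of the Marsabit-style survey setting: overall
#' mean mortality about 13%, and a perfect contract at trigger 0.23
#' paying out roughly 2% of insured value per season.
#'
#' @param n_locations Number of sub-locations (default 15).
#' @param years Number of survey years (default 8, labelled 2008 onward).
#' @param seasons Season labels within a year (default LRLD, SRSD).
#' @param psi True breakpoint of the mortality response (z units,
#'   default -1).
#' @param slope_below Mortality increase per z unit of forage deficit
#'   below the breakpoint (default 0.25).
#' @param slope_above Slope above the breakpoint (default 0: no forage
#'   effect in normal-to-good seasons).
#' @param base_mortality Mortality in good seasons (default 0.10).
#' @param noise_sd Standard deviation of additive mortality noise
#'   (default 0.05).
#' @param noise_placement `"homoskedastic"` (default), or
#'   `"high_mortality_heavy"` / `"low_mortality_heavy"` to concentrate
#'   the noise in bad or good states (noise sd doubled in the targeted
#'   quartile, halved elsewhere).
#' @param shock_prob Probability per location-season of a
#'   forage-independent mortality shock, e.g. disease (default 0.03).
#' @param shock_range Uniform range of the shock magnitude (default
#'   0.2-0.4).
#' @param mortality_cap Upper clip for simulated mortality (default
#'   0.95; total herd loss is not observed in survey data and would give
#'   zero wealth, outside the CRRA domain).
#' @param index_name Name of the raw index column (default `"ndvi"`).
#' @param seed Integer seed; fully determines the output.
#' @return A validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_locations = 15L, years = 8L,
                            seasons = c("LRLD", "SRSD"),
                            psi = -1, slope_below = 0.25,
                            slope_above = 0, base_mortality = 0.10,
                            noise_sd = 0.05,
                            noise_placement = c("homoskedastic",
                                                "high_mortality_heavy",
                                                "low_mortality_heavy"),
                            shock_prob = 0.03,
                            shock_range = c(0.2, 0.4),
                            mortality_cap = 0.95,
                            index_name = "ndvi", seed = 42L) {
  noise_placement <- match.arg(noise_placement)
  if (n_locations < 1L || years < 1L) stop("need >= 1 location and year")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (shock_prob < 0 || shock_prob > 1) stop("shock_prob must be in [0,1]")
  if (mortality_cap <= 0 || mortality_cap > 1) {
    stop("mortality_cap must be in (0, 1]")
  }
  if (base_mortality < 0 || base_mortality > 1) {
    stop("base_mortality must be in [0, 1]")
  }
  structure(list(n_locations = as.integer(n_locations),
                 years = as.integer(years), seasons = seasons, psi = psi,
                 slope_below = slope_below, slope_above = slope_above,
                 base_mortality = base_mortality, noise_sd = noise_sd,
                 noise_placement = noise_placement,
                 shock_prob = shock_prob, shock_range = shock_range,
                 mortality_cap = mortality_cap, index_name = index_name,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a panel of location-season mortality and index observations
#'
#' Draws a latent standard-normal forage anomaly `z` per location-season,
#' maps it to mean mortality through the piecewise-linear (hinge)
#' response of the scenario, adds placement-dependent noise and
#' occasional disease shocks, clips mortality to the admissible range,
#' and constructs a raw index observation per location as
#' `mu_l + sigma_l * z` with location-specific level and spread (so the
#' standardization step has real work to do).
#'
#' @param config A [scenario_config()].
#' @return A season table (`data.frame` with `location`, `year`,
#'   `season`, `mortality`, and the raw index column).  The latent
#'   anomaly is attached as attribute `"latent_z"` and the generating
#'   configuration as `"config"`.
#' @export
simulate_seasons <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  locs <- sprintf("loc%02d", seq_len(config$n_locations))
  grid <- expand.grid(season = config$seasons,
                      year = 2008L + seq_len(config$years) - 1L,
                      location = locs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("location", "year", "season")]
  n <- nrow(grid)
  z <- stats::rnorm(n)
  mu <- .hinge_mortality(z, config)
  sd_i <- rep(config$noise_sd, n)
  if (config$noise_placement != "homoskedastic" && config$noise_sd > 0) {
    hi <- mu >= stats::quantile(mu, 0.75)
    target <- if (config$noise_placement == "high_mortality_heavy") hi else
      mu <= stats::quantile(mu, 0.25)
    sd_i <- ifelse(target, 2 * config$noise_sd, 0.5 * config$noise_sd)
  }
  noise <- stats::rnorm(n, 0, sd_i)
  shock <- stats::rbinom(n, 1L, config$shock_prob) *
    stats::runif(n, config$shock_range[1L], config$shock_range[2L])
  mortality <- pmin(pmax(mu + noise + shock, 0), config$mortality_cap)
  mu_l <- stats::runif(config$n_locations, 0.35, 0.60)
  sd_l <- stats::runif(config$n_locations, 0.04, 0.08)
  li <- match(grid$location, locs)
  raw <- mu_l[li] + sd_l[li] * z
  out <- data.frame(grid, mortality = mortality,
                    stringsAsFactors = FALSE)
  out[[config$index_name]] <- raw
  attr(out, "latent_z") <- z
  attr(out, "config") <- config
  out
}

.hinge_mortality <- function(z, config) {
  config$base_mortality +
    config$slope_below * pmax(config$psi - z, 0) +
    config$slope_above * pmax(z - config$psi, 0)
}

#' Simulate two indices with matched predictive skill but different error
#' placement
#'
#' Generates a shared mortality series driven by a latent forage anomaly,
#' then two candidate index columns with (essentially) the same
#' segmented-model R-squared but opposite placement of their measurement
#' error:
#'
#' * `z_noisy_high` fails exactly in the high-mortality quartile — its
#'   index values there are shifted upward (the drought goes undetected),
#'   producing severe false negatives in the seasons that matter most;
#' * `z_noisy_low` fails in the low-mortality quartile — its index values
#'   there are shifted downward (bounded below at `z_floor`, a plausible
#'   but spurious drought reading), producing overpayments and scatter in
#'   seasons when losses are small.
#'
#' Both error fields are built from the same half-normal draws, i.e. the
#' error mass is reallocated between states rather than redrawn; the
#' magnitude of the high-mortality misses is then calibrated (by root
#' finding on the segmented-model R-squared) so the two indices match in
#' conventional goodness of fit.  If no calibration matches within
#' `r2_tol`, the low-side damage is attenuated and the noise redrawn, up
#' to `max_tries` attempts.
#'
#' @param config A [scenario_config()]; the mortality side uses its
#'   hinge response with a small homoskedastic noise floor (sd 0.03) and
#'   no disease shocks.
#' @param r2_tol Maximum allowed difference in segmented-model R-squared
#'   between the two indices (default 0.03).
#' @param max_tries Bounded number of redraw/attenuation attempts before
#'   failing (default 60).
#' @param error_scale Scale of the low-mortality index damage (default
#'   1.5; `0` gives two identical, error-free indices).
#' @param z_floor Lower bound of the spurious drought readings (default
#'   -2 z units).
#' @return A season table with `mortality`, `z_noisy_high`, and
#'   `z_noisy_low` columns (already standardized).  The achieved
#'   R-squared pair is attached as attribute `"r2"`.
#' @export
simulate_matched_indices <- function(config = scenario_config(),
                                     r2_tol = 0.03, max_tries = 60L,
                                     error_scale = 1.5, z_floor = -2) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  locs <- sprintf("loc%02d", seq_len(config$n_locations))
  grid <- expand.grid(season = config$seasons,
                      year = 2008L + seq_len(config$years) - 1L,
                      location = locs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("location", "year", "season")]
  n <- nrow(grid)
  z <- stats::rnorm(n)
  mu <- .hinge_mortality(z, config)
  mortality <- pmin(pmax(mu + stats::rnorm(n, 0, 0.03), 0),
                    config$mortality_cap)
  hi <- mortality >= stats::quantile(mortality, 0.75)
  lo <- mortality <= stats::quantile(mortality, 0.25)
  out <- data.frame(grid, mortality = mortality, stringsAsFactors = FALSE)
  std <- function(x) (x - mean(x)) / stats::sd(x)
  r2_of <- function(zcol) {
    out$..z.. <- zcol
    f <- tryCatch(loss_model(mortality ~ ..z.., out, kind = "sm"),
                  error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    goodness_of_fit(f, out)$r_squared
  }
  finish <- function(z_hi, z_lo, r2) {
    out$z_noisy_high <- z_hi
    out$z_noisy_low <- z_lo
    attr(out, "r2") <- r2
    attr(out, "latent_z") <- z
    attr(out, "config") <- config
    out
  }
  if (error_scale == 0) {
    zz <- std(z)
    return(finish(zz, zz, c(z_noisy_high = r2_of(zz),
                            z_noisy_low = r2_of(zz))))
  }
  cl <- error_scale
  for (try in seq_len(max_tries)) {
    e <- abs(stats::rnorm(n))  # shared half-normal error draws
    z_lo <- std(ifelse(lo, pmax(z - cl * e, z_floor), z))
    r2_lo <- r2_of(z_lo)
    if (!is.finite(r2_lo)) next
    z_hi_at <- function(c) std(ifelse(hi, z + c * e, z))
    gap <- function(c) {
      r2 <- r2_of(z_hi_at(c))
      if (!is.finite(r2)) return(NA_real_)
      r2 - r2_lo
    }
    root <- tryCatch(
      stats::uniroot(gap, c(0.01, 8), tol = 1e-4)$root,
      error = function(e) NA_real_)
    if (is.na(root)) {
      # misses cannot lose enough skill to match: attenuate the low-side
      # damage and redraw
      cl <- cl * 0.85
      next
    }
    z_hi <- z_hi_at(root)
    r2 <- c(z_noisy_high = r2_of(z_hi), z_noisy_low = r2_lo)
    if (all(is.finite(r2)) && abs(diff(r2)) < r2_tol) {
      return(finish(z_hi, z_lo, r2))
    }
  }
  stop("could not match R-squared within ", r2_tol, " after ", max_tries,
       " tries; consider a larger panel")
}

#' Stylized discrete mortality outcome distribution
#'
#' A 25-state discretization of seasonal herd mortality with
#' exponentially decaying (right-skewed) probabilities: frequent
#' low-mortality seasons and rare catastrophic ones up to 65% herd loss.
#' The default decay is chosen so a perfect contract with a 23% trigger
#' has an actuarially fair price of roughly 2% of insured value per
#' season (about $20 on a $1000 TLU).
#'
#' @param n_bins Number of mortality states (default 25).
#' @param max_mortality Largest mortality state (default 0.65).
#' @param decay Exponential decay scale of the state probabilities
#'   (default 0.14; also approximately the implied mean mortality).
#' @return A `data.frame` of class `"outcome_distribution"` with columns
#'   `mortality` (strictly increasing) and `prob` (summing to 1).
#' @export
outcome_distribution <- function(n_bins = 25L, max_mortality = 0.65,
                                 decay = 0.14) {
  if (n_bins < 2L) stop("need at least 2 states")
  if (max_mortality <= 0 || max_mortality > 1) {
    stop("max_mortality must be in (0, 1]")
  }
  M <- seq(0, max_mortality, length.out = n_bins)
  p <- exp(-M / decay)
  p <- p / sum(p)
  structure(data.frame(mortality = M, prob = p),
            class = c("outcome_distribution", "data.frame"))
}
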