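#' Natural-log transform of a positive index series
#'
#' Seasonal rainfall and NDVI aggregates are right-skewed; a log transform
#' brings them closer to normality before standardization.  NDVI can be
#' zero or negative over non-vegetated surfaces, so non-positive values are
#' a hard error rather than silently dropped.
#'
#' @param values Numeric vector, strictly positive.
#' @param keys Optional vector of labels (same length) used to name the
#'   offending records in error messages.
#' @return `log(values)`.
#' @export
log_transform <- function(values, keys = NULL) {
  bad <- !is.finite(values) | values <= 0
  if (any(bad)) {
    lab <- if (!is.null(keys)) keys[bad] else which(bad)
    stop("log_transform requires strictly positive values; offending: ",
         paste(utils::head(lab, 5L), collapse = ", "))
  }
  log(values)
}

#' Standardize a seasonal index into per-location z-scores
#'
#' Computes z-scores `z = (x - mu_l) / sigma_l` where `mu_l` and `sigma_l`
#' are the mean and (sample, n-1 denominator) standard deviation of the
#' index for location `l` across all seasons in the table.  Standardizing
#' per location expresses each season as an anomaly relative to that
#' location's own climatology, so locations with different mean greenness
#' or rainfall become comparable.
#'
#' By default both seasons of the year are pooled when computing `mu_l`
#' and `sigma_l`; set `by_season = TRUE` to stratify the climatology by
#' season-of-year (LRLD vs SRSD).
#'
#' @param data A season table (see [read_season_table()]).
#' @param index Name of the index column to standardize.
#' @param log Logical; log-transform (natural log) before standardizing.
#' @param by_season Logical; compute `mu_l`, `sigma_l` per
#'   (location, season) instead of per location.
#' @param location_col,season_col Column names for grouping.
#' @param zcol Name of the output column; default `paste0("z_", index)`.
#' @return `data` with the z-score column appended.  The per-group means
#'   and standard deviations (and the window of years they were computed
#'   over) are attached as attribute `"standardization"`.
#' @export
zscore_index <- function(data, index, log = FALSE, by_season = FALSE,
                         location_col = "location", season_col = "season",
                         zcol = paste0("z_", index)) {
  if (!index %in% names(data)) stop("no column '", index, "' in data")
  x <- data[[index]]
  keys <- paste(data[[location_col]], data$year, data[[season_col]], sep = "/")
  if (any(is.na(x))) {
    stop("missing index value for '", index, "' at: ",
         paste(utils::head(keys[is.na(x)], 5L), collapse = ", "))
  }
  if (log) x <- log_transform(x, keys = keys)
  grp <- if (by_season) {
    interaction(data[[location_col]], data[[season_col]], drop = TRUE)
  } else {
    factor(data[[location_col]])
  }
  mu <- tapply(x, grp, mean)
  sdv <- tapply(x, grp, stats::sd)
  ng <- tapply(x, grp, length)
  if (any(ng < 2L)) {
    stop("z-scores need at least 2 observations per group; too few in: ",
         paste(names(ng)[ng < 2L], collapse = ", "))
  }
  if (any(sdv <= 0 | !is.finite(sdv))) {
    stop("constant index (zero standard deviation) in group(s): ",
         paste(names(sdv)[sdv <= 0 | !is.finite(sdv)], collapse = ", "))
  }
  data[[zcol]] <- as.numeric((x - mu[as.character(grp)]) /
                               sdv[as.character(grp)])
  std <- data.frame(group = names(mu), mu = as.numeric(mu),
                    sigma = as.numeric(sdv), n = as.integer(ng),
                    stringsAsFactors = FALSE)
  attr(std, "year_window") <- range(data$year)
  attr(data, "standardization") <- std
  data
}
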