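#' @keywords internal
"_PACKAGE"

# TLU equivalents: 1 TLU = 1 cow = 0.7 camels = 10 goats or sheep.
.tlu_per_head <- c(cattle = 1, camels = 1 / 0.7, goats = 1 / 10, sheep = 1 / 10)

.seasons <- c("LRLD", "SRSD")

#' Convert a herd composition to Tropical Livestock Units
#'
#' Livestock counts of different species are combined into a single
#' Tropical Livestock Unit (TLU) figure using the conventional East-African
#' pastoralist equivalences: one TLU equals 1 cow, 0.7 camels, or 10 goats
#' or sheep.  The camel factor is applied as the exact reciprocal
#' `1 / 0.7`, not a rounded 1.4.
#'
#' @param herd Named numeric vector of head counts.  Allowed names are
#'   `"cattle"`, `"camels"`, `"goats"`, `"sheep"`; an empty vector is a
#'   valid (zero) herd.  Fractional head counts are allowed (e.g. shared
#'   animals).
#' @return A single number, the herd size in TLU.
#' @examples
#' tlu_from_herd(c(goats = 10))                     # 1 TLU
#' tlu_from_herd(c(cattle = 2, sheep = 5, camels = 1.4))
#' @export
tlu_from_herd <- function(herd) {
  if (length(herd) == 0L) return(0)
  if (is.null(names(herd)) || any(!nzchar(names(herd)))) {
    stop("herd must be a named vector (species -> head count)")
  }
  unknown <- setdiff(names(herd), names(.tlu_per_head))
  if (length(unknown) > 0L) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(herd)) || any(herd < 0)) {
    stop("herd counts must be finite and non-negative")
  }
  sum(herd * .tlu_per_head[names(herd)])
}

#' Read a long-format season table
#'
#' Reads a CSV of per-location, per-season records: observed livestock
#' mortality rate (a fraction of the herd) and one or more seasonal index
#' values (e.g. mean NDVI or rainfall for the season).  Column names are
#' configurable through `schema` so externally produced tables and the
#' synthetic generator share one reader.
#'
#' Rows with missing mortality are retained (they can still receive model
#' predictions); mortality outside `[0, 1]` and duplicated
#' (location, year, season) keys are errors.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping the canonical roles
#'   `location`, `year`, `season`, `mortality` to the column names used in
#'   the file.  Any remaining columns are treated as index columns and kept
#'   under their own names.
#' @return A `data.frame` with columns `location`, `year`, `season`,
#'   `mortality` followed by the index columns, one row per
#'   location-season.
#' @seealso [write_report()], [zscore_index()]
#' @export
read_season_table <- function(path,
                              schema = c(location = "location", year = "year",
                                         season = "season",
                                         mortality = "mortality")) {
  needed <- c("location", "year", "season", "mortality")
  if (!all(needed %in% names(schema))) {
    stop("schema must name columns for: ", paste(needed, collapse = ", "))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("failed to parse CSV '", path, "': ",
                             conditionMessage(e))
  )
  missing_cols <- setdiff(unname(schema[needed]), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing columns in '", path, "': ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    location  = as.character(df[[schema[["location"]]]]),
    year      = as.integer(df[[schema[["year"]]]]),
    season    = as.character(df[[schema[["season"]]]]),
    mortality = as.numeric(df[[schema[["mortality"]]]]),
    stringsAsFactors = FALSE
  )
  index_cols <- setdiff(names(df), unname(schema[needed]))
  for (ic in index_cols) out[[ic]] <- as.numeric(df[[ic]])

  bad_season <- !out$season %in% .seasons
  if (any(bad_season)) {
    stop("invalid season label(s) in row(s) ",
         paste(which(bad_season), collapse = ", "),
         " (expected LRLD or SRSD)")
  }
  bad_m <- !is.na(out$mortality) & (out$mortality < 0 | out$mortality > 1)
  if (any(bad_m)) {
    stop("mortality outside [0, 1] in row(s) ",
         paste(which(bad_m), collapse = ", "))
  }
  key <- paste(out$location, out$year, out$season, sep = "/")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (location, year, season) key(s): ",
         paste(dups, collapse = ", "))
  }
  out
}

#' Write a structured report to JSON
#'
#' Serializes welfare reports, sweep tables, or any list/data.frame to a
#' machine-readable JSON file that [read_report()] round-trips.
#'
#' @param x A list or data.frame (e.g. the welfare component of a
#'   [evaluate_contract()] result, or a sweep table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "rib_eval")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
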