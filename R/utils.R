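# Shared geometry, percentile and calendar helpers.

# Mean Earth radius, km. All great-circle distances in the package use this.
EARTH_RADIUS_KM <- 6371

# Meters per degree of latitude (and of longitude at the equator).
METERS_PER_DEGREE <- EARTH_RADIUS_KM * 1000 * pi / 180

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over both
#' point sets (recycled to a common length).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometers.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1) # ~111.19 km
haversine_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

# Single percentile convention used across all modules: linear interpolation
# between closest order statistics (stats::quantile type 7).
pctl <- function(x, probs) {
  stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
}

#' Missing-value vocabulary
#'
#' Controlled tokens emitted verbatim in all output tables:
#' "nav" (not available), "npr" (not provided), "nac" (confidential),
#' "nap" (not applicable).
#'
#' @param reason One of "not_collected", "withheld", "confidential",
#'   "not_applicable".
#' @return The corresponding token.
#' @export
#' @examples
#' encode_missing("not_collected")
encode_missing <- function(reason) {
  tokens <- c(
    not_collected  = "nav",
    withheld       = "npr",
    confidential   = "nac",
    not_applicable = "nap"
  )
  reason <- as.character(reason)
  bad <- !reason %in% names(tokens)
  if (any(bad)) {
    stop("unknown missing-value reason: ", paste(unique(reason[bad]), collapse = ", "))
  }
  unname(tokens[reason])
}

MISSING_TOKENS <- c("nav", "npr", "nac", "nap")

# Day-of-year on a fixed 366-bin calendar: Feb 29 occupies bin 60; in
# non-leap years bin 60 is skipped so Mar 1 is always bin 61.
doy366 <- function(dates) {
  lt <- as.POSIXlt(dates)
  yd <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  ifelse(!leap & yd >= 60L, yd + 1L, yd)
}

is_daily <- function(dates) {
  length(dates) >= 2 && all(diff(as.integer(as.Date(dates))) == 1L)
}

# Lengths of runs of TRUE in a logical vector (e.g. missing-data runs).
run_lengths <- function(flag) {
  r <- rle(as.logical(flag))
  r$lengths[r$values]
}
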