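# Provenance labels, station/island assignment, satellite match-up buffers,
# sample-level context aggregation, bias correction and priority merging.

#' Compose a sampling-design label
#'
#' Concatenates the station (OA), island (I), site (S) and colony (C)
#' components into the zero-padded label `OA###-I##-S##-C###`.
#'
#' @param oa Station number, 0-249 (0 = non-systematic event).
#' @param island Island number, 0-32.
#' @param site Site number, 0-99.
#' @param colony Colony number, 0-999.
#' @return Label string(s); vectorized over the components.
#' @export
#' @examples
#' compose_design_label(0, 4, 2, 12) # "OA000-I04-S02-C012"
compose_design_label <- function(oa, island, site, colony) {
  if (any(oa < 0 | oa > 249 | island < 0 | island > 32 |
          site < 0 | site > 99 | colony < 0 | colony > 999)) {
    stop("sampling-design component out of range (OA 0-249, I 0-32, ",
         "S 0-99, C 0-999)")
  }
  sprintf("OA%03d-I%02d-S%02d-C%03d", oa, island, site, colony)
}

#' Parse a sampling-design label back into its components
#'
#' Inverse of [compose_design_label()].
#'
#' @param label Label string(s) of the form `OA###-I##-S##-C###`.
#' @return Data frame with integer columns `oa`, `island`, `site`, `colony`.
#' @export
parse_design_label <- function(label) {
  m <- regmatches(label,
                  regexec("^OA(\\d{3})-I(\\d{2})-S(\\d{2})-C(\\d{3})$", label))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad)) stop("malformed design label: ", paste(label[bad], collapse = ", "))
  data.frame(oa = as.integer(vapply(m, `[`, "", 2)),
             island = as.integer(vapply(m, `[`, "", 3)),
             site = as.integer(vapply(m, `[`, "", 4)),
             colony = as.integer(vapply(m, `[`, "", 5)))
}

#' Group sampling events into stations
#'
#' Greedy clustering in time order: an event joins the currently open
#' station when it lies within `max_km` (great circle) and `max_days` of the
#' station centroid (running mean position and time); otherwise it opens the
#' next station. Events marked non-systematic that end up alone in their
#' station are assigned station 0 (unassigned), mirroring the convention
#' that isolated opportunistic events carry no station number.
#'
#' @param events Data frame with `time` (numeric days or POSIXct), `lon`,
#'   `lat`, and optionally logical `systematic` (default TRUE).
#' @param max_km Distance bound to the station centroid, km (default 75).
#' @param max_days Time bound to the station centroid, days (default 0.25).
#' @return Integer station id per event (0 = unassigned), in input order.
#' @export
assign_station <- function(events, max_km = 75, max_days = 0.25) {
  n <- nrow(events)
  if (!n) return(integer(0))
  tnum <- as.numeric(events$time)
  if (inherits(events$time, "POSIXct")) tnum <- tnum / 86400
  if (is.unsorted(tnum)) stop("events must be sorted by time")
  systematic <- if ("systematic" %in% names(events)) events$systematic else rep(TRUE, n)
  id <- integer(n)
  station <- 0L
  c_lon <- c_lat <- c_t <- NA_real_
  members <- 0L
  for (i in seq_len(n)) {
    if (members > 0 &&
        haversine_km(events$lon[i], events$lat[i], c_lon, c_lat) <= max_km &&
        abs(tnum[i] - c_t) <= max_days) {
      id[i] <- station
      c_lon <- (c_lon * members + events$lon[i]) / (members + 1)
      c_lat <- (c_lat * members + events$lat[i]) / (members + 1)
      c_t <- (c_t * members + tnum[i]) / (members + 1)
      members <- members + 1L
    } else {
      station <- station + 1L
      id[i] <- station
      c_lon <- events$lon[i]; c_lat <- events$lat[i]; c_t <- tnum[i]
      members <- 1L
    }
  }
  sizes <- tabulate(id)
  lone <- sizes[id] == 1L & !systematic
  id[lone] <- 0L
  # renumber surviving stations consecutively in time order
  kept <- unique(id[id > 0L])
  id[id > 0L] <- match(id[id > 0L], kept)
  id
}

#' Annotate a station with the nearest island within 370 km
#'
#' Stations within 200 nautical miles (370 km) of an island are labelled
#' with that island; the nearest island wins, ties broken by the lower
#' island code.
#'
#' @param station_lon,station_lat Station coordinates, degrees.
#' @param islands Data frame with `island` (integer code), `lon`, `lat`.
#' @param max_km Annotation radius, km (default 370 = 200 nmi).
#' @return Island code (integer) or NA when no island is in range.
#' @export
annotate_island <- function(station_lon, station_lat, islands, max_km = 370) {
  if (!nrow(islands)) return(NA_integer_)
  d <- haversine_km(station_lon, station_lat, islands$lon, islands$lat)
  in_range <- d <= max_km
  if (!any(in_range)) return(NA_integer_)
  cand <- which(in_range)
  cand <- cand[order(d[cand], islands$island[cand])]
  as.integer(islands$island[cand[1]])
}

#' Extract match-up statistics from a mapped satellite grid
#'
#' Collects the `(2b+1) x (2b+1)` pixel window centered on the pixel
#' containing the point and returns count, mean, standard deviation and the
#' 5/25/50/75/95 percentiles over its valid pixels. A 2-pixel buffer on a
#' 4-km grid gives the standard 5x5 (20 km) window, a 12-pixel buffer the
#' 25x25 (100 km) cloud-fallback window.
#'
#' @param grid List with `lon`, `lat` (pixel-center vectors, ascending) and
#'   `values` (matrix nlon x nlat, NA = masked).
#' @param lon,lat Match-up point, degrees (must fall inside the grid).
#' @param b Buffer half-width in pixels (>= 0).
#' @return List with `n`, `mean`, `stdev`, `p05`, `p25`, `p50`, `p75`,
#'   `p95`, `window` (side length in pixels), and `token` ("nav" when all
#'   pixels are missing).
#' @export
buffer_extract <- function(grid, lon, lat, b = 2) {
  stopifnot(b >= 0)
  half <- (grid$lon[2] - grid$lon[1]) / 2
  if (lon < grid$lon[1] - half || lon > grid$lon[length(grid$lon)] + half ||
      lat < grid$lat[1] - (grid$lat[2] - grid$lat[1]) / 2 ||
      lat > grid$lat[length(grid$lat)] + (grid$lat[2] - grid$lat[1]) / 2) {
    stop("match-up point lies outside the grid")
  }
  i <- which.min(abs(grid$lon - lon))
  j <- which.min(abs(grid$lat - lat))
  ii <- max(1, i - b):min(length(grid$lon), i + b)
  jj <- max(1, j - b):min(length(grid$lat), j + b)
  v <- as.numeric(grid$values[ii, jj])
  v <- v[!is.na(v)]
  if (!length(v)) {
    return(list(n = 0L, mean = NA_real_, stdev = NA_real_, p05 = NA_real_,
                p25 = NA_real_, p50 = NA_real_, p75 = NA_real_,
                p95 = NA_real_, window = 2L * b + 1L, token = "nav"))
  }
  q <- pctl(v, c(0.05, 0.25, 0.5, 0.75, 0.95))
  list(n = length(v), mean = mean(v),
       stdev = if (length(v) >= 2) stats::sd(v) else NA_real_,
       p05 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
       window = 2L * b + 1L, token = NA_character_)
}

#' Aggregate context records around a sample with lag bookkeeping
#'
#' Selects measurement records within the time, horizontal-distance and
#' depth tolerances of the sample and aggregates their values (n, mean,
#' stdev, 5/25/50/75/95 percentiles). The reported lags `dt` (days, signed,
#' sample minus context), `dxy` (km) and `dz` (m, positive when the sample
#' is deeper) are those of the nearest contributing record: nearest in time,
#' ties broken by horizontal distance. When no record qualifies the missing
#' token "nav" is returned with n = 0.
#'
#' @param sample List or one-row data frame with `time` (POSIXct or numeric
#'   days), `lon`, `lat`, `depth` (m, positive down).
#' @param records Data frame with `time`, `lon`, `lat`, `depth`, `value`.
#' @param max_dt Time tolerance, days.
#' @param max_dxy Horizontal tolerance, km.
#' @param max_dz Depth tolerance, m.
#' @return List with `n`, `mean`, `stdev`, `p05` ... `p95`, `dt`, `dxy`,
#'   `dz`, `token`.
#' @export
match_context <- function(sample, records, max_dt = 1, max_dxy = 75,
                          max_dz = 10) {
  stopifnot(max_dt > 0, max_dxy > 0, max_dz > 0)
  as_days <- function(t) if (inherits(t, "POSIXct")) as.numeric(t) / 86400 else as.numeric(t)
  dt <- as_days(sample$time) - as_days(records$time)
  dxy <- haversine_km(sample$lon, sample$lat, records$lon, records$lat)
  dz <- sample$depth - records$depth
  ok <- abs(dt) <= max_dt & dxy <= max_dxy & abs(dz) <= max_dz &
        !is.na(records$value)
  if (!any(ok)) {
    return(list(n = 0L, mean = NA_real_, stdev = NA_real_, p05 = NA_real_,
                p25 = NA_real_, p50 = NA_real_, p75 = NA_real_,
                p95 = NA_real_, dt = NA_real_, dxy = NA_real_,
                dz = NA_real_, token = "nav"))
  }
  v <- records$value[ok]
  q <- pctl(v, c(0.05, 0.25, 0.5, 0.75, 0.95))
  nearest <- which(ok)[order(abs(dt[ok]), dxy[ok])][1]
  list(n = length(v), mean = mean(v),
       stdev = if (length(v) >= 2) stats::sd(v) else NA_real_,
       p05 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
       dt = dt[nearest], dxy = dxy[nearest], dz = dz[nearest],
       token = NA_character_)
}

#' Regression bias correction of a satellite or model source
#'
#' Fits an ordinary least-squares regression of the source on the in-situ
#' reference over concurrent pairs; a bias exists when the slope differs
#' from 1 and/or the intercept from 0. Corrected values invert the fit:
#' `(source - intercept) / slope` (or `source / slope - intercept` with
#' `order = "divide_first"`). The correction is accepted only when the fit
#' is trustworthy: r >= `min_r`, slope within `slope_bounds`, and at least
#' `min_n` pairs; rejected sources should not be merged.
#'
#' @param source Source values (satellite or model).
#' @param reference Paired in-situ reference values.
#' @param order Inversion order; default subtracts the intercept first.
#' @param min_r Minimum Pearson correlation for acceptance.
#' @param slope_bounds Acceptable slope range.
#' @param min_n Minimum number of complete pairs.
#' @return A `bias_correction` list: `slope`, `intercept`, `r`, `n`,
#'   `corrected` (aligned with `source`, NA preserved), `accepted`.
#' @export
bias_correct_source <- function(source, reference,
                                order = c("subtract_first", "divide_first"),
                                min_r = 0.5, slope_bounds = c(1 / 3, 3),
                                min_n = 10) {
  order <- match.arg(order)
  ok <- !is.na(source) & !is.na(reference)
  n <- sum(ok)
  if (n < 2) stop("bias correction needs at least 2 complete pairs")
  if (stats::var(reference[ok]) == 0) {
    stop("reference has zero variance: regression is undefined")
  }
  fit <- stats::lm(source[ok] ~ reference[ok])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- stats::cor(source[ok], reference[ok])
  corrected <- if (order == "subtract_first") {
    (source - intercept) / slope
  } else {
    source / slope - intercept
  }
  accepted <- !is.na(r) && r >= min_r && slope >= slope_bounds[1] &&
    slope <= slope_bounds[2] && n >= min_n
  structure(list(slope = slope, intercept = intercept, r = r, n = n,
                 corrected = corrected, accepted = accepted),
            class = "bias_correction")
}

#' Merge prioritized sources into one series with provenance
#'
#' For each station, takes the first non-missing value in priority order
#' (in-situ first, then accepted bias-corrected satellite/model sources) and
#' records which source supplied it. Stations missing in every source get
#' the token "nav". An in-situ value, when present, is never overwritten.
#'
#' @param sources Named list of numeric vectors, equal length, in priority
#'   order (e.g. `list(insitu = ..., satellite = ..., model = ...)`).
#' @param accepted Named logical: whether each non-primary source passed
#'   bias-correction acceptance (defaults to TRUE for all). Rejected sources
#'   are skipped entirely.
#' @return Data frame with `value` (numeric, NA where nothing was available)
#'   and `provenance` (source name or "nav").
#' @export
merge_sources <- function(sources, accepted = NULL) {
  stopifnot(length(sources) >= 1, !is.null(names(sources)))
  n <- length(sources[[1]])
  stopifnot(all(vapply(sources, length, integer(1)) == n))
  if (is.null(accepted)) accepted <- stats::setNames(rep(TRUE, length(sources)),
                                                     names(sources))
  value <- rep(NA_real_, n)
  provenance <- rep("nav", n)
  for (nm in names(sources)) {
    if (!isTRUE(accepted[[nm]]) && nm != names(sources)[1]) next
    fill <- is.na(value) & !is.na(sources[[nm]])
    value[fill] <- sources[[nm]][fill]
    provenance[fill] <- nm
  }
  data.frame(value = value, provenance = provenance,
             stringsAsFactors = FALSE)
}

#' Interpolate a station-level gap in time
#'
#' Fills interior missing values by time-weighted linear interpolation
#' between the adjacent non-missing stations (the afternoon trace-metal
#' case: a sample taken between two morning stations). Boundary gaps are
#' left missing.
#'
#' @param values Numeric vector in station order.
#' @param times Numeric times of the stations (same length; defaults to the
#'   station index).
#' @return Numeric vector with interior gaps filled.
#' @export
interpolate_station_gap <- function(values, times = seq_along(values)) {
  ok <- !is.na(values)
  if (sum(ok) < 2) return(values)
  filled <- values
  gaps <- which(!ok)
  if (length(gaps)) {
    filled[gaps] <- stats::approx(times[ok], values[ok], xout = times[gaps],
                                  method = "linear", rule = 1)$y
  }
  filled
}
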