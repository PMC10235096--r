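# CoRTAD-style heat and cold thermal-stress indices and site summaries.
#
# Conventions: "past 52 weeks" is a trailing 364-day window inclusive of the
# current day; degree heating/cooling weeks divide the 84-day qualifying sum
# by 7 so units are degC-weeks; all percentiles use linear interpolation.

#' Count exceedances in a trailing window
#'
#' For each day, the number of days in the trailing window (inclusive of the
#' current day) whose value satisfies the comparison. Missing values never
#' qualify. Days whose full window precedes the first observed day are
#' flagged burn-in; their counts are computed over the partial window.
#'
#' @param values Daily numeric vector (gap-filled).
#' @param threshold Comparison threshold.
#' @param direction `"ge"` (value >= threshold) or `"le"` (value <=
#'   threshold).
#' @param window Window length in days (default 364 = 52 weeks).
#' @return List with integer `count` and logical `burn_in`, both aligned
#'   with `values`.
#' @export
rolling_exceedance_count <- function(values, threshold,
                                     direction = c("ge", "le"),
                                     window = 364L) {
  direction <- match.arg(direction)
  hit <- if (direction == "ge") values >= threshold else values <= threshold
  hit[is.na(hit)] <- FALSE
  cs <- cumsum(hit)
  n <- length(values)
  i <- seq_len(n)
  count <- cs - c(rep(0L, min(window, n)), cs[seq_len(max(n - window, 0))])
  first_ok <- which(!is.na(values))[1]
  if (is.na(first_ok)) first_ok <- 1L
  burn_in <- (i - first_ok + 1L) < window
  list(count = as.integer(count), burn_in = burn_in)
}

rolling_sum <- function(x, window) {
  x[is.na(x)] <- 0
  cs <- cumsum(x)
  n <- length(x)
  cs - c(rep(0, min(window, n)), cs[seq_len(max(n - window, 0))])
}

#' Degree heating / cooling weeks
#'
#' Accumulates qualifying thermal-stress anomalies over a trailing 84-day
#' (12-week) window and expresses the sum in degC-weeks (daily sum / 7).
#' Heat mode accumulates `tsa` on days with `tsa >= threshold`; cold mode
#' accumulates `tsa` on days with `tsa <= -threshold` (result <= 0).
#'
#' @param tsa Daily thermal stress anomaly, degC (gap-filled).
#' @param threshold Qualifying magnitude, degC (default 1).
#' @param window Accumulation window, days (default 84).
#' @param mode `"heat"` or `"cold"`.
#' @return Numeric vector of DHW (>= 0) or DCW (<= 0) in degC-weeks.
#' @export
degree_weeks <- function(tsa, threshold = 1, window = 84L,
                         mode = c("heat", "cold")) {
  mode <- match.arg(mode)
  qual <- if (mode == "heat") tsa >= threshold else tsa <= -threshold
  qual[is.na(qual)] <- FALSE
  rolling_sum(ifelse(qual, tsa, 0), window) / 7
}

#' Assemble the full per-day thermal index table for one site
#'
#' Computes, per day: the interpolated SST and anomaly, the heat and cold
#' thermal stress anomalies (SST minus the maximum / minimum weekly
#' climatology), degree heating and cooling weeks, and the 52-week
#' exceedance frequencies of each. Column names follow the field's bracketed
#' labels (e.g. `TSA_DHW`). A `burn_in` flag marks days whose 52-week
#' windows (including the window of the DHW/DCW frequencies, which trail an
#' 84-day accumulation) are not yet fully covered by data.
#'
#' @param series An `sst_series`.
#' @param clim A [build_climatology()] result; built from `series` when NULL.
#' @return A `thermal_index_series` data frame with columns `date`,
#'   `sst_mean_9pixel`, `seasonal_average_9pixel`, `SST_anomaly_9pixel`,
#'   `SST_mean_interpl`, `SST_anomaly_interpl`, `SST_anomaly_freq`,
#'   `TSA_heat`, `TSA_heat_freq`, `TSA_DHW`, `TSA_DHW_freq`, `TSA_cold`,
#'   `TSA_cold_freq`, `TSA_DCW`, `TSA_DCW_freq`, `burn_in`; attribute
#'   `gap_p95` carries the 95th percentile of consecutive-missing run
#'   lengths.
#' @export
assemble_indices <- function(series, clim = NULL) {
  if (is.null(clim)) clim <- build_climatology(series)
  stopifnot(inherits(clim, "seasonal_climatology"))
  anomaly <- compute_anomaly(series, clim)
  sst_fill <- fill_gaps(series$sst)
  anom_fill <- fill_gaps(anomaly)
  sst_interp <- sst_fill$filled
  anom_interp <- anom_fill$filled

  tsa_heat <- sst_interp - clim$max_weekly_clim
  tsa_cold <- sst_interp - clim$min_weekly_clim
  dhw <- degree_weeks(tsa_heat, mode = "heat")
  dcw <- degree_weeks(tsa_cold, mode = "cold")

  anom_freq <- rolling_exceedance_count(anom_interp, 1, "ge")
  heat_freq <- rolling_exceedance_count(tsa_heat, 1, "ge")
  cold_freq <- rolling_exceedance_count(tsa_cold, -1, "le")
  dhw_freq <- rolling_exceedance_count(dhw, 1, "ge")
  dcw_freq <- rolling_exceedance_count(dcw, -1, "le")

  # full validity of the DHW/DCW frequencies needs 364 days of DHW, which
  # itself needs 84 days of TSA: flag the first 364 + 84 - 1 observed days
  n <- length(sst_interp)
  first_ok <- which(!is.na(series$sst))[1]
  burn_in <- (seq_len(n) - first_ok + 1L) < (364L + 84L)

  out <- data.frame(
    date = series$date,
    sst_mean_9pixel = series$sst,
    seasonal_average_9pixel = clim$seasonal_cycle[doy366(series$date)],
    SST_anomaly_9pixel = anomaly,
    SST_mean_interpl = sst_interp,
    SST_anomaly_interpl = anom_interp,
    SST_anomaly_freq = anom_freq$count,
    TSA_heat = tsa_heat,
    TSA_heat_freq = heat_freq$count,
    TSA_DHW = dhw,
    TSA_DHW_freq = dhw_freq$count,
    TSA_cold = tsa_cold,
    TSA_cold_freq = cold_freq$count,
    TSA_DCW = dcw,
    TSA_DCW_freq = dcw_freq$count,
    burn_in = burn_in
  )
  attr(out, "gap_p95") <- sst_fill$gap_p95
  attr(out, "gap_run_lengths") <- sst_fill$run_lengths
  attr(out, "climatology") <- clim
  class(out) <- c("thermal_index_series", "data.frame")
  out
}

last_stress_event <- function(dates, tsa, qualifies, sampling_idx) {
  # most recent maximal qualifying run starting on or before the sampling day
  r <- rle(qualifies)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & starts <= sampling_idx)
  if (!length(cand)) return(NULL)
  k <- cand[length(cand)]
  s <- starts[k]
  e <- min(ends[k], sampling_idx)
  list(end_date = dates[e], peak = max(abs(tsa[s:e])) * sign(tsa[s]),
       duration = e - s + 1L,
       ongoing = ends[k] >= sampling_idx)
}

#' Summarize a site's thermal history at its sampling date
#'
#' Reduces the per-day index table to single values per site: for each index
#' the min, max, sum, mean, sd over the non-burn-in span up to the sampling
#' date and the value at the sampling day (last available prior day if
#' missing); the most recent heat and cold stress events (end date, peak,
#' duration) defined as maximal runs with `TSA_heat >= 1` / `TSA_cold <= -1`;
#' the recovery time since each (0 if the event is ongoing); and the 95th
#' percentile of missing-run durations.
#'
#' @param indices A [assemble_indices()] result.
#' @param sampling_date Sampling day (within the non-burn-in span).
#' @return A `site_thermal_summary` list with elements `stats` (data frame:
#'   index, min, max, sum, mean, sd, value_at_sampling), `last_heat_event`,
#'   `last_cold_event`, `recovery_days_heat`, `recovery_days_cold`,
#'   `gap_p95`.
#' @export
summarize_site <- function(indices, sampling_date) {
  stopifnot(inherits(indices, "thermal_index_series"))
  sampling_date <- as.Date(sampling_date)
  idx <- match(sampling_date, indices$date)
  if (is.na(idx)) stop("sampling date outside the series span")
  if (indices$burn_in[idx]) {
    stop("sampling date falls inside the index burn-in period")
  }
  keep <- !indices$burn_in & indices$date <= sampling_date
  cols <- setdiff(names(indices), c("date", "burn_in"))
  stats <- do.call(rbind, lapply(cols, function(cl) {
    v <- indices[[cl]][keep]
    vs <- v[!is.na(v)]
    at <- indices[[cl]][indices$date <= sampling_date]
    at <- at[!is.na(at)]
    data.frame(index = cl,
               min = min(vs), max = max(vs), sum = sum(vs),
               mean = mean(vs), sd = stats::sd(vs),
               value_at_sampling = if (length(at)) at[length(at)] else NA_real_)
  }))

  span <- which(keep)
  heat <- last_stress_event(indices$date, indices$TSA_heat,
                            !is.na(indices$TSA_heat) & indices$TSA_heat >= 1, idx)
  cold <- last_stress_event(indices$date, indices$TSA_cold,
                            !is.na(indices$TSA_cold) & indices$TSA_cold <= -1, idx)
  span_days <- length(span)
  rec <- function(ev) {
    if (is.null(ev)) return(span_days)
    if (ev$ongoing) 0 else as.numeric(sampling_date - ev$end_date)
  }
  structure(list(stats = stats,
                 last_heat_event = heat, last_cold_event = cold,
                 recovery_days_heat = rec(heat),
                 recovery_days_cold = rec(cold),
                 gap_p95 = attr(indices, "gap_p95")),
            class = "site_thermal_summary")
}

#' Match a site to the nearest Reef Check survey within 10 km
#'
#' @param site_lon,site_lat Site coordinates, degrees.
#' @param candidates Data frame with columns `lon`, `lat` (and any id
#'   columns, carried through).
#' @param max_km Match radius, km (default 10).
#' @return List with `matched` (logical); when matched, `candidate` (the
#'   matched row) and `distance_km`.
#' @export
match_reefcheck <- function(site_lon, site_lat, candidates, max_km = 10) {
  if (!nrow(candidates)) return(list(matched = FALSE))
  d <- haversine_km(site_lon, site_lat, candidates$lon, candidates$lat)
  k <- which.min(d)
  if (d[k] > max_km) return(list(matched = FALSE))
  list(matched = TRUE, candidate = candidates[k, , drop = FALSE],
       distance_km = d[k])
}
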