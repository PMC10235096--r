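# Site-level SST aggregation, seasonal climatology and anomaly computation.

#' Pool per-scene pixel extractions into a daily SST series
#'
#' Averages all pixel values recorded for a site on each calendar day
#' (across scenes and platforms) into a daily mean and sample standard
#' deviation. Days with no pixels are present in the output with missing
#' values and `n_pixels = 0`; the sd is missing whenever fewer than 2 pixels
#' contributed.
#'
#' @param pixel_records Data frame with columns `site_id`, `date`, `value`
#'   (degC, one row per pixel).
#' @return An `sst_series` data frame spanning the full date range with
#'   columns `site_id`, `date`, `sst`, `sst_sd`, `n_pixels`.
#' @export
daily_average_pixels <- function(pixel_records) {
  stopifnot(all(c("site_id", "date", "value") %in% names(pixel_records)))
  pixel_records$date <- as.Date(pixel_records$date)
  site <- unique(pixel_records$site_id)
  if (length(site) != 1) stop("pixel records must belong to a single site")
  dates <- seq(min(pixel_records$date), max(pixel_records$date), by = "day")
  key <- match(pixel_records$date, dates)
  n_pixels <- tabulate(key, nbins = length(dates))
  sums <- vapply(seq_along(dates), function(i) sum(pixel_records$value[key == i]),
                 numeric(1))
  sst <- ifelse(n_pixels > 0, sums / n_pixels, NA_real_)
  sst_sd <- vapply(seq_along(dates), function(i) {
    v <- pixel_records$value[key == i]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  }, numeric(1))
  out <- data.frame(site_id = site, date = dates, sst = sst, sst_sd = sst_sd,
                    n_pixels = n_pixels, stringsAsFactors = FALSE)
  class(out) <- c("sst_series", "data.frame")
  out
}

# Zero-phase Chebyshev type-I low-pass (order 3, 0.1 dB passband ripple,
# cutoff 1/36 cycles per day) applied to the day-of-year cycle triplicated
# to avoid edge artifacts; the middle copy is returned.
smooth_cycle <- function(cycle366) {
  filt <- signal::cheby1(3, Rp = 0.1, W = (1 / 36) / 0.5, type = "low")
  tripled <- rep(cycle366, 3)
  sm <- signal::filtfilt(filt, tripled)
  sm[367:732]
}

#' Build the seasonal SST climatology for a site
#'
#' Averages the series per day-of-year (366-bin calendar: Feb 29 is bin 60,
#' skipped in non-leap years), triplicates the cycle, applies a zero-phase
#' low-pass filter (Chebyshev type I, order 3, passband ripple 0.1 dB,
#' cutoff period 36 days) and extracts the middle year. Weekly climatologies
#' are means over 52 contiguous 7-day bins of the filtered cycle (bin 52
#' absorbs days 358-366); their extremes give the maximum and minimum weekly
#' climatology used by the thermal-stress indices.
#'
#' @param series An `sst_series` (from [generate_sst_series()] or
#'   [daily_average_pixels()]) spanning at least 3 full years.
#' @return A `seasonal_climatology`: list with `seasonal_cycle` (366 values,
#'   degC), `weekly_means` (52 values), `max_weekly_clim`, `min_weekly_clim`.
#' @export
build_climatology <- function(series) {
  stopifnot(inherits(series, "data.frame"), "sst" %in% names(series))
  if (nrow(series) < 3 * 365) stop("climatology requires at least 3 full years of data")
  doy <- doy366(series$date)
  raw <- vapply(1:366, function(d) {
    v <- series$sst[doy == d]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (is.na(raw[60]) && !anyNA(raw[-60])) {
    # Feb 29 bin can be legitimately empty when the span has no leap year
    raw[60] <- mean(raw[c(59, 61)])
  }
  if (anyNA(raw)) {
    stop("day-of-year bin(s) ", paste(which(is.na(raw)), collapse = ", "),
         " contain no data in any year; interpolate the series across ",
         "day-of-year bins before building a climatology")
  }
  cycle <- smooth_cycle(raw)
  week_bin <- pmin((1:366 - 1) %/% 7 + 1, 52)
  weekly <- as.numeric(tapply(cycle, week_bin, mean))
  structure(list(seasonal_cycle = cycle, weekly_means = weekly,
                 max_weekly_clim = max(weekly), min_weekly_clim = min(weekly)),
            class = "seasonal_climatology")
}

#' Daily SST anomaly relative to the seasonal climatology
#'
#' `anomaly = sst - seasonal_cycle(day of year)`; missing wherever the SST
#' is missing.
#'
#' @param series An `sst_series`.
#' @param clim A [build_climatology()] result for the same site.
#' @return Numeric vector of anomalies (degC), aligned with `series$date`.
#' @export
compute_anomaly <- function(series, clim) {
  stopifnot(inherits(clim, "seasonal_climatology"))
  series$sst - clim$seasonal_cycle[doy366(series$date)]
}

#' Linearly interpolate interior gaps and summarize missing runs
#'
#' Interior missing values are filled by linear interpolation against the
#' day index; leading and trailing missing values are left missing (there is
#' no anchor on one side). Gap statistics are computed on the original
#' missing runs, before filling.
#'
#' @param values Numeric vector with NAs (daily resolution assumed).
#' @return List with `filled` (numeric vector), `run_lengths` (lengths of
#'   consecutive-missing runs), and `gap_p95` (95th percentile of the run
#'   lengths; 0 when there are no gaps).
#' @export
fill_gaps <- function(values) {
  if (all(is.na(values))) stop("cannot interpolate an all-missing series")
  runs <- run_lengths(is.na(values))
  filled <- values
  idx <- seq_along(values)
  ok <- !is.na(values)
  if (any(!ok)) {
    filled[!ok] <- stats::approx(idx[ok], values[ok], xout = idx[!ok],
                                 method = "linear", rule = 1)$y
  }
  list(filled = filled,
       run_lengths = if (length(runs)) runs else integer(0),
       gap_p95 = if (length(runs)) pctl(runs, 0.95) else 0)
}
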