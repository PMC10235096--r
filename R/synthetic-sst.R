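# Synthetic daily SST series with known ground truth: seasonal cycle + linear
# trend + AR(1) noise + injected heat/cold events + missing-data runs.

#' Describe a synthetic SST scenario
#'
#' Parameters of a site-level daily SST record: a sinusoidal seasonal cycle,
#' a linear warming trend, stationary AR(1) weather noise, optional discrete
#' heatwave/cold-spell events, and geometric-length missing-data runs. The
#' defaults emulate a tropical Pacific reef site: 27 degC mean, 2 degC
#' seasonal amplitude, 0.2 degC per decade warming, 0.25 degC daily noise
#' with lag-1 autocorrelation 0.8, and ~5% missing days in runs of mean
#' length 5 (cloud cover).
#'
#' @param site_id Site identifier.
#' @param start_date,end_date Calendar span (coerced with [as.Date()]); must
#'   cover at least 3 full years so a climatology can be built downstream.
#' @param mean_sst Long-term mean, degC.
#' @param seasonal_amplitude Half peak-to-trough seasonal range, degC.
#' @param peak_day Day-of-year (366-bin calendar) of the seasonal maximum.
#' @param trend Linear trend, degC per decade.
#' @param noise_sd Stationary standard deviation of the AR(1) noise, degC.
#' @param ar1 Lag-1 autocorrelation of the noise, in [0, 1).
#' @param events List of [thermal_event()] descriptors.
#' @param gap_mean_len Mean length (days) of a missing-data run.
#' @param gap_fraction Target fraction of missing days, in [0, 0.5).
#' @param seed Integer seed; generation is deterministic given the scenario.
#' @return An object of class `sst_scenario`.
#' @export
sst_scenario <- function(site_id = "SITE-01",
                         start_date = "2002-01-01",
                         end_date = "2016-12-31",
                         mean_sst = 27,
                         seasonal_amplitude = 2,
                         peak_day = 75,
                         trend = 0.2,
                         noise_sd = 0.25,
                         ar1 = 0.8,
                         events = list(),
                         gap_mean_len = 5,
                         gap_fraction = 0.05,
                         seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(end_date > start_date, noise_sd >= 0, gap_fraction >= 0,
            gap_fraction < 0.5, gap_mean_len >= 1, ar1 >= 0, ar1 < 1)
  if (length(events) && inherits(events, "thermal_event")) events <- list(events)
  for (ev in events) {
    stopifnot(inherits(ev, "thermal_event"))
    if (ev$start_date < start_date ||
        ev$start_date + ev$duration - 1 > end_date) {
      stop("thermal event window falls outside the scenario span")
    }
  }
  structure(
    list(site_id = site_id, start_date = start_date, end_date = end_date,
         mean_sst = mean_sst, seasonal_amplitude = seasonal_amplitude,
         peak_day = peak_day, trend = trend, noise_sd = noise_sd, ar1 = ar1,
         events = events, gap_mean_len = gap_mean_len,
         gap_fraction = gap_fraction, seed = as.integer(seed)),
    class = "sst_scenario"
  )
}

#' Describe an injected thermal event
#'
#' A discrete anomaly added to the synthetic SST series: positive amplitude
#' for a heatwave, negative for a cold spell. Square events add the full
#' amplitude on every day; triangular events ramp linearly up to the
#' amplitude at the midpoint and back down, symmetric about it.
#'
#' @param start_date First day of the event.
#' @param duration Event length in days (> 0).
#' @param amplitude Peak anomaly, degC (sign gives heat/cold).
#' @param shape "square" or "triangular".
#' @return An object of class `thermal_event`.
#' @export
thermal_event <- function(start_date, duration, amplitude,
                          shape = c("square", "triangular")) {
  shape <- match.arg(shape)
  stopifnot(duration > 0)
  structure(list(start_date = as.Date(start_date),
                 duration = as.integer(duration),
                 amplitude = amplitude, shape = shape),
            class = "thermal_event")
}

event_profile <- function(ev) {
  d <- ev$duration
  if (ev$shape == "square") return(rep(ev$amplitude, d))
  # symmetric linear ramp peaking at the midpoint
  mid <- (d + 1) / 2
  ev$amplitude * (1 - abs(seq_len(d) - mid) / mid)
}

#' Generate a synthetic daily SST series
#'
#' Builds one value per calendar day as seasonal cycle + trend + event
#' anomaly + AR(1) noise, then blanks geometric-length missing runs placed
#' uniformly without overlap. The noise is initialized from its stationary
#' distribution so there is no burn-in artifact. The attached truth record
#' carries the noise-free components so downstream estimates (climatology,
#' anomalies, indices) can be checked against ground truth.
#'
#' @param scenario An [sst_scenario()].
#' @return An `sst_series` data frame with columns `site_id`, `date`, `sst`,
#'   `sst_sd`, `n_pixels`, and attribute `truth`: a data frame with per-day
#'   `seasonal`, `trend`, `event_anomaly`.
#' @export
generate_sst_series <- function(scenario) {
  stopifnot(inherits(scenario, "sst_scenario"))
  dates <- seq(scenario$start_date, scenario$end_date, by = "day")
  n <- length(dates)
  if (n < 3 * 365) {
    stop("scenario span must cover at least 3 years: a seasonal climatology ",
         "needs multiple annual cycles")
  }
  doy <- doy366(dates)
  seasonal <- scenario$mean_sst + scenario$seasonal_amplitude *
    cos(2 * pi * (doy - scenario$peak_day) / 366)
  trend_comp <- scenario$trend * as.numeric(dates - scenario$start_date) / 3652.5

  event_anom <- numeric(n)
  for (ev in scenario$events) {
    idx <- match(ev$start_date, dates) + seq_len(ev$duration) - 1L
    event_anom[idx] <- event_anom[idx] + event_profile(ev)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(scenario$seed)

  noise <- numeric(n)
  if (scenario$noise_sd > 0) {
    innov_sd <- scenario$noise_sd * sqrt(1 - scenario$ar1^2)
    noise[1] <- stats::rnorm(1, 0, scenario$noise_sd) # stationary start
    e <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in seq_len(n - 1)) noise[i + 1] <- scenario$ar1 * noise[i] + e[i]
  }

  missing_mask <- logical(n)
  target <- round(scenario$gap_fraction * n)
  if (target > 0) {
    placed <- 0L
    while (placed < target) {
      len <- stats::rgeom(1, 1 / scenario$gap_mean_len) + 1L
      len <- min(len, target - placed + 1L)
      ok <- FALSE
      for (try in seq_len(200)) {
        s <- sample.int(n - len + 1L, 1L)
        if (!any(missing_mask[s:(s + len - 1L)])) { ok <- TRUE; break }
      }
      if (!ok) break
      missing_mask[s:(s + len - 1L)] <- TRUE
      placed <- placed + len
    }
  }

  sst <- seasonal + trend_comp + event_anom + noise
  sst_sd <- rep(0.1, n)
  n_pixels <- rep(9L, n)
  sst[missing_mask] <- NA_real_
  sst_sd[missing_mask] <- NA_real_
  n_pixels[missing_mask] <- 0L

  out <- data.frame(site_id = scenario$site_id, date = dates, sst = sst,
                    sst_sd = sst_sd, n_pixels = n_pixels,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(date = dates, seasonal = seasonal,
                                   trend = trend_comp,
                                   event_anomaly = event_anom)
  attr(out, "scenario") <- scenario
  class(out) <- c("sst_series", "data.frame")
  out
}
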