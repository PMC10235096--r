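# Synthetic multi-source measurement tables and plankton samples.

#' Describe a multi-source measurement scenario
#'
#' A ground-truth variable observed by three acquisition routes: in-situ
#' (equal to truth), satellite and model, each of which reports
#' `slope * truth + intercept + noise` with its own missingness. Used as a
#' parameter-recovery fixture for regression bias correction and priority
#' merging. The default truth is centered near the origin (mean 2, sd 2):
#' the intercept of a match-up regression is only identifiable near the
#' data's support, so a variable on this scale makes intercept recovery a
#' meaningful check rather than an extrapolation far outside it.
#'
#' @param n Number of stations/time points.
#' @param truth_mean,truth_sd Level and spread of the true variable.
#' @param satellite,model Named lists with `slope` (non-zero), `intercept`,
#'   `noise_sd`, `missing_fraction`.
#' @param insitu_missing_fraction Fraction of in-situ values withheld.
#' @param seed Integer seed.
#' @return A `source_scenario` object.
#' @export
source_scenario <- function(n = 200,
                            truth_mean = 2, truth_sd = 2,
                            satellite = list(slope = 1.3, intercept = -0.5,
                                             noise_sd = 0.1,
                                             missing_fraction = 0.1),
                            model = list(slope = 0.9, intercept = 0.8,
                                         noise_sd = 0.2,
                                         missing_fraction = 0.05),
                            insitu_missing_fraction = 0.2,
                            seed = 1L) {
  stopifnot(n >= 2, satellite$slope != 0, model$slope != 0,
            insitu_missing_fraction >= 0, insitu_missing_fraction < 1)
  structure(list(n = as.integer(n), truth_mean = truth_mean,
                 truth_sd = truth_sd, satellite = satellite, model = model,
                 insitu_missing_fraction = insitu_missing_fraction,
                 seed = as.integer(seed)),
            class = "source_scenario")
}

#' Generate linked truth / in-situ / satellite / model tables
#'
#' @param scenario A [source_scenario()].
#' @return A list of data frames `truth`, `insitu`, `satellite`, `model`,
#'   each with columns `station`, `value` (NA where missing). Satellite and
#'   model values are `slope * truth + intercept + noise`; in-situ values
#'   equal truth where present.
#' @export
generate_multisource <- function(scenario) {
  stopifnot(inherits(scenario, "source_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n
  truth <- stats::rnorm(n, scenario$truth_mean, scenario$truth_sd)
  corrupt <- function(src) {
    v <- src$slope * truth + src$intercept +
      stats::rnorm(n, 0, src$noise_sd)
    if (src$missing_fraction > 0) {
      v[sample.int(n, round(src$missing_fraction * n))] <- NA_real_
    }
    v
  }
  insitu <- truth
  if (scenario$insitu_missing_fraction > 0) {
    insitu[sample.int(n, round(scenario$insitu_missing_fraction * n))] <- NA_real_
  }
  st <- seq_len(n)
  list(
    truth = data.frame(station = st, value = truth),
    insitu = data.frame(station = st, value = insitu),
    satellite = data.frame(station = st, value = corrupt(scenario$satellite)),
    model = data.frame(station = st, value = corrupt(scenario$model))
  )
}

#' Generate a synthetic plankton sample with a power-law size spectrum
#'
#' Draws object biovolumes from a truncated power-law density
#' `n(s) ~ s^spectral_slope` on `size_range` by inverse-CDF sampling
#' (log-uniform when the slope is exactly -1). All objects are flagged
#' living.
#'
#' @param spectral_slope Exponent of the abundance density (unitless).
#' @param n_objects Number of objects (> 0).
#' @param volume_sampled Water volume filtered, m^3 (> 0).
#' @param size_range Biovolume bounds, mm^3, both positive.
#' @param net_id Identifier carried on the sample.
#' @param seed Integer seed.
#' @return A `plankton_sample`: data frame with `object_id`,
#'   `biovolume_mm3`, `living`, plus attributes `volume_sampled` and
#'   `net_id`.
#' @export
generate_plankton_sample <- function(spectral_slope = -2, n_objects = 10000,
                                     volume_sampled = 40,
                                     size_range = c(2^-8, 2^4),
                                     net_id = "NET-A", seed = 1L) {
  stopifnot(n_objects > 0, volume_sampled > 0, all(size_range > 0),
            size_range[2] > size_range[1])
  set.seed(seed)
  a <- size_range[1]; b <- size_range[2]
  u <- stats::runif(n_objects)
  s <- if (abs(spectral_slope + 1) < 1e-12) {
    exp(log(a) + u * (log(b) - log(a)))
  } else {
    k <- spectral_slope + 1
    (a^k + u * (b^k - a^k))^(1 / k)
  }
  out <- data.frame(object_id = seq_len(n_objects), biovolume_mm3 = s,
                    living = TRUE)
  attr(out, "volume_sampled") <- volume_sampled
  attr(out, "net_id") <- net_id
  attr(out, "spectral_slope") <- spectral_slope
  class(out) <- c("plankton_sample", "data.frame")
  out
}
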