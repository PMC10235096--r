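# Theoretical net tow volumes, normalized biovolume size spectra (NBSS) and
# inter-net sampling efficiency.

#' Theoretical volume filtered by a net tow
#'
#' `volume = opening area * tow speed * tow duration`, with
#' `opening area = pi * net radius^2`. Used when the flow is too slow to
#' spin a flowmeter reliably.
#'
#' @param net_radius Net opening radius, m.
#' @param tow_speed Tow speed, m s^-1.
#' @param tow_duration Tow duration, s.
#' @return Volume filtered, m^3.
#' @export
#' @examples
#' theoretical_volume(0.15, 0.69, 900) # ~43.9 m^3
theoretical_volume <- function(net_radius, tow_speed, tow_duration) {
  if (any(c(net_radius, tow_speed, tow_duration) <= 0)) {
    stop("net radius, tow speed and tow duration must all be positive")
  }
  pi * net_radius^2 * tow_speed * tow_duration
}

#' Log2-spaced biovolume bins
#'
#' Bin edges at integer powers of 2 (mm^3), anchored at 2^0 and extended to
#' cover the given size range.
#'
#' @param size_range Biovolume range to cover, mm^3.
#' @return Numeric vector of strictly increasing bin edges.
#' @export
nbss_bins <- function(size_range) {
  stopifnot(all(size_range > 0))
  lo <- floor(log2(min(size_range)))
  hi <- ceiling(log2(max(size_range)))
  if (hi == lo) hi <- lo + 1
  2^(lo:hi)
}

#' Normalized biovolume size spectrum of living organisms
#'
#' Per size class: total biovolume of living objects in the class, divided
#' by the class width (mm^3) and by the volume of water sampled (m^3), so
#' values are in mm^3 mm^-3 m^-3 -- an abundance-per-size analogue.
#' Non-living objects are excluded before binning.
#'
#' @param sample A `plankton_sample` (see [generate_plankton_sample()]) or a
#'   data frame with `biovolume_mm3` and logical `living`.
#' @param bins Bin edges, mm^3 (default: log2 bins covering the sample).
#' @param volume_sampled Sampled volume, m^3 (taken from the sample
#'   attribute when NULL).
#' @return An `nbss_spectrum` data frame with `bin_low`, `bin_high`, `nbss`,
#'   `count`; attribute `volume_sampled`.
#' @export
compute_nbss <- function(sample, bins = NULL, volume_sampled = NULL) {
  if (is.null(volume_sampled)) volume_sampled <- attr(sample, "volume_sampled")
  stopifnot(!is.null(volume_sampled), volume_sampled > 0)
  live <- sample[sample$living, , drop = FALSE]
  if (!nrow(live)) stop("sample contains no living objects")
  if (is.null(bins)) bins <- nbss_bins(range(live$biovolume_mm3))
  stopifnot(all(diff(bins) > 0))
  s <- live$biovolume_mm3
  outside <- s < bins[1] | s > bins[length(bins)]
  if (any(outside)) {
    stop("object(s) outside bin coverage: ",
         paste(utils::head(live$object_id[outside], 5), collapse = ", "))
  }
  k <- findInterval(s, bins, rightmost.closed = TRUE)
  nb <- length(bins) - 1
  total <- vapply(seq_len(nb), function(i) sum(s[k == i]), numeric(1))
  count <- tabulate(k, nbins = nb)
  width <- diff(bins)
  out <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                    nbss = total / width / volume_sampled, count = count)
  attr(out, "volume_sampled") <- volume_sampled
  class(out) <- c("nbss_spectrum", "data.frame")
  out
}

#' Fit the log-log slope of an NBSS spectrum
#'
#' Ordinary least squares of log(nbss) against log(geometric bin center),
#' over classes with at least `min_count` objects (sparse tail classes carry
#' large sampling noise).
#'
#' @param spectrum A [compute_nbss()] result.
#' @param min_count Minimum objects per class to enter the fit.
#' @return Fitted slope (unitless).
#' @export
nbss_slope <- function(spectrum, min_count = 5) {
  use <- spectrum$count >= min_count & spectrum$nbss > 0
  if (sum(use) < 2) stop("too few populated size classes to fit a slope")
  x <- log(sqrt(spectrum$bin_low[use] * spectrum$bin_high[use]))
  y <- log(spectrum$nbss[use])
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Sampling efficiency of one net relative to another
#'
#' Mean and standard deviation, over shared size classes where both spectra
#' are positive, of the per-class ratio `a / b`.
#'
#' @param spectrum_a,spectrum_b [compute_nbss()] results on identical bins.
#' @return List with `mean`, `sd`, `n_classes`, and the per-class `ratios`.
#' @export
net_efficiency <- function(spectrum_a, spectrum_b) {
  if (nrow(spectrum_a) != nrow(spectrum_b) ||
      any(spectrum_a$bin_low != spectrum_b$bin_low)) {
    stop("spectra must be computed on identical bins")
  }
  shared <- spectrum_a$nbss > 0 & spectrum_b$nbss > 0
  if (!any(shared)) stop("no shared non-empty size class")
  ratios <- spectrum_a$nbss[shared] / spectrum_b$nbss[shared]
  list(mean = mean(ratios),
       sd = if (length(ratios) >= 2) stats::sd(ratios) else 0,
       n_classes = length(ratios), ratios = ratios)
}
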