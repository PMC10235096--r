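# Analytic surface-velocity fields with closed-form Eulerian/Lagrangian truth.

#' Describe a synthetic flow scenario
#'
#' Defines a gridded (lon, lat, time) surface-current field of one of five
#' analytic kinds. Rates are given per day; the generated `u`, `v` are in
#' m s^-1. The default grid emulates a 0.25-degree, daily product over a
#' small equatorial domain (the local tangent-plane construction keeps the
#' analytic truth exact to well under grid tolerance there).
#'
#' Kinds and parameters (all optional, shown with defaults):
#' \describe{
#'   \item{uniform}{`u = 0.5`, `v = 0` (m s^-1): constant flow.}
#'   \item{solid_body}{`omega = 0.1` (d^-1) rotation about the domain center;
#'     optional `core_radius` (degrees) makes a Rankine vortex: solid-body
#'     core, irrotational 1/r decay outside.}
#'   \item{strain}{`sigma = 0.1` (d^-1): u = sigma x, v = -sigma y.}
#'   \item{divergent}{`delta = 0.05` (d^-1): u = delta x / 2, v = delta y / 2.}
#'   \item{double_gyre}{`A = 0.1` (m s^-1), `eps = 0.25`, `period = 10` (d):
#'     the standard time-periodic double-gyre stream function; qualitative
#'     use only, no closed-form truth attached.}
#' }
#'
#' @param kind Flow kind, see Details.
#' @param params Named list of kind-specific rates.
#' @param lon_range,lat_range Domain extent, degrees.
#' @param resolution Grid spacing, degrees (> 0; grid must span >= 5x5 nodes).
#' @param n_days Number of daily time steps.
#' @param steady If TRUE the field is time-invariant.
#' @return A `flow_scenario` object.
#' @export
flow_scenario <- function(kind = c("uniform", "solid_body", "strain",
                                   "divergent", "double_gyre"),
                          params = list(),
                          lon_range = c(-2.5, 2.5), lat_range = c(-2.5, 2.5),
                          resolution = 0.25, n_days = 70, steady = TRUE) {
  kind <- match.arg(kind)
  stopifnot(resolution > 0, n_days >= 1)
  if (diff(lon_range) / resolution < 4 || diff(lat_range) / resolution < 4) {
    stop("grid must span at least 5 x 5 nodes")
  }
  defaults <- switch(kind,
    uniform = list(u = 0.5, v = 0),
    solid_body = list(omega = 0.1, core_radius = NULL),
    strain = list(sigma = 0.1),
    divergent = list(delta = 0.05),
    double_gyre = list(A = 0.1, eps = 0.25, period = 10)
  )
  params <- utils::modifyList(defaults, params)
  structure(list(kind = kind, params = params, lon_range = lon_range,
                 lat_range = lat_range, resolution = resolution,
                 n_days = as.integer(n_days), steady = isTRUE(steady)),
            class = "flow_scenario")
}

#' Generate a gridded velocity field from an analytic scenario
#'
#' Evaluates the scenario's velocity law on the full (lon, lat, time) grid.
#' For the uniform, solid-body, strain and divergent kinds the returned
#' object carries closed-form truth fields at every node: divergence,
#' vorticity and the shear/strain term s^2 in d^-1 (d^-2 for s^2), the
#' Okubo-Weiss parameter OW = s^2 - vorticity^2 in d^-2, and where defined a
#' constant FTLE (d^-1).
#'
#' @param scenario A [flow_scenario()].
#' @return A `velocity_field`: list with `lon`, `lat` (degree vectors),
#'   `time` (days, 0-based), arrays `u`, `v` of dim (nlon, nlat, ntime) in
#'   m s^-1, and `truth` (list of nlon x nlat matrices, or NULL).
#' @export
generate_velocity_field <- function(scenario) {
  stopifnot(inherits(scenario, "flow_scenario"))
  lon <- seq(scenario$lon_range[1], scenario$lon_range[2], by = scenario$resolution)
  lat <- seq(scenario$lat_range[1], scenario$lat_range[2], by = scenario$resolution)
  time <- seq_len(scenario$n_days) - 1
  nlon <- length(lon); nlat <- length(lat); nt <- length(time)
  lon0 <- mean(range(lon)); lat0 <- mean(range(lat))

  # local tangent-plane coordinates (meters), x scaled by cos(lat) pointwise
  latm <- matrix(lat, nlon, nlat, byrow = TRUE)
  lonm <- matrix(lon, nlon, nlat)
  x <- METERS_PER_DEGREE * cos(latm * pi / 180) * (lonm - lon0)
  y <- METERS_PER_DEGREE * (latm - lat0)

  p <- scenario$params
  day <- 86400
  truth <- NULL
  slice <- function(t_days) {
    switch(scenario$kind,
      uniform = list(u = matrix(p$u, nlon, nlat), v = matrix(p$v, nlon, nlat)),
      solid_body = {
        w <- p$omega / day
        if (is.null(p$core_radius)) {
          list(u = -w * y, v = w * x)
        } else {
          a <- p$core_radius * METERS_PER_DEGREE
          r2 <- pmax(x^2 + y^2, 1e-6)
          f <- ifelse(r2 <= a^2, 1, a^2 / r2)
          list(u = -w * y * f, v = w * x * f)
        }
      },
      strain = {
        s <- p$sigma / day
        list(u = s * x, v = -s * y)
      },
      divergent = {
        d <- p$delta / day / 2
        list(u = d * x, v = d * y)
      },
      double_gyre = {
        # stream function psi = A sin(pi f(xs,t)) sin(pi ys) on [0,2]x[0,1]
        xs <- 2 * (lonm - min(lon)) / diff(range(lon))
        ys <- (latm - min(lat)) / diff(range(lat))
        eps <- p$eps; om <- 2 * pi / p$period
        at <- eps * sin(om * t_days); bt <- 1 - 2 * eps * sin(om * t_days)
        f <- at * xs^2 + bt * xs
        dfdx <- 2 * at * xs + bt
        list(u = -pi * p$A * sin(pi * f) * cos(pi * ys),
             v = pi * p$A * cos(pi * f) * sin(pi * ys) * dfdx)
      }
    )
  }

  u <- array(NA_real_, c(nlon, nlat, nt))
  v <- array(NA_real_, c(nlon, nlat, nt))
  for (k in seq_len(nt)) {
    s <- slice(if (scenario$steady) 0 else time[k])
    u[, , k] <- s$u
    v[, , k] <- s$v
  }

  zero <- matrix(0, nlon, nlat)
  truth <- switch(scenario$kind,
    uniform = list(diverg = zero, vorticity = zero, s2 = zero, ow = zero,
                   ftle = zero),
    solid_body = {
      w <- p$omega
      if (is.null(p$core_radius)) {
        list(diverg = zero, vorticity = zero + 2 * w, s2 = zero,
             ow = zero - 4 * w^2, ftle = zero)
      } else {
        a <- p$core_radius * METERS_PER_DEGREE
        r2 <- x^2 + y^2
        core <- r2 <= a^2
        # outside a Rankine core the flow is irrotational pure shear-strain:
        # s^2 = (2 w a^2 / r^2)^2, vorticity = 0
        s2 <- ifelse(core, 0, (2 * w * a^2 / pmax(r2, 1e-6))^2)
        list(diverg = zero, vorticity = ifelse(core, 2 * w, 0), s2 = s2,
             ow = ifelse(core, -4 * w^2, s2), ftle = NULL)
      }
    },
    strain = list(diverg = zero, vorticity = zero, s2 = zero + 4 * p$sigma^2,
                  ow = zero + 4 * p$sigma^2, ftle = zero + p$sigma),
    divergent = list(diverg = zero + p$delta, vorticity = zero, s2 = zero,
                     ow = zero, ftle = NULL),
    double_gyre = NULL
  )

  structure(list(lon = lon, lat = lat, time = time, u = u, v = v,
                 steady = scenario$steady, truth = truth,
                 scenario = scenario),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d nodes, %d days, lon [%g, %g], lat [%g, %g]\n",
              length(x$lon), length(x$lat), length(x$time),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

# Bilinear (space) + linear (time) interpolation of u, v at particle
# positions. Returns NA for positions outside the domain or touching a
# missing-velocity corner. Vectorized over particles.
vf_interp <- function(field, lon, lat, t) {
  n <- length(lon)
  u <- rep(NA_real_, n); v <- rep(NA_real_, n)
  glon <- field$lon; glat <- field$lat; gt <- field$time
  inside <- lon >= glon[1] & lon <= glon[length(glon)] &
            lat >= glat[1] & lat <= glat[length(glat)] &
            !is.na(lon) & !is.na(lat)
  if (!any(inside)) return(list(u = u, v = v, inside = inside))
  i <- pmin(findInterval(lon[inside], glon), length(glon) - 1L)
  j <- pmin(findInterval(lat[inside], glat), length(glat) - 1L)
  dl <- glon[2] - glon[1]; dp <- glat[2] - glat[1]
  wx <- (lon[inside] - glon[i]) / dl
  wy <- (lat[inside] - glat[j]) / dp

  tt <- rep_len(t, n)[inside]
  tt <- pmin(pmax(tt, gt[1]), gt[length(gt)])
  if (field$steady || length(gt) == 1L) {
    k <- rep(1L, length(i)); wt <- rep(0, length(i))
  } else {
    k <- pmin(findInterval(tt, gt), length(gt) - 1L)
    wt <- (tt - gt[k]) / (gt[2] - gt[1])
  }

  nlon <- length(glon); nlat <- length(glat)
  idx <- function(ii, jj, kk) ii + (jj - 1L) * nlon + (kk - 1L) * nlon * nlat
  bil <- function(arr, kk) {
    a00 <- arr[idx(i, j, kk)];       a10 <- arr[idx(i + 1L, j, kk)]
    a01 <- arr[idx(i, j + 1L, kk)];  a11 <- arr[idx(i + 1L, j + 1L, kk)]
    a00 * (1 - wx) * (1 - wy) + a10 * wx * (1 - wy) +
      a01 * (1 - wx) * wy + a11 * wx * wy
  }
  u1 <- bil(field$u, k); v1 <- bil(field$v, k)
  if (any(wt > 0)) {
    u2 <- bil(field$u, k + 1L); v2 <- bil(field$v, k + 1L)
    u1 <- u1 * (1 - wt) + u2 * wt
    v1 <- v1 * (1 - wt) + v2 * wt
  }
  u[inside] <- u1; v[inside] <- v1
  list(u = u, v = v, inside = inside)
}
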