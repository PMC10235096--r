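# Lagrangian diagnostics: stadium seeding, RK4 advection, FTLE, Lagrangian
# divergence, retention time, flow-network betweenness, station statistics.

#' Describe a stadium-shaped station region
#'
#' The water mass sampled along a transect is modelled as a stadium: the set
#' of points within `radius` degrees of the segment joining the transect
#' endpoints (a rectangle capped by two semi-circles). The stadium is filled
#' with virtual particles on a regular lattice of pitch `spacing` degrees.
#'
#' @param p_start,p_end Transect endpoints, `c(lon, lat)` degrees.
#' @param radius Semi-circle radius, degrees (default 0.1).
#' @param spacing Particle lattice pitch, degrees (default 0.01).
#' @return A `stadium_spec` object.
#' @export
stadium_spec <- function(p_start, p_end = p_start, radius = 0.1,
                         spacing = 0.01) {
  stopifnot(length(p_start) == 2, length(p_end) == 2, radius > 0,
            spacing > 0, spacing <= radius)
  structure(list(p_start = as.numeric(p_start), p_end = as.numeric(p_end),
                 radius = radius, spacing = spacing),
            class = "stadium_spec")
}

# Degree-space distance from points to the segment p_start--p_end.
dist_to_segment <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
  sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
}

#' Seed virtual particles in a stadium region
#'
#' Lattice points (pitch `spacing`, anchored at `p_start`) are retained when
#' their degree-space distance to the transect segment is at most `radius`
#' (boundary points included).
#'
#' @param spec A [stadium_spec()].
#' @return Data frame of particle positions `lon`, `lat` (degrees).
#' @export
seed_stadium <- function(spec) {
  stopifnot(inherits(spec, "stadium_spec"))
  a <- spec$p_start; b <- spec$p_end; r <- spec$radius; h <- spec$spacing
  lon_lo <- min(a[1], b[1]) - r; lon_hi <- max(a[1], b[1]) + r
  lat_lo <- min(a[2], b[2]) - r; lat_hi <- max(a[2], b[2]) + r
  gx <- a[1] + seq(floor((lon_lo - a[1]) / h), ceiling((lon_hi - a[1]) / h)) * h
  gy <- a[2] + seq(floor((lat_lo - a[2]) / h), ceiling((lat_hi - a[2]) / h)) * h
  g <- expand.grid(lon = gx, lat = gy)
  keep <- dist_to_segment(g$lon, g$lat, a, b) <= r + 1e-12
  if (!any(keep)) stop("degenerate stadium: no lattice point falls inside")
  g[keep, , drop = FALSE]
}

#' Advect particles through a velocity field
#'
#' Integrates particle trajectories with 4th-order Runge-Kutta at a fixed
#' 0.125-day step, bilinear spatial and linear temporal interpolation of the
#' velocities, storing positions at daily resolution. Particles that reach a
#' missing-velocity cell are flagged `beached`, particles that exit the grid
#' are flagged `left_domain`; both are frozen at their last valid position.
#'
#' @param particles Data frame with `lon`, `lat` (degrees).
#' @param field A `velocity_field`.
#' @param t0 Start time, days (within the field's span).
#' @param tau Advective time, days (positive integer).
#' @param direction `"backward"` (default, as for origin diagnostics) or
#'   `"forward"`.
#' @param step RK4 step, days.
#' @return A `trajectory_set`: list with matrices `lon`, `lat` of dim
#'   (n_particles, tau + 1) holding daily positions from t0 outward,
#'   `days` (signed offsets 0..tau), `status` per particle
#'   ("ok", "beached", "left_domain"), `tau`, `direction`.
#' @export
advect <- function(particles, field, t0, tau,
                   direction = c("backward", "forward"), step = 0.125) {
  direction <- match.arg(direction)
  stopifnot(inherits(field, "velocity_field"), tau > 0)
  sgn <- if (direction == "forward") 1 else -1
  t_end <- t0 + sgn * tau
  if (!field$steady &&
      (min(t0, t_end) < field$time[1] || max(t0, t_end) > max(field$time))) {
    stop("required time window [", min(t0, t_end), ", ", max(t0, t_end),
         "] lies outside the field span")
  }
  np <- nrow(particles)
  full_days <- floor(tau + 1e-9)
  rem <- tau - full_days
  if (rem > 0 && abs(rem / step - round(rem / step)) > 1e-9) {
    stop("tau must be a whole number of RK4 steps")
  }
  day_offsets <- c(0:full_days, if (rem > 0) tau)
  n_store <- length(day_offsets)
  lon <- matrix(NA_real_, np, n_store)
  lat <- matrix(NA_real_, np, n_store)
  lon[, 1] <- particles$lon
  lat[, 1] <- particles$lat
  status <- rep("ok", np)
  cur_lon <- particles$lon; cur_lat <- particles$lat

  deriv <- function(plon, plat, t) {
    w <- vf_interp(field, plon, plat, t)
    list(dlon = w$u * 86400 / (METERS_PER_DEGREE * cos(plat * pi / 180)),
         dlat = w$v * 86400 / METERS_PER_DEGREE,
         inside = w$inside, ok = w$inside & !is.na(w$u))
  }

  for (d in seq_len(n_store - 1)) {
    seg_len <- day_offsets[d + 1] - day_offsets[d]
    for (s in seq_len(round(seg_len / step))) {
      active <- status == "ok"
      if (!any(active)) break
      t <- t0 + sgn * (day_offsets[d] + (s - 1) * step)
      h <- sgn * step
      al <- cur_lon[active]; ap <- cur_lat[active]
      k1 <- deriv(al, ap, t)
      k2 <- deriv(al + h / 2 * k1$dlon, ap + h / 2 * k1$dlat, t + h / 2)
      k3 <- deriv(al + h / 2 * k2$dlon, ap + h / 2 * k2$dlat, t + h / 2)
      k4 <- deriv(al + h * k3$dlon, ap + h * k3$dlat, t + h)
      ok <- k1$ok & k2$ok & k3$ok & k4$ok
      new_lon <- al + h / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
      new_lat <- ap + h / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
      ai <- which(active)
      lost <- ai[!ok]
      if (length(lost)) {
        # a stage evaluation outside the grid means the particle exited;
        # inside but missing velocity means it beached
        exited <- !(k1$inside & k2$inside & k3$inside & k4$inside)[!ok]
        status[lost] <- ifelse(exited, "left_domain", "beached")
      }
      keep <- ai[ok]
      cur_lon[keep] <- new_lon[ok]
      cur_lat[keep] <- new_lat[ok]
    }
    live <- status == "ok"
    lon[live, d + 1] <- cur_lon[live]
    lat[live, d + 1] <- cur_lat[live]
  }
  structure(list(lon = lon, lat = lat, days = sgn * day_offsets, t0 = t0,
                 tau = tau, direction = direction, status = status),
            class = "trajectory_set")
}

#' Finite-time Lyapunov exponents for seeded particles
#'
#' For each particle, an auxiliary cross of four points at +/- `spacing`
#' degrees is advected (backward by default) over `tau` days; the flow-map
#' gradient is formed by central differences of the auxiliary endpoints in
#' meters, and FTLE = ln(lambda_max(F'F)) / (2 tau), in d^-1. Particles with
#' any lost auxiliary get a missing FTLE.
#'
#' @param particles Data frame with `lon`, `lat`.
#' @param field A `velocity_field`.
#' @param t0 Start day.
#' @param tau Advective time, days.
#' @param spacing Auxiliary offset, degrees.
#' @param direction `"backward"` (default) or `"forward"`.
#' @return Numeric vector of FTLE values (d^-1), NA where undefined.
#' @export
ftle <- function(particles, field, t0, tau, spacing = 0.01,
                 direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  np <- nrow(particles)
  aux <- data.frame(
    lon = c(particles$lon + spacing, particles$lon - spacing,
            particles$lon, particles$lon),
    lat = c(particles$lat, particles$lat,
            particles$lat + spacing, particles$lat - spacing)
  )
  tr <- advect(aux, field, t0, tau, direction = direction)
  last <- ncol(tr$lon)
  fl <- matrix(tr$lon[, last], np, 4) # columns: E, W, N, S
  fp <- matrix(tr$lat[, last], np, 4)
  ok <- matrix(tr$status == "ok", np, 4)
  good <- rowSums(ok) == 4

  out <- rep(NA_real_, np)
  if (!any(good)) return(out)
  m <- METERS_PER_DEGREE
  dx0 <- 2 * spacing * m * cos(particles$lat[good] * pi / 180)
  dy0 <- 2 * spacing * m
  latc <- rowMeans(fp[good, , drop = FALSE])
  cosf <- cos(latc * pi / 180)
  f11 <- (fl[good, 1] - fl[good, 2]) * m * cosf / dx0
  f21 <- (fp[good, 1] - fp[good, 2]) * m / dx0
  f12 <- (fl[good, 3] - fl[good, 4]) * m * cosf / dy0
  f22 <- (fp[good, 3] - fp[good, 4]) * m / dy0
  # largest eigenvalue of the 2x2 Cauchy-Green tensor F'F
  a <- f11^2 + f21^2; b <- f11 * f12 + f21 * f22; d <- f12^2 + f22^2
  lmax <- (a + d) / 2 + sqrt(pmax(((a - d) / 2)^2 + b^2, 0))
  out[good] <- log(pmax(lmax, .Machine$double.eps)) / (2 * tau)
  out
}

#' Lagrangian divergence along backward trajectories
#'
#' Time-mean of the Eulerian divergence interpolated along each particle's
#' (backward) trajectory: trapezoidal integral over the daily stored
#' positions divided by tau, so units stay d^-1. Lost particles get NA.
#'
#' @param trajectories A [advect()] result.
#' @param field The `velocity_field` used for the advection.
#' @return Numeric vector, one value (d^-1) per particle.
#' @export
lagrangian_divergence <- function(trajectories, field) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  tau <- trajectories$tau
  np <- nrow(trajectories$lon)
  vals <- matrix(NA_real_, np, tau + 1)
  for (k in 0:tau) {
    t_abs <- trajectories$t0 + trajectories$days[k + 1]
    t_grid <- if (field$steady) field$time[1] else
      field$time[which.min(abs(field$time - t_abs))]
    ef <- eulerian_fields(field, t_grid)
    vals[, k + 1] <- grid_interp(ef$diverg, field$lon, field$lat,
                                 trajectories$lon[, k + 1],
                                 trajectories$lat[, k + 1])
  }
  ok <- trajectories$status == "ok"
  out <- rep(NA_real_, np)
  w <- c(0.5, rep(1, tau - 1), 0.5) # trapezoid over tau day-long intervals
  out[ok] <- as.numeric(vals[ok, , drop = FALSE] %*% w) / tau
  out
}

#' Retention time inside an eddy
#'
#' Advects particles backward over a 60-day window and counts, backward from
#' t0, the consecutive days each particle spends inside an eddy. Eddy
#' membership on each day uses the Okubo-Weiss criterion
#' `OW(position) < -0.2 sd(OW)` where the standard deviation is spatial,
#' over the whole domain at that day. A particle outside an eddy at t0 gets
#' 0; values are capped at the window length.
#'
#' @param particles Data frame with `lon`, `lat`.
#' @param field A `velocity_field`.
#' @param t0 Sampling day.
#' @param window Backward window, days (default 60).
#' @return Integer days per particle (NA for lost particles).
#' @export
retention_time <- function(particles, field, t0, window = 60) {
  tr <- advect(particles, field, t0, window, direction = "backward")
  np <- nrow(particles)
  in_eddy <- matrix(FALSE, np, window + 1)
  for (k in 0:window) {
    t_abs <- t0 - k
    t_grid <- if (field$steady) field$time[1] else
      field$time[which.min(abs(field$time - t_abs))]
    ef <- eulerian_fields(field, t_grid)
    sd_ow <- stats::sd(as.numeric(ef$ow), na.rm = TRUE)
    owp <- grid_interp(ef$ow, field$lon, field$lat,
                       tr$lon[, k + 1], tr$lat[, k + 1])
    in_eddy[, k + 1] <- !is.na(owp) & owp < -0.2 * sd_ow
  }
  out <- rep(NA_integer_, np)
  ok <- tr$status == "ok"
  out[ok] <- apply(in_eddy[ok, , drop = FALSE], 1, function(z) {
    r <- rle(z)
    if (!r$values[1]) 0L else min(r$lengths[1], window)
  })
  out
}

#' Lagrangian flow-network betweenness
#'
#' Bins the domain into `node_size`-degree boxes and advects one particle
#' per box over two legs centered on t0: leg 1 from t0 - tau/2 to t0 (giving
#' transition indicators P1(a -> m)), leg 2 from t0 to t0 + tau/2 (giving
#' P2(m -> b)). The betweenness of node m is sum_{a,b} P1(a -> m) P2(m -> b),
#' normalized to sum 1 over nodes: boxes that both receive water from many
#' origins and pass it onward score high (circulation bottlenecks).
#'
#' @param field A `velocity_field`.
#' @param t0 Center day.
#' @param tau Total advective window, days (each leg is tau / 2).
#' @param node_size Box size, degrees (defaults to the grid resolution).
#' @return A `flow_network`: list with `betweenness` (matrix over boxes,
#'   sums to 1), `box_lon`, `box_lat` (box centers), `tau`.
#' @export
flow_network_betweenness <- function(field, t0, tau, node_size = NULL) {
  if (is.null(node_size)) node_size <- field$lon[2] - field$lon[1]
  half <- tau / 2
  box_lon <- seq(field$lon[1] + node_size / 2, max(field$lon), by = node_size)
  box_lat <- seq(field$lat[1] + node_size / 2, max(field$lat), by = node_size)
  seeds <- expand.grid(lon = box_lon, lat = box_lat)
  box_of <- function(lon, lat) {
    i <- floor((lon - field$lon[1]) / node_size) + 1L
    j <- floor((lat - field$lat[1]) / node_size) + 1L
    ok <- !is.na(lon) & i >= 1 & i <= length(box_lon) &
          j >= 1 & j <= length(box_lat)
    ifelse(ok, i + (j - 1L) * length(box_lon), NA_integer_)
  }
  leg1 <- advect(seeds, field, t0 - half, half, direction = "forward")
  leg2 <- advect(seeds, field, t0, half, direction = "forward")
  if (all(leg1$status != "ok") || all(leg2$status != "ok")) {
    stop("flow-network legs lost every particle")
  }
  last <- ncol(leg1$lon)
  nb <- length(box_lon) * length(box_lat)
  # incoming mass: leg-1 particles landing in each box at t0
  dest1 <- box_of(leg1$lon[, last], leg1$lat[, last])
  dest1[leg1$status != "ok"] <- NA
  incoming <- tabulate(dest1[!is.na(dest1)], nbins = nb)
  # outgoing mass: each box's own particle surviving leg 2
  outgoing <- as.numeric(leg2$status == "ok" &
                         !is.na(box_of(leg2$lon[, last], leg2$lat[, last])))
  betw <- incoming * outgoing
  if (sum(betw) == 0) stop("flow network is empty: no connected paths")
  betw <- betw / sum(betw)
  structure(list(betweenness = matrix(betw, length(box_lon), length(box_lat)),
                 box_lon = box_lon, box_lat = box_lat, tau = tau,
                 node_size = node_size),
            class = "flow_network")
}

# betweenness of the box containing each position
network_value_at <- function(net, lon, lat) {
  i <- floor((lon - (net$box_lon[1] - net$node_size / 2)) / net$node_size) + 1L
  j <- floor((lat - (net$box_lat[1] - net$node_size / 2)) / net$node_size) + 1L
  ok <- !is.na(lon) & i >= 1 & i <= length(net$box_lon) &
        j >= 1 & j <= length(net$box_lat)
  out <- rep(NA_real_, length(lon))
  out[ok] <- net$betweenness[cbind(i[ok], j[ok])]
  out
}

summary_row <- function(diag, tau, values) {
  v <- values[!is.na(values)]
  n_ok <- length(v)
  if (n_ok < 4 || n_ok < 0.5 * length(values)) {
    return(data.frame(diagnostic = diag, tau_days = tau, mean = NA_real_,
                      p25 = NA_real_, p50 = NA_real_, p75 = NA_real_,
                      n_ok = n_ok))
  }
  q <- pctl(v, c(0.25, 0.5, 0.75))
  data.frame(diagnostic = diag, tau_days = tau, mean = mean(v),
             p25 = q[1], p50 = q[2], p75 = q[3], n_ok = n_ok)
}

#' Station-level Eulerian and Lagrangian diagnostics
#'
#' Seeds the station's stadium region, evaluates the five Eulerian
#' diagnostics at the sampling day (interpolated to the particles) and the
#' Lagrangian diagnostics per advective time, and reduces each to four
#' values: mean and 25/50/75 percentiles over the surviving particles.
#' Retention time is computed only at the largest advective time. Statistics
#' are withheld (missing) when fewer than 4 particles survive or more than
#' half are lost.
#'
#' @param spec A [stadium_spec()].
#' @param field A `velocity_field`.
#' @param t0 Sampling day.
#' @param tau_list Advective times, days (default 5, 10, 15, 20, 30, 60).
#' @param station_id Identifier carried into the output.
#' @param node_size Betweenness box size, degrees (grid resolution when
#'   NULL).
#' @return A `station_diagnostics` data frame with columns `station_id`,
#'   `diagnostic`, `tau_days` (NA for Eulerian rows), `mean`, `p25`, `p50`,
#'   `p75`, `n_ok`.
#' @export
station_diagnostics <- function(spec, field, t0,
                                tau_list = c(5, 10, 15, 20, 30, 60),
                                station_id = "ST-01", node_size = NULL) {
  particles <- seed_stadium(spec)
  t_grid <- if (field$steady) field$time[1] else
    field$time[which.min(abs(field$time - t0))]
  ef <- eulerian_fields(field, t_grid)
  rows <- list()
  for (nm in c("uabs", "ekin", "diverg", "vorticity", "ow")) {
    vals <- grid_interp(ef[[nm]], field$lon, field$lat,
                        particles$lon, particles$lat)
    lab <- c(uabs = "Uabs", ekin = "Ekin", diverg = "EulerDiverg",
             vorticity = "Vorticity", ow = "OW")[[nm]]
    rows[[length(rows) + 1]] <- summary_row(lab, NA_real_, vals)
  }
  for (tau in sort(tau_list)) {
    rows[[length(rows) + 1]] <-
      summary_row("Ftle", tau, ftle(particles, field, t0, tau,
                                    spacing = spec$spacing))
    tr <- advect(particles, field, t0, tau, direction = "backward")
    rows[[length(rows) + 1]] <-
      summary_row("LagrDiverg", tau, lagrangian_divergence(tr, field))
    net <- flow_network_betweenness(field, t0, tau, node_size)
    rows[[length(rows) + 1]] <-
      summary_row("betw", tau, network_value_at(net, particles$lon,
                                                particles$lat))
  }
  tmax <- max(tau_list)
  rows[[length(rows) + 1]] <-
    summary_row("RetentionTime", tmax,
                retention_time(particles, field, t0, window = tmax))
  out <- do.call(rbind, rows)
  if (all(is.na(out$mean))) stop("all particles lost: no diagnostics available")
  out <- cbind(station_id = station_id, out)
  class(out) <- c("station_diagnostics", "data.frame")
  out
}
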