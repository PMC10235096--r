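# Independent brute-force oracles used across the test files. These are kept
# deliberately naive (double loops, explicit enumeration) so they share no
# code path with the implementation they check.

# O(n * w) trailing-window exceedance count, inclusive of the current day.
brute_rolling_count <- function(values, threshold, direction, window = 364L) {
  n <- length(values)
  vapply(seq_len(n), function(i) {
    w <- values[max(1, i - window + 1):i]
    w <- w[!is.na(w)]
    if (direction == "ge") sum(w >= threshold) else sum(w <= threshold)
  }, numeric(1))
}

# O(n * w) degree heating/cooling weeks.
brute_degree_weeks <- function(tsa, threshold = 1, window = 84L, mode = "heat") {
  n <- length(tsa)
  vapply(seq_len(n), function(i) {
    w <- tsa[max(1, i - window + 1):i]
    w <- w[!is.na(w)]
    q <- if (mode == "heat") w[w >= threshold] else w[w <= -threshold]
    sum(q) / 7
  }, numeric(1))
}

# Linear interpolation between closest order statistics, written out long-hand.
brute_percentile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 1) return(rep(x, length(p)))
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Haversine from the closed form, independent of geosphere.
brute_haversine_km <- function(lon1, lat1, lon2, lat2, r = 6371) {
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlmb <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlmb / 2)^2
  2 * r * asin(sqrt(a))
}

# Brute-force stadium membership over an explicit lattice.
brute_stadium_count <- function(a, b, radius, spacing) {
  lon_lo <- min(a[1], b[1]) - radius; lon_hi <- max(a[1], b[1]) + radius
  lat_lo <- min(a[2], b[2]) - radius; lat_hi <- max(a[2], b[2]) + radius
  gx <- a[1] + seq(floor((lon_lo - a[1]) / spacing),
                   ceiling((lon_hi - a[1]) / spacing)) * spacing
  gy <- a[2] + seq(floor((lat_lo - a[2]) / spacing),
                   ceiling((lat_hi - a[2]) / spacing)) * spacing
  count <- 0L
  for (x in gx) for (y in gy) {
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    t <- if (len2 == 0) 0 else max(0, min(1, ((x - a[1]) * abx + (y - a[2]) * aby) / len2))
    d <- sqrt((x - (a[1] + t * abx))^2 + (y - (a[2] + t * aby))^2)
    if (d <= radius + 1e-12) count <- count + 1L
  }
  count
}

# Greedy centroid station clustering, re-derived independently.
brute_assign_station <- function(events, max_km = 75, max_days = 0.25) {
  n <- nrow(events)
  id <- integer(n)
  next_id <- 0L
  cl <- list()
  for (i in seq_len(n)) {
    joined <- FALSE
    if (next_id > 0) {
      k <- next_id
      cx <- mean(events$lon[cl[[k]]]); cy <- mean(events$lat[cl[[k]]])
      ct <- mean(as.numeric(events$time[cl[[k]]]))
      if (brute_haversine_km(events$lon[i], events$lat[i], cx, cy) <= max_km &&
          abs(as.numeric(events$time[i]) - ct) <= max_days) {
        cl[[k]] <- c(cl[[k]], i); id[i] <- k; joined <- TRUE
      }
    }
    if (!joined) {
      next_id <- next_id + 1L
      cl[[next_id]] <- i
      id[i] <- next_id
    }
  }
  sys <- if ("systematic" %in% names(events)) events$systematic else rep(TRUE, n)
  sizes <- tabulate(id)
  id[sizes[id] == 1L & !sys] <- 0L
  kept <- unique(id[id > 0L])
  id[id > 0L] <- match(id[id > 0L], kept)
  id
}

# Splice two velocity fields in time: field `before` for days < t_switch,
# `after` at days >= t_switch (grids must match). Produces an unsteady field.
splice_fields <- function(before, after, t_switch) {
  stopifnot(identical(before$lon, after$lon), identical(before$lat, after$lat),
            identical(before$time, after$time))
  u <- before$u; v <- before$v
  k <- which(before$time >= t_switch)
  u[, , k] <- after$u[, , k]
  v[, , k] <- after$v[, , k]
  structure(list(lon = before$lon, lat = before$lat, time = before$time,
                 u = u, v = v, steady = FALSE, truth = NULL, scenario = NULL),
            class = "velocity_field")
}
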