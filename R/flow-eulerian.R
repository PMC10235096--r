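# Eulerian diagnostics on a gridded velocity field.

#' Eulerian diagnostics at one day
#'
#' Computes, at every grid node: absolute velocity `uabs = sqrt(u^2 + v^2)`
#' (m s^-1), kinetic energy `ekin = 0.5 (u^2 + v^2)` (m^2 s^-2), divergence
#' `du/dx + dv/dy` and vorticity `dv/dx - du/dy` (d^-1), the shear/strain
#' term `s2 = (du/dx - dv/dy)^2 + (dv/dx + du/dy)^2` (d^-2), and the
#' Okubo-Weiss parameter `ow = s2 - vorticity^2` (d^-2; negative inside
#' eddies). Derivatives are centered finite differences (one-sided at the
#' domain edges) on a spherical metric: meters per degree of longitude are
#' scaled by cos(lat), Earth radius 6371 km. Nodes with missing velocities
#' propagate missing diagnostics.
#'
#' @param field A `velocity_field`.
#' @param day Time (days) at which to evaluate; must match a stored step.
#' @return An `eulerian_fields` list of nlon x nlat matrices: `uabs`,
#'   `ekin`, `diverg`, `vorticity`, `s2`, `ow`, plus `lon`, `lat`.
#' @export
eulerian_fields <- function(field, day = field$time[1]) {
  stopifnot(inherits(field, "velocity_field"))
  k <- if (field$steady) 1L else match(day, field$time)
  if (is.na(k)) stop("day ", day, " is not a stored time step")
  u <- field$u[, , k]
  v <- field$v[, , k]
  lon <- field$lon; lat <- field$lat
  dlon <- lon[2] - lon[1]; dlat <- lat[2] - lat[1]

  # centered differences along a matrix dimension, one-sided at edges
  ddx1 <- function(m) { # along rows (lon)
    n <- nrow(m)
    out <- m
    out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
    out[1, ] <- m[2, ] - m[1, ]
    out[n, ] <- m[n, ] - m[n - 1, ]
    out
  }
  ddy1 <- function(m) t(ddx1(t(m)))

  dx_m <- METERS_PER_DEGREE * dlon * matrix(cos(lat * pi / 180),
                                            nrow(u), ncol(u), byrow = TRUE)
  dy_m <- METERS_PER_DEGREE * dlat

  dudx <- ddx1(u) / dx_m; dudy <- ddy1(u) / dy_m
  dvdx <- ddx1(v) / dx_m; dvdy <- ddy1(v) / dy_m

  day_s <- 86400
  diverg <- (dudx + dvdy) * day_s
  vorticity <- (dvdx - dudy) * day_s
  s2 <- ((dudx - dvdy) * day_s)^2 + ((dvdx + dudy) * day_s)^2
  structure(list(uabs = sqrt(u^2 + v^2), ekin = 0.5 * (u^2 + v^2),
                 diverg = diverg, vorticity = vorticity, s2 = s2,
                 ow = s2 - vorticity^2, lon = lon, lat = lat),
            class = "eulerian_fields")
}

# Bilinear interpolation of a node-valued matrix at point positions.
grid_interp <- function(mat, lon, lat, plon, plat) {
  out <- rep(NA_real_, length(plon))
  inside <- plon >= lon[1] & plon <= lon[length(lon)] &
            plat >= lat[1] & plat <= lat[length(lat)] &
            !is.na(plon) & !is.na(plat)
  if (!any(inside)) return(out)
  i <- pmin(findInterval(plon[inside], lon), length(lon) - 1L)
  j <- pmin(findInterval(plat[inside], lat), length(lat) - 1L)
  wx <- (plon[inside] - lon[i]) / (lon[2] - lon[1])
  wy <- (plat[inside] - lat[j]) / (lat[2] - lat[1])
  nlon <- length(lon)
  id <- function(ii, jj) ii + (jj - 1L) * nlon
  out[inside] <- mat[id(i, j)] * (1 - wx) * (1 - wy) +
    mat[id(i + 1L, j)] * wx * (1 - wy) +
    mat[id(i, j + 1L)] * (1 - wx) * wy +
    mat[id(i + 1L, j + 1L)] * wx * wy
  out
}
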