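# Flow diagnostics: stadium seeding, Eulerian fields, advection, FTLE,
# Lagrangian divergence, retention time, betweenness, station statistics.

interior <- function(f) 2:(length(f$lon) - 1)

test_that("stadium seeding matches brute-force membership enumeration", {
  # degenerate transect: a disc
  disc <- seed_stadium(stadium_spec(c(0, 0), c(0, 0), radius = 0.1,
                                    spacing = 0.01))
  expect_equal(nrow(disc), brute_stadium_count(c(0, 0), c(0, 0), 0.1, 0.01))
  # long transect: area formula within 5% of enumeration
  sp <- stadium_spec(c(0, 0), c(1, 0), radius = 0.1, spacing = 0.01)
  st <- seed_stadium(sp)
  expect_equal(nrow(st), brute_stadium_count(c(0, 0), c(1, 0), 0.1, 0.01))
  analytic <- (pi * 0.1^2 + 2 * 0.1 * 1) / 0.01^2
  expect_lt(abs(nrow(st) - analytic) / analytic, 0.05)
  # every retained particle satisfies the membership predicate
  d <- sqrt(pmin((st$lon - 0)^2, (st$lon - 1)^2) + st$lat^2)
  on_segment <- st$lon >= 0 & st$lon <= 1
  dist <- ifelse(on_segment, abs(st$lat), d)
  expect_true(all(dist <= 0.1 + 1e-9))
  expect_error(seed_stadium(stadium_spec(c(0, 0), radius = 1e-9,
                                         spacing = 1e-9)),
               NA) # tiny but non-degenerate disc still has its anchor point
})

test_that("Eulerian diagnostics match analytic truth on all test fields", {
  fsb <- generate_velocity_field(flow_scenario("solid_body",
                                               params = list(omega = 0.1)))
  ef <- eulerian_fields(fsb)
  i <- interior(fsb)
  expect_lt(max(abs(ef$vorticity[i, i] - 0.2)), 1e-3)
  expect_lt(max(abs(ef$diverg[i, i])), 1e-3)
  expect_lt(max(abs(ef$ow[i, i] + 0.04)), 1e-3)

  fst <- generate_velocity_field(flow_scenario("strain",
                                               params = list(sigma = 0.1)))
  efs <- eulerian_fields(fst)
  expect_lt(max(abs(efs$ow[i, i] - 0.04)), 1e-3)
  expect_lt(max(abs(efs$vorticity[i, i])), 1e-3)

  fdv <- generate_velocity_field(flow_scenario("divergent",
                                               params = list(delta = 0.05)))
  efd <- eulerian_fields(fdv)
  expect_lt(max(abs(efd$diverg[i, i] - 0.05)), 1e-3)

  fun <- generate_velocity_field(flow_scenario("uniform",
                                               params = list(u = 0.5, v = 0)))
  efu <- eulerian_fields(fun)
  expect_equal(unique(as.numeric(efu$uabs)), 0.5)
  expect_equal(unique(as.numeric(efu$ekin)), 0.125)
  expect_true(all(abs(efu$diverg) < 1e-12))
})

test_that("Okubo-Weiss identity holds exactly at every node", {
  for (kind in c("solid_body", "strain", "divergent", "double_gyre")) {
    f <- generate_velocity_field(flow_scenario(kind))
    ef <- eulerian_fields(f)
    expect_equal(ef$ow, ef$s2 - ef$vorticity^2, tolerance = 1e-12, info = kind)
  }
})

test_that("advection reproduces uniform displacement and conserves rotation", {
  fu <- generate_velocity_field(flow_scenario("uniform",
                                              params = list(u = 0.5, v = 0),
                                              lon_range = c(-3, 6),
                                              n_days = 12))
  tr <- advect(data.frame(lon = 0, lat = 0), fu, t0 = 0, tau = 10,
               direction = "forward")
  expect_equal(tr$lon[1, 11], 0.5 * 86400 * 10 / (6371000 * pi / 180),
               tolerance = 1e-3)
  expect_lt(abs(tr$lat[1, 11]), 1e-9)

  fsb <- generate_velocity_field(flow_scenario("solid_body",
                                               params = list(omega = 0.1)))
  tr2 <- advect(data.frame(lon = 0.5, lat = 0), fsb, t0 = 60, tau = 60,
                direction = "backward")
  r <- sqrt(tr2$lon[1, ]^2 + tr2$lat[1, ]^2)
  expect_lt(max(abs(r - 0.5)) / 0.5, 0.001)
})

test_that("forward-then-backward advection returns to the start", {
  for (kind in c("solid_body", "strain", "double_gyre")) {
    f <- generate_velocity_field(flow_scenario(kind))
    p0 <- data.frame(lon = c(0.3, -0.5, 0.1), lat = c(0.2, 0.4, -0.6))
    fw <- advect(p0, f, t0 = 10, tau = 5, direction = "forward")
    last <- ncol(fw$lon)
    p1 <- data.frame(lon = fw$lon[, last], lat = fw$lat[, last])
    bw <- advect(p1, f, t0 = 15, tau = 5, direction = "backward")
    expect_lt(max(abs(bw$lon[, ncol(bw$lon)] - p0$lon),
                  abs(bw$lat[, ncol(bw$lat)] - p0$lat)), 1e-3, )
  }
})

test_that("particles exiting the grid are flagged and frozen", {
  fu <- generate_velocity_field(flow_scenario("uniform",
                                              params = list(u = 1.5, v = 0)))
  tr <- advect(data.frame(lon = 2.0, lat = 0), fu, t0 = 0, tau = 10,
               direction = "forward")
  expect_equal(tr$status, "left_domain")
  expect_error(advect(data.frame(lon = 0, lat = 0),
                      generate_velocity_field(flow_scenario("uniform",
                                                            n_days = 5,
                                                            steady = FALSE)),
                      t0 = 0, tau = 10, direction = "forward"),
               "outside the field span")
})

test_that("FTLE equals the strain rate in a linear strain flow", {
  fst <- generate_velocity_field(flow_scenario("strain",
                                               params = list(sigma = 0.1)))
  p <- data.frame(lon = c(0, 0.2, -0.1), lat = c(0, -0.2, 0.15))
  for (tau in c(5, 20)) { # backward stretching e^(sigma tau) must stay in-domain
    v <- ftle(p, fst, t0 = 60, tau = tau)
    expect_lt(max(abs(v - 0.1)), 0.002)
  }
  # uniform flow: no stretching (on the equator; off-equator the cos(lat)
  # metric induces a weak real shear, bounded separately)
  fu <- generate_velocity_field(flow_scenario("uniform",
                                              params = list(u = 0.1, v = 0)))
  peq <- data.frame(lon = c(0, 0.5, -0.5), lat = 0)
  expect_lt(max(abs(ftle(peq, fu, t0 = 60, tau = 10))), 1e-6)
  expect_lt(max(abs(ftle(p, fu, t0 = 60, tau = 10))), 1e-5)
  # rotation is an isometry
  fsb <- generate_velocity_field(flow_scenario("solid_body"))
  expect_lt(max(abs(ftle(p, fsb, t0 = 60, tau = 30))), 5e-3)
})

test_that("Lagrangian divergence time-averages the Eulerian divergence", {
  fdv <- generate_velocity_field(flow_scenario("divergent",
                                               params = list(delta = 0.05)))
  p <- data.frame(lon = c(0.05, -0.02), lat = c(0.02, 0.04))
  for (tau in c(5, 20)) {
    tr <- advect(p, fdv, t0 = 60, tau = tau, direction = "backward")
    expect_lt(max(abs(lagrangian_divergence(tr, fdv) - 0.05)), 0.002)
  }
  # divergence-free field
  fst <- generate_velocity_field(flow_scenario("strain"))
  trs <- advect(p, fst, t0 = 60, tau = 10, direction = "backward")
  expect_lt(max(abs(lagrangian_divergence(trs, fst))), 1e-3)
  # piecewise: divergent for the older half-window, quiescent after
  f0 <- generate_velocity_field(flow_scenario("uniform",
                                              params = list(u = 0, v = 0),
                                              n_days = 11, steady = FALSE))
  fdyn <- generate_velocity_field(flow_scenario("divergent",
                                                params = list(delta = 0.05),
                                                n_days = 11, steady = FALSE))
  spliced <- splice_fields(fdyn, f0, t_switch = 5.5)
  trp <- advect(data.frame(lon = 0.01, lat = 0.01), spliced, t0 = 10,
                tau = 10, direction = "backward")
  expect_lt(abs(lagrangian_divergence(trp, spliced) - 0.025), 0.005)
})

test_that("retention time counts consecutive days inside an eddy", {
  fsb <- generate_velocity_field(flow_scenario("solid_body",
                                               params = list(omega = 0.1,
                                                             core_radius = 1)))
  # core particle: inside the vortex the whole 60-day window
  expect_equal(retention_time(data.frame(lon = 0.05, lat = 0), fsb, t0 = 60),
               60L)
  # strain-dominated region: OW > 0, retention zero (particle near the
  # contracting axis so the backward trajectory stays in-domain)
  fst <- generate_velocity_field(flow_scenario("strain"))
  expect_equal(retention_time(data.frame(lon = 0.3, lat = 1e-3), fst, t0 = 60),
               0L)
  # vortex switched on k days before sampling: retention = k +/- 1
  k <- 20
  f0 <- generate_velocity_field(flow_scenario("uniform",
                                              params = list(u = 0, v = 0),
                                              n_days = 61, steady = FALSE))
  fon <- generate_velocity_field(flow_scenario("solid_body",
                                               params = list(omega = 0.1,
                                                             core_radius = 1),
                                               n_days = 61, steady = FALSE))
  spliced <- splice_fields(f0, fon, t_switch = 60 - k)
  rt <- retention_time(data.frame(lon = 0.05, lat = 0), spliced, t0 = 60)
  expect_lte(abs(rt - k), 1)
})

test_that("betweenness is normalized and uniform under uniform flow", {
  fu <- generate_velocity_field(flow_scenario("uniform",
                                              params = list(u = 0.2, v = 0)))
  net <- flow_network_betweenness(fu, t0 = 30, tau = 10)
  expect_equal(sum(net$betweenness), 1, tolerance = 1e-9)
  pos <- net$betweenness[net$betweenness > 0]
  expect_lt(diff(range(pos)), 1e-12)
})

test_that("betweenness equals the explicit two-leg double sum", {
  f <- generate_velocity_field(flow_scenario("double_gyre",
                                             params = list(A = 0.15),
                                             resolution = 0.5,
                                             n_days = 30, steady = FALSE))
  tau <- 10; t0 <- 15
  node <- 0.5
  net <- flow_network_betweenness(f, t0, tau, node_size = node)
  # oracle: explicit transition tables from independently advected ensembles
  seeds <- expand.grid(lon = net$box_lon, lat = net$box_lat)
  nb <- nrow(seeds)
  box_of <- function(lon, lat) {
    i <- floor((lon - f$lon[1]) / node) + 1L
    j <- floor((lat - f$lat[1]) / node) + 1L
    ok <- !is.na(lon) & i >= 1 & i <= length(net$box_lon) &
          j >= 1 & j <= length(net$box_lat)
    ifelse(ok, i + (j - 1L) * length(net$box_lon), NA_integer_)
  }
  P1 <- matrix(0, nb, nb); P2 <- matrix(0, nb, nb)
  l1 <- advect(seeds, f, t0 - tau / 2, tau / 2, direction = "forward")
  l2 <- advect(seeds, f, t0, tau / 2, direction = "forward")
  d1 <- box_of(l1$lon[, ncol(l1$lon)], l1$lat[, ncol(l1$lat)])
  d2 <- box_of(l2$lon[, ncol(l2$lon)], l2$lat[, ncol(l2$lat)])
  for (a in seq_len(nb)) {
    if (l1$status[a] == "ok" && !is.na(d1[a])) P1[a, d1[a]] <- 1
    if (l2$status[a] == "ok" && !is.na(d2[a])) P2[a, d2[a]] <- 1
  }
  betw_oracle <- vapply(seq_len(nb), function(m) {
    sum(P1[, m]) * sum(P2[m, ])
  }, numeric(1))
  betw_oracle <- betw_oracle / sum(betw_oracle)
  expect_equal(as.numeric(net$betweenness), betw_oracle, tolerance = 1e-12)
})

test_that("station diagnostics summarize particles with ordered percentiles", {
  sp <- stadium_spec(c(0, 0), c(0.2, 0), spacing = 0.02)
  fu <- generate_velocity_field(flow_scenario("uniform",
                                              params = list(u = 0.3, v = 0.1)))
  tab <- station_diagnostics(sp, fu, t0 = 30, tau_list = c(5, 10),
                             station_id = "OA-TEST")
  # uniform field: all particle values equal, so mean = p25 = p50 = p75
  eul <- tab[tab$diagnostic %in% c("Uabs", "Ekin"), ]
  expect_equal(eul$mean, eul$p25, tolerance = 1e-9)
  expect_equal(eul$p25, eul$p75, tolerance = 1e-9)
  expect_equal(tab$mean[tab$diagnostic == "Uabs"], sqrt(0.3^2 + 0.1^2),
               tolerance = 1e-9)
  # exactly four summary statistics per diagnostic per tau
  expect_true(all(c("mean", "p25", "p50", "p75") %in% names(tab)))
  expect_true(all(tab$p25 <= tab$p50 & tab$p50 <= tab$p75, na.rm = TRUE))
  # retention only at the largest advective time
  rt <- tab[tab$diagnostic == "RetentionTime", ]
  expect_equal(rt$tau_days, 10)
  # Lagrangian values coincide across tau in steady uniform flow
  ft <- tab[tab$diagnostic == "Ftle", ]
  expect_equal(ft$mean[1], ft$mean[2], tolerance = 1e-5)
  ld <- tab[tab$diagnostic == "LagrDiverg", ]
  expect_equal(ld$mean[1], ld$mean[2], tolerance = 1e-5)
})

test_that("station percentiles agree with a brute-force order-statistic fit", {
  set.seed(3)
  v <- rnorm(37)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_equal(q, brute_percentile(v, c(0.25, 0.5, 0.75)))
})
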