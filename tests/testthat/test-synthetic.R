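# Scenario generators: annual raster, station series, road network,
# trajectories and ground truth.

test_that("annual raster is background plus hotspots and is deterministic", {
  sc <- mini_config(hotspots = data.frame(lon = numeric(0), lat = numeric(0),
                                          amplitude = numeric(0),
                                          sigma_deg = numeric(0)))
  g <- gen_annual_grid(sc)
  expect_true(all(g$values == sc$background))
  hs <- data.frame(lon = 114.25, lat = 30.55, amplitude = 30, sigma_deg = 0.04)
  sc2 <- mini_config(hotspots = hs)
  g2 <- gen_annual_grid(sc2)
  i <- which(g2$values == max(g2$values), arr.ind = TRUE)
  ctr <- dynexposure:::grid_cell_center(g2, i[1, 1], i[1, 2])
  expect_lt(abs(ctr[1] - hs$lon), 1.5 * sc2$cell_size)
  expect_lt(abs(ctr[2] - hs$lat), 1.5 * sc2$cell_size)
  expect_equal(max(g2$values), sc2$background + hs$amplitude, tolerance = 1e-2)
  expect_identical(gen_annual_grid(sc2)$values, g2$values)
  sc_bad <- mini_config(hotspots = data.frame(lon = 100, lat = 0,
                                              amplitude = 1, sigma_deg = 0.1))
  expect_error(gen_annual_grid(sc_bad), "outside")
})

test_that("station series share the temporal signal and honour the episode", {
  sc <- mini_config(n_days = 5, station_noise_sd = 0, diurnal = rep(1, 24),
                    episode = NULL)
  g <- gen_annual_grid(sc)
  st <- gen_station_series(sc, g)
  # flat multipliers, no noise: series equals the annual value at the station
  for (s in st)
    expect_equal(s$pm25, rep(grid_value(g, s$lon, s$lat), 5 * 24))
  # episode peak lands inside its window and reaches ~peak at a background cell
  sc2 <- mini_config(n_days = 5, station_noise_sd = 0, diurnal = rep(1, 24),
                     episode = list(start_day = 2, duration_days = 2, peak = 300),
                     hotspots = data.frame(lon = numeric(0), lat = numeric(0),
                                           amplitude = numeric(0),
                                           sigma_deg = numeric(0)))
  st2 <- gen_station_series(sc2, gen_annual_grid(sc2))
  s <- st2[[1]]
  peak_hour <- which.max(s$pm25)
  expect_true(peak_hour >= 25 && peak_hour <= 72)
  expect_equal(max(s$pm25), 300, tolerance = 0.05)
  # two noiseless stations on an uniform grid are perfectly correlated
  expect_equal(stats::cor(st2[[1]]$pm25, st2[[2]]$pm25), 1)
  # station outside the grid is a config error
  bad <- data.frame(station_id = "x", lon = 100, lat = 0)
  expect_error(gen_station_series(sc, g, bad), "outside")
})

test_that("lattice network has the expected size, lengths and connectivity", {
  sc <- mini_config(network = list(kind = "grid", nx = 3, ny = 3,
                                   spacing = 0.02, margin = 0.04))
  net <- gen_road_network(sc)
  expect_equal(nrow(net$nodes), 9L)
  expect_equal(nrow(net$edges), 12L)
  expect_true(dynexposure:::network_is_connected(net))
  # all edge lengths match the spacing within 0.1%
  lat_mid <- mean(net$nodes$lat)
  expect_true(all(abs(net$edges$length_m / (0.02 * 111194.9) - 1) < 0.15))
  horiz <- net$edges$length_m[abs(net$edges$length_m -
                                    0.02 * dynexposure:::m_per_deg_lon(lat_mid)) < 50]
  expect_true(length(horiz) >= 6)
  r <- gen_road_network(mini_config(network = list(kind = "radial",
                                                   spacing = 0.02,
                                                   n_spokes = 6, n_rings = 3)))
  expect_true(dynexposure:::network_is_connected(r))
  expect_equal(nrow(r$nodes), 1L + 6L * 3L)
})

test_that("trajectories are deterministic, on-network at zero noise, and span the days", {
  sc <- mini_config(n_taxis = 5, n_days = 2, gps_noise_sigma_m = 0)
  net <- gen_road_network(sc)
  sim <- gen_trajectories(sc, net)
  expect_equal(length(unique(sim$fixes$taxi_id)), 5L)
  expect_equal(length(unique(as.Date(sim$fixes$time))), 2L)
  # zero noise: every fix lies on an edge (lattice edges are lon/lat lines)
  on_lon <- vapply(sim$fixes$lon, function(x)
    any(abs(x - net$nodes$lon) < 1e-9), logical(1))
  on_lat <- vapply(sim$fixes$lat, function(x)
    any(abs(x - net$nodes$lat) < 1e-9), logical(1))
  expect_true(all(on_lon | on_lat))
  sim2 <- gen_trajectories(sc, net)
  expect_identical(sim2$fixes, sim$fixes)
  expect_identical(sim2$truth$trips$ei, sim$truth$trips$ei)
})

test_that("ground-truth exposure matches the closed form on a constant field", {
  f <- constant_field(80)
  sc <- mini_config(gps_noise_sigma_m = 0,
                    extent = c(lon_min = 114, lat_min = 30.3,
                               lon_max = 114.2, lat_max = 30.5),
                    network = list(kind = "grid", nx = 5, ny = 5,
                                   spacing = 0.02, margin = 0.04))
  net <- gen_road_network(sc)
  sim <- gen_trajectories(sc, net, f, lambda = 1)
  tt <- sim$truth$trips
  expect_equal(tt$ei, 80 * tt$duration_h, tolerance = 1e-9)
  expect_equal(tt$twa, rep(80, nrow(tt)), tolerance = 1e-9)
  # lambda scales EI linearly
  sim2 <- gen_trajectories(sc, net, f, lambda = 0.5)
  expect_equal(sim2$truth$trips$ei, tt$ei / 2, tolerance = 1e-9)
})

test_that("ground-truth Riemann integration is stable under step halving", {
  s <- mini_scenario()
  tt <- s$truth$trips[1:10, ]
  for (k in seq_len(nrow(tt))) {
    path <- s$truth$paths[[tt$taxi_id[k]]]
    t_a <- as.numeric(tt$time_start[k]) - as.numeric(path$t0)
    t_b <- as.numeric(tt$time_end[k]) - as.numeric(path$t0)
    e1 <- true_exposure(path, s$field, t_a, t_b, step_s = 1)
    e05 <- true_exposure(path, s$field, t_a, t_b, step_s = 0.5)
    expect_lt(abs(e1 - e05) / e05, 1e-4)
  }
})
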