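# Shared fixtures, built in code. The "mini" scenario (2 taxis, 1 day) keeps
# unit tests fast; pieces are cached per test run since generation is
# deterministic under the configured seed.

mini_config <- function(...) {
  args <- utils::modifyList(list(n_taxis = 2, n_days = 1, seed = 42L),
                            list(...), keep.null = TRUE)
  do.call(scenario_config, args)
}

.scenario_cache <- new.env(parent = emptyenv())

mini_scenario <- function() {
  if (is.null(.scenario_cache$mini)) {
    sc <- mini_config()
    grid <- gen_annual_grid(sc)
    stations <- gen_station_series(sc, grid)
    net <- gen_road_network(sc)
    field <- concentration_field(grid, stations)
    sim <- gen_trajectories(sc, net, field)
    .scenario_cache$mini <- list(config = sc, grid = grid, stations = stations,
                                 net = net, field = field, fixes = sim$fixes,
                                 truth = sim$truth)
  }
  .scenario_cache$mini
}

mini_matched <- function() {
  if (is.null(.scenario_cache$matched)) {
    s <- mini_scenario()
    trips <- extract_trips(clean_fixes(s$fixes, s$config$extent))
    .scenario_cache$matched <- unlist(
      lapply(trips, map_match, network = s$net), recursive = FALSE)
  }
  .scenario_cache$matched
}

# A flat 3x3-degree-free constant grid for closed-form exposure checks.
constant_grid <- function(value = 50, n = 20, origin = c(114, 30.3),
                          cell = 0.01) {
  annual_grid(matrix(value, n, n), origin[1], origin[2], cell)
}

# A single-station constant series spanning `hours` hours.
constant_station <- function(value = 50, hours = 24, lon = 114.05,
                             lat = 30.35, id = "s1",
                             start = "2014-05-13") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  station_series(id, lon, lat, t0 + 3600 * (seq_len(hours) - 1),
                 rep(value, hours))
}

# Field whose fused value is constant everywhere/always.
constant_field <- function(value = 50, hours = 24, start = "2014-05-13") {
  concentration_field(constant_grid(value),
                      list(constant_station(value, hours = hours,
                                            start = start)))
}

# Hand-built two-node straight road along a parallel of latitude.
straight_network <- function(lat = 30.35, lon0 = 114.02, lon1 = 114.12) {
  road_network(
    nodes = data.frame(id = 1:2, lon = c(lon0, lon1), lat = lat),
    edges = data.frame(edge_id = 1L, from = 1L, to = 2L))
}

# A matched trip built directly (bypassing the matcher) from a timed
# straight-line path, for segmentation closed forms.
manual_trip <- function(lons, lats, times, taxi_id = "TX") {
  fx <- data.frame(taxi_id = taxi_id, time = times, lon = lons, lat = lats,
                   heading = 0, occupied = TRUE, stringsAsFactors = FALSE)
  tr <- dynexposure:::new_trip(taxi_id, fx)
  coords <- cbind(lon = lons, lat = lats)
  cum <- dynexposure:::polyline_cumdist_m(coords)
  tr$matched <- list(edge_ids = integer(0), fix_edge_ids = numeric(0),
                     fix_dist_m = cum, path_coords = coords, path_cum_m = cum)
  tr$distance_km <- cum[length(cum)] / 1000
  tr
}

local_time <- function(s, start = "2014-05-13") {
  as.POSIXct(paste(start, "00:00:00"), tz = "UTC") + s
}
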