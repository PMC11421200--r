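# Synthetic study scenario: a Wuhan-like 0.5 x 0.5 degree extent with an
# annual raster (smooth background + urban hotspots), nine stations sharing a
# diurnal cycle and a multi-day pollution episode peaking near 300 ug/m^3, a
# road lattice, and taxis emitting noisy GPS fixes along shortest-path routes
# with full ground truth for recovery tests.

#' Synthetic scenario configuration
#'
#' Desk-scale defaults: 50 taxis over 7 days on a 0.01-degree grid spanning a
#' ~0.5 x 0.5 degree extent, 10-s GPS sampling with 10-m isotropic noise,
#' 30 km/h travel, geometric occupied/vacant run lengths with means
#' 10 min / 5 min. The study-scale scenario (19 days, thousands of taxis,
#' episode on days 9-15) is reachable by overriding fields.
#'
#' @param extent named numeric: `lon_min`, `lat_min`, `lon_max`, `lat_max`.
#' @param cell_size annual-grid cell edge, degrees.
#' @param background background annual concentration, ug/m^3.
#' @param hotspots data.frame `lon, lat, amplitude, sigma_deg` of Gaussian
#'   concentration bumps added to the background.
#' @param n_taxis,n_days fleet size and study length.
#' @param start_date first study day (local), `"YYYY-MM-DD"`.
#' @param sampling_interval_s GPS fix spacing, seconds.
#' @param gps_noise_sigma_m isotropic GPS noise standard deviation, metres.
#' @param speed_kmh constant travel speed on all edges.
#' @param mean_occupied_s,mean_vacant_s mean geometric run lengths, seconds.
#' @param diurnal 24 hourly multipliers applied to station series.
#' @param episode list `start_day` (1-based), `duration_days`, `peak`
#'   (ug/m^3 reached by a background-level station at the episode apex).
#' @param station_noise_sd hourly measurement noise sd, ug/m^3.
#' @param stations data.frame `station_id, fx, fy` of station positions as
#'   fractions of the extent; default nine stations.
#' @param network list: `kind` ("grid" or "radial"), `nx`, `ny`, `spacing`
#'   (degrees), `margin` (degrees inset from the extent edge); for radial,
#'   `n_spokes` and `n_rings`.
#' @param seed integer RNG seed; identical seeds give byte-identical outputs.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(extent = c(lon_min = 114.0, lat_min = 30.3,
                                       lon_max = 114.5, lat_max = 30.8),
                            cell_size = 0.01,
                            background = 45.5,
                            hotspots = data.frame(
                              lon = c(114.28, 114.12),
                              lat = c(30.60, 30.42),
                              amplitude = c(30, 15),
                              sigma_deg = c(0.04, 0.05)),
                            n_taxis = 50, n_days = 7,
                            start_date = "2014-05-13",
                            sampling_interval_s = 10,
                            gps_noise_sigma_m = 10,
                            speed_kmh = 30,
                            mean_occupied_s = 600, mean_vacant_s = 300,
                            diurnal = c(1.15, 1.18, 1.20, 1.22, 1.20, 1.12,
                                        1.05, 1.02, 1.05, 1.08, 1.00, 0.92,
                                        0.85, 0.82, 0.80, 0.82, 0.85, 0.90,
                                        0.95, 1.00, 1.05, 1.08, 1.10, 1.12),
                            episode = list(start_day = 3, duration_days = 3,
                                           peak = 300),
                            station_noise_sd = 5,
                            stations = data.frame(
                              station_id = letters[1:9],
                              fx = c(0.77, 0.82, 0.28, 0.63, 0.63, 0.59,
                                     0.53, 0.15, 0.77),
                              fy = c(0.56, 0.45, 0.67, 0.47, 0.59, 0.64,
                                     0.58, 0.20, 0.66)),
                            network = list(kind = "grid", nx = 21, ny = 21,
                                           spacing = 0.02, margin = 0.04),
                            seed = 1L) {
  stopifnot(n_taxis >= 1, n_days >= 1, gps_noise_sigma_m >= 0,
            sampling_interval_s >= 1, length(diurnal) == 24)
  if (speed_kmh <= 0) stop("speed_kmh must be > 0", call. = FALSE)
  cfg <- list(extent = extent, cell_size = cell_size, background = background,
              hotspots = hotspots, n_taxis = as.integer(n_taxis),
              n_days = as.integer(n_days), start_date = start_date,
              sampling_interval_s = sampling_interval_s,
              gps_noise_sigma_m = gps_noise_sigma_m, speed_kmh = speed_kmh,
              mean_occupied_s = mean_occupied_s, mean_vacant_s = mean_vacant_s,
              diurnal = diurnal, episode = episode,
              station_noise_sd = station_noise_sd, stations = stations,
              network = network, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

scenario_start <- function(config) {
  as.POSIXct(paste(config$start_date, "00:00:00"), tz = STATION_TZ)
}

# Station lon/lat from fractional positions.
scenario_station_locations <- function(config) {
  e <- config$extent
  data.frame(station_id = config$stations$station_id,
             lon = e[["lon_min"]] + config$stations$fx * (e[["lon_max"]] - e[["lon_min"]]),
             lat = e[["lat_min"]] + config$stations$fy * (e[["lat_max"]] - e[["lat_min"]]),
             stringsAsFactors = FALSE)
}

#' Generate the synthetic annual concentration raster
#'
#' Smooth surface: constant background plus Gaussian bumps at the configured
#' hotspots, evaluated at cell centres. Deterministic (no randomness).
#'
#' @param config a [scenario_config()].
#' @return an [annual_grid()].
#' @export
gen_annual_grid <- function(config) {
  e <- config$extent; s <- config$cell_size
  n_cols <- round((e[["lon_max"]] - e[["lon_min"]]) / s)
  n_rows <- round((e[["lat_max"]] - e[["lat_min"]]) / s)
  hs <- config$hotspots
  if (!is.null(hs) && nrow(hs) > 0) {
    inside <- hs$lon >= e[["lon_min"]] & hs$lon <= e[["lon_max"]] &
      hs$lat >= e[["lat_min"]] & hs$lat <= e[["lat_max"]]
    if (!all(inside))
      stop("hotspot lies outside the scenario extent", call. = FALSE)
  }
  lon_c <- e[["lon_min"]] + (seq_len(n_cols) - 0.5) * s
  lat_c <- e[["lat_min"]] + (seq_len(n_rows) - 0.5) * s
  m <- matrix(config$background, nrow = n_rows, ncol = n_cols)
  if (!is.null(hs) && nrow(hs) > 0) {
    for (k in seq_len(nrow(hs))) {
      dx <- outer(rep(1, n_rows), (lon_c - hs$lon[k])^2)
      dy <- outer((lat_c - hs$lat[k])^2, rep(1, n_cols))
      m <- m + hs$amplitude[k] * exp(-(dx + dy) / (2 * hs$sigma_deg[k]^2))
    }
  }
  annual_grid(m, e[["lon_min"]], e[["lat_min"]], s)
}

# Shared hourly multipliers: diurnal cycle by hour of day times the pollution
# episode profile (raised cosine over the episode window, scaled so that a
# background-level station reaches `peak` at the apex).
scenario_hour_multipliers <- function(config) {
  n_h <- config$n_days * 24L
  hod <- (seq_len(n_h) - 1L) %% 24L
  diurnal <- config$diurnal[hod + 1L]
  ep <- config$episode
  mult_ep <- rep(1, n_h)
  if (!is.null(ep) && !is.null(ep$duration_days) && ep$duration_days > 0) {
    h0 <- (ep$start_day - 1) * 24
    h1 <- h0 + ep$duration_days * 24
    hrs <- seq_len(n_h) - 1L
    w <- ifelse(hrs >= h0 & hrs < h1,
                0.5 * (1 - cos(2 * pi * (hrs - h0) / (h1 - h0))), 0)
    mult_ep <- 1 + (ep$peak / config$background - 1) * w
  }
  diurnal * mult_ep
}

#' Generate hourly station series
#'
#' Each station's hourly value is its annual-grid value times the shared
#' diurnal and episode multipliers, plus Gaussian measurement noise, clipped
#' at zero. All stations share the temporal signal, emulating a monitoring
#' network with a consistent pattern of change over time.
#'
#' @param config a [scenario_config()].
#' @param grid the scenario's [annual_grid()].
#' @param station_locations data.frame `station_id, lon, lat`; defaults to
#'   the configured station positions.
#' @return named list of [station_series()].
#' @export
gen_station_series <- function(config, grid,
                               station_locations = scenario_station_locations(config)) {
  e <- config$extent
  out_of <- station_locations$lon < e[["lon_min"]] | station_locations$lon > e[["lon_max"]] |
    station_locations$lat < e[["lat_min"]] | station_locations$lat > e[["lat_max"]]
  if (any(out_of))
    stop(sprintf("station(s) outside grid extent: %s",
                 paste(station_locations$station_id[out_of], collapse = ", ")),
         call. = FALSE)
  mult <- scenario_hour_multipliers(config)
  t0 <- scenario_start(config)
  times <- t0 + (seq_along(mult) - 1L) * 3600
  set.seed(config$seed + 1L)
  out <- lapply(seq_len(nrow(station_locations)), function(k) {
    annual <- grid_value(grid, station_locations$lon[k], station_locations$lat[k])
    vals <- annual * mult +
      if (config$station_noise_sd > 0)
        stats::rnorm(length(mult), 0, config$station_noise_sd) else 0
    station_series(station_locations$station_id[k],
                   station_locations$lon[k], station_locations$lat[k],
                   times, pmax(vals, 0))
  })
  names(out) <- station_locations$station_id
  out
}

#' Generate the synthetic road network
#'
#' `kind = "grid"`: an nx-by-ny street lattice with the configured spacing,
#' inset from the extent edge by `margin`. `kind = "radial"`: spokes from a
#' central node crossed by concentric rings. Both are connected planar
#' networks with straight-segment edges.
#'
#' @param config a [scenario_config()].
#' @return a [road_network()].
#' @export
gen_road_network <- function(config) {
  e <- config$extent; nw <- config$network
  if (identical(nw$kind, "grid")) {
    nx <- nw$nx; ny <- nw$ny; sp <- nw$spacing
    lon0 <- e[["lon_min"]] + nw$margin; lat0 <- e[["lat_min"]] + nw$margin
    if (lon0 + (nx - 1) * sp > e[["lon_max"]] || lat0 + (ny - 1) * sp > e[["lat_max"]])
      stop("lattice does not fit inside the extent", call. = FALSE)
    id <- function(ix, iy) (iy - 1L) * nx + ix
    nodes <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
    nodes <- data.frame(id = id(nodes$ix, nodes$iy),
                        lon = lon0 + (nodes$ix - 1) * sp,
                        lat = lat0 + (nodes$iy - 1) * sp)
    nodes <- nodes[order(nodes$id), ]
    h <- expand.grid(ix = seq_len(nx - 1L), iy = seq_len(ny))
    v <- expand.grid(ix = seq_len(nx), iy = seq_len(ny - 1L))
    edges <- data.frame(
      from = c(id(h$ix, h$iy), id(v$ix, v$iy)),
      to = c(id(h$ix + 1L, h$iy), id(v$ix, v$iy + 1L)))
    edges$edge_id <- seq_len(nrow(edges))
    road_network(nodes, edges[, c("edge_id", "from", "to")])
  } else if (identical(nw$kind, "radial")) {
    n_sp <- if (is.null(nw$n_spokes)) 8L else nw$n_spokes
    n_ri <- if (is.null(nw$n_rings)) 4L else nw$n_rings
    sp <- nw$spacing
    cx <- (e[["lon_min"]] + e[["lon_max"]]) / 2
    cy <- (e[["lat_min"]] + e[["lat_max"]]) / 2
    ang <- 2 * pi * (seq_len(n_sp) - 1) / n_sp
    nodes <- data.frame(id = 1L, lon = cx, lat = cy)
    for (r in seq_len(n_ri))
      nodes <- rbind(nodes, data.frame(
        id = 1L + (r - 1L) * n_sp + seq_len(n_sp),
        lon = cx + r * sp * cos(ang), lat = cy + r * sp * sin(ang)))
    nid <- function(r, s) if (r == 0) 1L else 1L + (r - 1L) * n_sp + s
    edges <- NULL
    for (s in seq_len(n_sp)) for (r in seq_len(n_ri))
      edges <- rbind(edges, data.frame(from = nid(r - 1L, s), to = nid(r, s)))
    for (r in seq_len(n_ri)) for (s in seq_len(n_sp))
      edges <- rbind(edges, data.frame(from = nid(r, s),
                                       to = nid(r, if (s == n_sp) 1L else s + 1L)))
    edges$edge_id <- seq_len(nrow(edges))
    road_network(nodes, edges[, c("edge_id", "from", "to")])
  } else stop(sprintf("unknown network kind '%s'", nw$kind), call. = FALSE)
}

#' Generate taxi trajectories with ground truth
#'
#' Each taxi alternates vacant/occupied runs with geometric lengths; every
#' run chains shortest paths between random network nodes at constant speed,
#' so the taxi is always moving along the network. GPS fixes are emitted
#' every `sampling_interval_s` seconds as the true position plus isotropic
#' Gaussian noise. Ground truth records, per occupied run (trip), the true
#' edge sequence and the true exposure integral against `field`, plus each
#' taxi's exact continuous path (piecewise linear with constant speed) from
#' which positions at any time resolution can be reconstructed.
#'
#' @param config a [scenario_config()].
#' @param network the scenario [road_network()].
#' @param field a [concentration_field()] used for ground-truth exposure, or
#'   `NULL` to skip exposure truth.
#' @param lambda filtration coefficient used for ground-truth EI.
#' @return list with `fixes` (data.frame as from [read_trajectory_csv()]) and
#'   `truth` (a `ground_truth` object).
#' @export
gen_trajectories <- function(config, network, field = NULL, lambda = 1) {
  if (config$speed_kmh <= 0) stop("speed_kmh must be > 0", call. = FALSE)
  set.seed(config$seed + 2L)
  v <- config$speed_kmh / 3.6
  total_s <- config$n_days * 86400
  t0 <- scenario_start(config)
  node_ids <- network$nodes$id
  node_lon <- network$nodes$lon[order(network$nodes$id)]
  node_lat <- network$nodes$lat[order(network$nodes$id)]
  ids_sorted <- sort(node_ids)
  D <- node_distances(network)
  nid <- as.integer(rownames(D))
  node_row <- integer(max(nid)); node_row[nid] <- seq_along(nid)
  fixes_list <- vector("list", config$n_taxis)
  trip_rows <- list(); edge_seqs <- list(); paths <- list()
  n_trips <- 0L
  for (tx in seq_len(config$n_taxis)) {
    taxi_id <- sprintf("T%03d", tx)
    current <- sample(ids_sorted, 1L)
    node_seq <- current
    run_status <- logical(0); run_start <- numeric(0); run_end <- numeric(0)
    run_edges <- list()
    t_cur <- 0; occupied <- FALSE
    while (t_cur < total_s) {
      mean_s <- if (occupied) config$mean_occupied_s else config$mean_vacant_s
      target <- stats::rgeom(1L, 1 / mean_s) + 1
      rt <- 0; redges <- integer(0)
      while (rt < target) {
        # destination within the remaining-time reach so run lengths track
        # the sampled geometric target; fall back to the nearest node
        drow <- D[node_row[current], ]
        reach <- (target - rt) * v
        cand <- nid[drow > 0 & drow <= reach]
        dest <- if (length(cand) == 0L) {
          nid[drow > 0][which.min(drow[drow > 0])]
        } else if (length(cand) == 1L) cand else sample(cand, 1L)
        sp <- shortest_node_path(network, current, dest)
        node_seq <- c(node_seq, sp$nodes[-1])
        redges <- c(redges, sp$edge_ids)
        rt <- rt + sum(network$edges$length_m[match(sp$edge_ids, network$edges$edge_id)]) / v
        current <- dest
      }
      run_status <- c(run_status, occupied)
      run_start <- c(run_start, t_cur); run_end <- c(run_end, t_cur + rt)
      run_edges[[length(run_edges) + 1L]] <- redges
      t_cur <- t_cur + rt
      occupied <- !occupied
    }
    # continuous path: node polyline with constant speed (lattice edges are
    # straight, so node coordinates are the exact vertex stream)
    coords <- cbind(lon = node_lon[match(node_seq, ids_sorted)],
                    lat = node_lat[match(node_seq, ids_sorted)])
    cum <- polyline_cumdist_m(coords)
    paths[[taxi_id]] <- list(coords = coords, cum = cum, speed_mps = v,
                             t0 = t0, total_s = total_s)
    # fixes
    tf <- seq(0, total_s - 1e-6, by = config$sampling_interval_s)
    pos <- polyline_point_at(coords, cum, v * tf)
    ri <- findInterval(tf, run_start)
    occ <- run_status[ri]
    hd <- c(bearing_deg(pos[-nrow(pos), 1], pos[-nrow(pos), 2],
                        pos[-1, 1], pos[-1, 2]), 0)
    if (nrow(pos) >= 2L) hd[length(hd)] <- hd[length(hd) - 1L]
    lon <- pos[, 1]; lat <- pos[, 2]
    if (config$gps_noise_sigma_m > 0) {
      lon <- lon + stats::rnorm(length(lon), 0, config$gps_noise_sigma_m) / m_per_deg_lon(lat)
      lat <- lat + stats::rnorm(length(lat), 0, config$gps_noise_sigma_m) / m_per_deg_lat()
    }
    fixes_list[[tx]] <- data.frame(
      taxi_id = taxi_id, time = t0 + tf, lon = lon, lat = lat,
      heading = hd, occupied = occ, stringsAsFactors = FALSE)
    # ground-truth trips = occupied runs clipped to the study window
    occ_runs <- which(run_status & run_start < total_s)
    for (k in occ_runs) {
      n_trips <- n_trips + 1L
      t_a <- run_start[k]; t_b <- min(run_end[k], total_s)
      ed <- run_edges[[k]]
      ed <- ed[c(TRUE, diff(ed) != 0)]
      if (t_b < run_end[k]) {  # clipped: keep edges reachable before cutoff
        keep_m <- v * (t_b - t_a)
        lens <- network$edges$length_m[match(ed, network$edges$edge_id)]
        ed <- ed[cumsum(lens) - lens < keep_m]
      }
      ei <- NA_real_
      if (!is.null(field)) {
        ei <- true_exposure(paths[[taxi_id]], field, t_a, t_b,
                            step_s = 1, lambda = lambda)
      }
      dur_h <- (t_b - t_a) / 3600
      trip_rows[[n_trips]] <- data.frame(
        taxi_id = taxi_id, trip_idx = k, time_start = t0 + t_a,
        time_end = t0 + t_b, duration_h = dur_h, ei = ei,
        twa = if (is.na(ei)) NA_real_ else ei / (lambda * dur_h),
        stringsAsFactors = FALSE)
      edge_seqs[[n_trips]] <- ed
    }
  }
  truth <- structure(
    list(trips = do.call(rbind, trip_rows), edge_seqs = edge_seqs,
         paths = paths, lambda = lambda, step_s = 1),
    class = "ground_truth")
  fixes <- do.call(rbind, fixes_list)
  rownames(fixes) <- NULL
  list(fixes = fixes, truth = truth)
}

#' True positions along a taxi's continuous path
#'
#' @param path one element of `truth$paths`.
#' @param t_s times in seconds since scenario start.
#' @return matrix of lon/lat positions.
#' @export
true_positions <- function(path, t_s) {
  polyline_point_at(path$coords, path$cum, path$speed_mps * t_s)
}

#' Ground-truth exposure integral over a time window
#'
#' Midpoint Riemann sum of the fused concentration along the true path at
#' `step_s`-second steps, times the filtration coefficient. Units ug.h/m^3.
#'
#' @param path one element of `truth$paths`.
#' @param field a [concentration_field()].
#' @param t_a,t_b window bounds, seconds since scenario start.
#' @param step_s integration step, seconds.
#' @param lambda filtration coefficient.
#' @export
true_exposure <- function(path, field, t_a, t_b, step_s = 1, lambda = 1) {
  if (t_b <= t_a) return(0)
  brk <- unique(c(seq(t_a, t_b, by = step_s), t_b))
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  dt_h <- diff(brk) / 3600
  pos <- true_positions(path, mid)
  conc <- predict(field, pos[, 1], pos[, 2], path$t0 + mid)
  if (anyNA(conc))
    stop("ground-truth exposure window has hours with no usable base-station value",
         call. = FALSE)
  lambda * sum(conc * dt_h)
}

#' Match pipeline trips to ground-truth trips
#'
#' Associates each (matched) trip with the ground-truth occupied run of the
#' same taxi whose time window contains the trip's midpoint.
#'
#' @param trips list of trips from [extract_trips()] / [map_match()].
#' @param truth `ground_truth` object from [gen_trajectories()].
#' @return integer vector: for each trip, the row of `truth$trips` (or `NA`).
#' @export
match_ground_truth <- function(trips, truth) {
  tt <- truth$trips
  vapply(trips, function(tr) {
    mid <- as.numeric(tr$time_start) / 2 + as.numeric(tr$time_end) / 2
    i <- which(tt$taxi_id == tr$taxi_id &
                 as.numeric(tt$time_start) <= mid &
                 as.numeric(tt$time_end) >= mid)
    if (length(i) == 0L) NA_integer_ else i[1]
  }, integer(1))
}
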