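# Cleaning, trip extraction and HMM map matching.

fix_row <- function(taxi, t_s, lon, lat, occ = TRUE) {
  data.frame(taxi_id = taxi, time = local_time(t_s), lon = lon, lat = lat,
             heading = 0, occupied = occ, stringsAsFactors = FALSE)
}

test_that("clean_fixes applies extent, duplicate and speed rules", {
  ext <- c(lon_min = 114, lat_min = 30, lon_max = 115, lat_max = 31)
  base <- do.call(rbind, list(
    fix_row("T1", 0, 114.10, 30.50),
    fix_row("T1", 10, 114.101, 30.50),     # ~96 m in 10 s: fine
    fix_row("T1", 20, 119.0, 30.50),       # outside extent
    fix_row("T1", 30, 114.102, 30.50),
    fix_row("T1", 30, 114.102, 30.50),     # duplicate timestamp
    fix_row("T1", 40, 114.70, 30.50)))     # ~57 km in 10 s: speeding
  expect_message(out <- clean_fixes(base, ext, 120), "removed 3/6")
  expect_equal(nrow(out), 3L)
  expect_equal(out$time, local_time(c(0, 10, 30)))
  # all-valid input passes through unchanged, and cleaning is idempotent
  ok <- base[1:2, ]
  expect_identical(clean_fixes(ok, ext, 120), ok)
  expect_identical(clean_fixes(out, ext, 120), out)
})

test_that("speed rule measures against the previous kept fix", {
  ext <- c(lon_min = 114, lat_min = 30, lon_max = 115, lat_max = 31)
  # outlier B between A and C: B dropped, C kept relative to A
  fx <- do.call(rbind, list(
    fix_row("T1", 0, 114.10, 30.50),
    fix_row("T1", 10, 114.40, 30.50),     # jump out
    fix_row("T1", 20, 114.1002, 30.50))) # back near A
  expect_message(out <- clean_fixes(fx, ext, 120))
  expect_equal(out$lon, c(114.10, 114.1002))
})

test_that("extract_trips returns maximal occupied runs passing filters", {
  mk <- function(occ) do.call(rbind, lapply(seq_along(occ), function(i)
    fix_row("T1", (i - 1) * 60, 114.1 + i * 0.001, 30.5, occ[i])))
  # V V O O O V -> one trip of 3 fixes
  tr <- extract_trips(mk(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)))
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]$fixes), 3L)
  expect_equal(tr[[1]]$time_start, local_time(120))
  expect_equal(tr[[1]]$time_end, local_time(240))
  # all vacant -> no trips
  expect_length(extract_trips(mk(rep(FALSE, 5))), 0L)
  # O O V O O -> two trips
  expect_length(extract_trips(mk(c(TRUE, TRUE, FALSE, TRUE, TRUE))), 2L)
  # sub-threshold runs are counted, not returned
  short <- mk(c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_message(expect_length(extract_trips(short), 0L), "below trip")
})

test_that("occupied fixes partition into at most one trip each", {
  s <- mini_scenario()
  fx <- clean_fixes(s$fixes, s$config$extent)
  trips <- extract_trips(fx)
  keys <- unlist(lapply(trips, function(t)
    paste(t$fixes$taxi_id, as.numeric(t$fixes$time))))
  expect_false(anyDuplicated(keys) > 0)
  occ_all <- unlist(lapply(trips, function(t) t$fixes$occupied))
  expect_true(all(occ_all))
})

test_that("noise-free fixes on one straight edge match that edge exactly", {
  net <- straight_network(lat = 30.35)
  lons <- seq(114.03, 114.06, by = 0.005)
  tr <- manual_trip(lons, rep(30.35, length(lons)),
                    local_time(seq(0, by = 60, length.out = length(lons))))
  m <- map_match(tr, net, min_distance_m = 0)
  expect_length(m, 1L)
  expect_equal(m[[1]]$matched$edge_ids, 1L)
  expect_equal(unique(m[[1]]$matched$fix_edge_ids), 1)
  span <- haversine_m(lons[1], 30.35, lons[length(lons)], 30.35)
  expect_equal(m[[1]]$distance_km * 1000, span, tolerance = 1e-6)
})

test_that("single-fix trip matches to the nearest edge point with distance 0", {
  net <- straight_network(lat = 30.35)
  tr <- manual_trip(114.05, 30.3502, local_time(0))
  m <- map_match(tr, net, min_fixes = 1L, min_duration_s = 0,
                 min_distance_m = 0, candidate_radius_m = 100)
  expect_length(m, 1L)
  expect_equal(m[[1]]$distance_km, 0)
  expect_equal(m[[1]]$matched$fix_edge_ids, 1)
})

test_that("a fix with no candidates splits the trip into sub-trips", {
  net <- straight_network(lat = 30.35)
  lons <- seq(114.03, 114.10, by = 0.005)
  lats <- rep(30.35, length(lons))
  lats[8] <- 30.40  # far off the road
  tr <- manual_trip(lons, lats,
                    local_time(seq(0, by = 120, length.out = length(lons))))
  expect_message(m <- map_match(tr, net, min_distance_m = 0), "split")
  expect_length(m, 2L)
  expect_equal(nrow(m[[1]]$fixes) + nrow(m[[2]]$fixes), length(lons) - 1L)
})

test_that("zero-noise synthetic trips recover the exact ground-truth edge sequence", {
  sc <- mini_config(gps_noise_sigma_m = 0)
  net <- gen_road_network(sc)
  sim <- gen_trajectories(sc, net)
  trips <- extract_trips(clean_fixes(sim$fixes, sc$extent))
  mi_all <- match_ground_truth(trips, sim$truth)
  set.seed(1)
  pick <- sample(length(trips), 40)
  for (k in pick) {
    m <- map_match(trips[[k]], net)
    if (length(m) == 0L) next
    truth_edges <- sim$truth$edge_seqs[[mi_all[k]]]
    expect_equal(mean(m[[1]]$matched$fix_edge_ids %in% truth_edges), 1)
    # matched path is exactly the traversed stretch of the true sequence
    expect_true(all(m[[1]]$matched$edge_ids %in% truth_edges))
  }
})

test_that("matched distance is at least the straight-line origin-destination distance", {
  matched <- mini_matched()
  for (tr in matched[seq(1, length(matched), by = 5)]) {
    straight <- haversine_m(tr$origin[["lon"]], tr$origin[["lat"]],
                            tr$destination[["lon"]], tr$destination[["lat"]])
    expect_gte(tr$distance_km * 1000, straight - 2 * 50)  # candidate radius slack
  }
})
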