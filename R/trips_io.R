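# Matched-trip serialisation: GeoJSON LineStrings carrying enough per-fix
# information (times, along-path distances, raw positions) to rebuild the
# trip objects for the exposure stage.

#' Write matched trips as GeoJSON
#'
#' One LineString feature per trip (the matched path) with properties
#' `taxi_id`, `time_start`, `time_end`, `distance_km` plus the per-fix
#' arrays needed to re-load the trips for exposure integration.
#'
#' @param trips list of matched `taxi_trip` objects.
#' @param path output path.
#' @export
write_trips_geojson <- function(trips, path) {
  feats <- lapply(trips, function(tr) {
    pc <- tr$matched$path_coords
    list(type = "Feature",
         properties = list(
           taxi_id = tr$taxi_id,
           time_start = format(tr$time_start, "%Y-%m-%d %H:%M:%S"),
           time_end = format(tr$time_end, "%Y-%m-%d %H:%M:%S"),
           distance_km = tr$distance_km,
           fix_time = as.numeric(tr$fixes$time),
           fix_lon = tr$fixes$lon, fix_lat = tr$fixes$lat,
           fix_dist_m = tr$matched$fix_dist_m),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(pc)),
                                              function(i) as.numeric(pc[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read matched trips from GeoJSON
#'
#' Inverse of [write_trips_geojson()].
#'
#' @param path GeoJSON path.
#' @return list of matched `taxi_trip` objects (without edge ids, which are
#'   not needed downstream of map matching).
#' @export
read_trips_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  lapply(js$features, function(f) {
    p <- f$properties
    fx <- data.frame(
      taxi_id = p$taxi_id,
      time = as.POSIXct(as.numeric(unlist(p$fix_time)),
                        origin = "1970-01-01", tz = STATION_TZ),
      lon = as.numeric(unlist(p$fix_lon)), lat = as.numeric(unlist(p$fix_lat)),
      heading = NA_real_, occupied = TRUE, stringsAsFactors = FALSE)
    tr <- new_trip(p$taxi_id, fx)
    pc <- do.call(rbind, lapply(f$geometry$coordinates,
                                function(q) as.numeric(unlist(q))))
    colnames(pc) <- c("lon", "lat")
    tr$matched <- list(edge_ids = integer(0), fix_edge_ids = numeric(0),
                       fix_dist_m = as.numeric(unlist(p$fix_dist_m)),
                       path_coords = pc,
                       path_cum_m = polyline_cumdist_m(pc))
    tr$distance_km <- as.numeric(p$distance_km)
    tr
  })
}
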