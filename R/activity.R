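# Activity analysis for driver subgroups: kernel density hotspot surfaces
# over trip origins/destinations and trip-distance statistics. Densities are
# planar in degrees (points per squared degree); at city-scale extents the
# lon/lat anisotropy is a documented caveat, not corrected.

#' Quartic kernel density surface
#'
#' Evaluates a quartic (biweight) kernel density at the centres of a regular
#' lon/lat grid: each point contributes total mass 1 via
#' `K(r) = 3 / (pi h^2) * (1 - r^2/h^2)^2` for `r < h` (compact support).
#' The grid covers the point bounding box padded by one bandwidth, snapped
#' to whole cells, so the surface integral equals the point count up to
#' cell-centre discretisation.
#'
#' @param points data.frame with `lon`, `lat` columns (>= 1 point).
#' @param cell_size grid cell edge, degrees (0.001 for hotspot maps).
#' @param bandwidth kernel radius `h`, degrees.
#' @param kernel kernel name; only `"quartic"` is implemented.
#' @return an object of class `density_surface` (shares the grid layout of
#'   [annual_grid()]: `values`, `origin_lon`, `origin_lat`, `cell_size`)
#'   with `bandwidth`, `kernel` and `n_points`.
#' @export
kde_surface <- function(points, cell_size = 0.001, bandwidth = 0.005,
                        kernel = "quartic") {
  if (nrow(points) == 0L) stop("kde_surface needs at least one point", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  kernel <- match.arg(kernel, "quartic")
  pad <- bandwidth + cell_size
  origin_lon <- floor((min(points$lon) - pad) / cell_size) * cell_size
  origin_lat <- floor((min(points$lat) - pad) / cell_size) * cell_size
  n_cols <- ceiling((max(points$lon) + pad - origin_lon) / cell_size)
  n_rows <- ceiling((max(points$lat) + pad - origin_lat) / cell_size)
  m <- matrix(0, nrow = n_rows, ncol = n_cols)
  h2 <- bandwidth^2
  w <- ceiling(bandwidth / cell_size)  # window half-width in cells
  off <- (-w):w
  for (p in seq_len(nrow(points))) {
    ci <- floor((points$lon[p] - origin_lon) / cell_size) + 1
    ri <- floor((points$lat[p] - origin_lat) / cell_size) + 1
    rows <- ri + off; cols <- ci + off
    rk <- rows >= 1 & rows <= n_rows; ck <- cols >= 1 & cols <= n_cols
    rows <- rows[rk]; cols <- cols[ck]
    cx <- origin_lon + (cols - 0.5) * cell_size
    cy <- origin_lat + (rows - 0.5) * cell_size
    d2 <- outer((cy - points$lat[p])^2, (cx - points$lon[p])^2, `+`)
    contrib <- ifelse(d2 < h2, 3 / (pi * h2) * (1 - d2 / h2)^2, 0)
    m[rows, cols] <- m[rows, cols] + contrib
  }
  structure(
    list(values = m, origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
         bandwidth = bandwidth, kernel = kernel, n_points = nrow(points)),
    class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  mass <- sum(x$values) * x$cell_size^2
  cat(sprintf(
    "density_surface: %d x %d cells of %g deg, %s kernel h=%g deg\n  %d points, surface mass %.3f\n",
    x$n_rows, x$n_cols, x$cell_size, x$kernel, x$bandwidth, x$n_points, mass))
  invisible(x)
}

# Cell of the surface maximum, as c(row, col).
surface_argmax <- function(surface) {
  i <- which.max(surface$values)
  c(row = (i - 1L) %% surface$n_rows + 1L,
    col = (i - 1L) %/% surface$n_rows + 1L)
}

trip_meta <- function(trips) {
  data.frame(
    taxi_id = vapply(trips, `[[`, character(1), "taxi_id"),
    day_type = day_type_of(as.POSIXct(
      vapply(trips, function(t) as.numeric(t$time_start), numeric(1)),
      origin = "1970-01-01", tz = STATION_TZ)),
    distance_km = vapply(trips, `[[`, numeric(1), "distance_km"))
}

trip_od_points <- function(trips, sel) {
  do.call(rbind, lapply(trips[sel], function(t)
    data.frame(lon = c(t$origin[["lon"]], t$destination[["lon"]]),
               lat = c(t$origin[["lat"]], t$destination[["lat"]]))))
}

#' Hotspot surfaces for high/low exposure groups
#'
#' Kernel density surfaces over the origins and destinations of each group's
#' trips, split by weekday/weekend.
#'
#' @param trips list of matched `taxi_trip` objects.
#' @param high_ids,low_ids taxi ids of the high/low exposure groups.
#' @param day_type `"both"`, `"weekday"` or `"weekend"`.
#' @param cell_size,bandwidth passed to [kde_surface()].
#' @return named list of `density_surface`s: `high_weekday`, `high_weekend`,
#'   `low_weekday`, `low_weekend` (only the requested day types).
#' @export
group_hotspots <- function(trips, high_ids, low_ids, day_type = "both",
                           cell_size = 0.001, bandwidth = 0.005) {
  day_type <- match.arg(day_type, c("both", "weekday", "weekend"))
  meta <- trip_meta(trips)
  days <- if (day_type == "both") c("weekday", "weekend") else day_type
  out <- list()
  for (grp in c("high", "low")) {
    ids <- if (grp == "high") high_ids else low_ids
    for (d in days) {
      sel <- meta$taxi_id %in% ids & meta$day_type == d
      if (!any(sel))
        stop(sprintf("no %s trips for the %s-exposure group", d, grp),
             call. = FALSE)
      out[[paste(grp, d, sep = "_")]] <-
        kde_surface(trip_od_points(trips, sel), cell_size, bandwidth)
    }
  }
  out
}

#' Trip-distance statistics for a driver group
#'
#' @param trips list of matched `taxi_trip` objects.
#' @param group_ids taxi ids of the group.
#' @param day_type `"both"`, `"weekday"` or `"weekend"`.
#' @return list with `mean_km`, `median_km`, `n`.
#' @export
trip_distance_stats <- function(trips, group_ids, day_type = "both") {
  day_type <- match.arg(day_type, c("both", "weekday", "weekend"))
  meta <- trip_meta(trips)
  sel <- meta$taxi_id %in% group_ids
  if (day_type != "both") sel <- sel & meta$day_type == day_type
  if (!any(sel)) stop("no trips selected", call. = FALSE)
  d <- meta$distance_km[sel]
  list(mean_km = mean(d), median_km = stats::median(d), n = length(d))
}

#' Write a density surface as GeoJSON cell polygons
#'
#' One Polygon feature per non-zero cell with a `density` property
#' (points per squared degree).
#'
#' @param surface a `density_surface`.
#' @param path output path.
#' @export
write_density_geojson <- function(surface, path) {
  nz <- which(surface$values > 0, arr.ind = TRUE)
  s <- surface$cell_size
  feats <- lapply(seq_len(nrow(nz)), function(k) {
    r <- nz[k, 1]; c <- nz[k, 2]
    x0 <- surface$origin_lon + (c - 1) * s; y0 <- surface$origin_lat + (r - 1) * s
    ring <- list(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s),
                 c(x0, y0))
    list(type = "Feature",
         properties = list(density = surface$values[r, c]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
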