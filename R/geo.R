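# Geodesic helpers shared across the package. All coordinates are WGS84
# lon/lat degrees; all ground distances are metres unless a name says km.

# Mean Earth radius, metres. Declared once so distance-based tests are exact.
EARTH_RADIUS_M <- 6371008.8

#' Haversine ground distance
#'
#' Vectorised great-circle distance between two sets of lon/lat points,
#' using the mean Earth radius 6371.0088 km.
#'
#' @param lon1,lat1,lon2,lat2 numeric vectors of coordinates in degrees.
#' @return distance in metres, recycled to the common length.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  if (n == 0L) return(numeric(0))
  geosphere::distHaversine(
    cbind(rep_len(lon1, n), rep_len(lat1, n)),
    cbind(rep_len(lon2, n), rep_len(lat2, n)),
    r = EARTH_RADIUS_M
  )
}

# Metres per degree of latitude (constant) and longitude (varies with lat).
m_per_deg_lat <- function() pi * EARTH_RADIUS_M / 180
m_per_deg_lon <- function(lat) m_per_deg_lat() * cos(lat * pi / 180)

# Cumulative along-polyline distance in metres. `coords` is a 2-column
# matrix (lon, lat); returns a vector of length nrow(coords) starting at 0.
polyline_cumdist_m <- function(coords) {
  n <- nrow(coords)
  if (n <= 1L) return(numeric(n))
  legs <- haversine_m(coords[-n, 1], coords[-n, 2], coords[-1, 1], coords[-1, 2])
  c(0, cumsum(legs))
}

# Project a point onto the segment (a, b) in a local planar frame centred on
# the point. Returns list(dist_m, frac, lon, lat): the perpendicular (clamped)
# distance, the fractional position along the segment and the foot point.
# Accurate at the sub-kilometre scales used for map-matching candidates.
project_point_segment <- function(lon, lat, ax, ay, bx, by) {
  mlat <- m_per_deg_lat()
  mlon <- m_per_deg_lon(lat)
  axm <- (ax - lon) * mlon; aym <- (ay - lat) * mlat
  bxm <- (bx - lon) * mlon; bym <- (by - lat) * mlat
  dx <- bxm - axm; dy <- bym - aym
  len2 <- dx * dx + dy * dy
  frac <- if (len2 <= 0) 0 else max(0, min(1, -(axm * dx + aym * dy) / len2))
  px <- axm + frac * dx; py <- aym + frac * dy
  list(
    dist_m = sqrt(px * px + py * py),
    frac = frac,
    lon = ax + frac * (bx - ax),
    lat = ay + frac * (by - ay)
  )
}

# Interpolate positions along a polyline at given along-path distances.
# `cum` is polyline_cumdist_m(coords). Distances are clamped to the path.
polyline_point_at <- function(coords, cum, dist_m) {
  total <- cum[length(cum)]
  d <- pmin(pmax(dist_m, 0), total)
  if (length(cum) == 1L) {
    return(cbind(lon = rep(coords[1, 1], length(d)),
                 lat = rep(coords[1, 2], length(d))))
  }
  i <- findInterval(d, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(cum) - 1L)
  seg_len <- cum[i + 1L] - cum[i]
  f <- ifelse(seg_len > 0, (d - cum[i]) / seg_len, 0)
  cbind(lon = coords[i, 1] + f * (coords[i + 1L, 1] - coords[i, 1]),
        lat = coords[i, 2] + f * (coords[i + 1L, 2] - coords[i, 2]))
}

# Initial bearing (degrees in [0, 360)) from point 1 to point 2.
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  b[is.na(b)] <- 0
  (b + 360) %% 360
}
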