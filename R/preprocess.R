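# Cleaning of raw fixes and extraction of occupied trips.

#' Clean raw GPS fixes
#'
#' Per taxi, in time order: drops fixes outside the study extent, duplicate
#' timestamps (first kept), and fixes implying a segment speed above
#' `max_speed_kmh` from the previously *kept* fix (greedy forward pass).
#' Cleaning is total and idempotent; removal counts are reported via
#' `message()`.
#'
#' @param fixes data.frame of fixes sorted by (taxi_id, time).
#' @param extent named numeric `lon_min, lat_min, lon_max, lat_max`, or
#'   `NULL` to skip the extent filter.
#' @param max_speed_kmh plausibility bound on segment speed.
#' @return the cleaned fixes data.frame.
#' @export
clean_fixes <- function(fixes, extent = NULL, max_speed_kmh = 120) {
  n0 <- nrow(fixes)
  if (n0 == 0L) return(fixes)
  keep <- rep(TRUE, n0)
  if (!is.null(extent)) {
    keep <- fixes$lon >= extent[["lon_min"]] & fixes$lon <= extent[["lon_max"]] &
      fixes$lat >= extent[["lat_min"]] & fixes$lat <= extent[["lat_max"]]
  }
  n_extent <- sum(!keep)
  fx <- fixes[keep, , drop = FALSE]
  dup <- duplicated(data.frame(fx$taxi_id, as.numeric(fx$time)))
  n_dup <- sum(dup)
  fx <- fx[!dup, , drop = FALSE]
  # greedy speed filter per taxi against the previous kept fix
  vmax <- max_speed_kmh / 3.6
  keep_speed <- unlist(lapply(split(seq_len(nrow(fx)), fx$taxi_id), function(idx) {
    if (length(idx) <= 1L) return(rep(TRUE, length(idx)))
    lon <- fx$lon[idx]; lat <- fx$lat[idx]; tm <- as.numeric(fx$time[idx])
    d <- haversine_m(lon[-length(lon)], lat[-length(lat)], lon[-1], lat[-1])
    sp <- d / pmax(diff(tm), 1e-9)
    ok <- rep(TRUE, length(idx))
    if (any(sp > vmax)) {
      last <- 1L
      for (i in 2:length(idx)) {
        d1 <- haversine_m(lon[last], lat[last], lon[i], lat[i])
        if (d1 / max(tm[i] - tm[last], 1e-9) > vmax) ok[i] <- FALSE else last <- i
      }
    }
    ok
  }), use.names = FALSE)
  # split() orders groups by taxi_id, matching the row sort order of fixes
  n_speed <- sum(!keep_speed)
  out <- fx[keep_speed, , drop = FALSE]
  if (n_extent + n_dup + n_speed > 0)
    message(sprintf("clean_fixes: removed %d/%d fixes (%d outside extent, %d duplicate, %d over speed)",
                    n0 - nrow(out), n0, n_extent, n_dup, n_speed))
  rownames(out) <- NULL
  out
}

new_trip <- function(taxi_id, fixes) {
  structure(
    list(taxi_id = taxi_id, time_start = fixes$time[1],
         time_end = fixes$time[nrow(fixes)], fixes = fixes,
         origin = c(lon = fixes$lon[1], lat = fixes$lat[1]),
         destination = c(lon = fixes$lon[nrow(fixes)], lat = fixes$lat[nrow(fixes)]),
         matched = NULL, distance_km = NA_real_),
    class = "taxi_trip")
}

#' @export
print.taxi_trip <- function(x, ...) {
  cat(sprintf("taxi_trip %s: %s -> %s, %d fixes%s\n", x$taxi_id,
              format(x$time_start), format(x$time_end), nrow(x$fixes),
              if (is.na(x$distance_km)) " (unmatched)"
              else sprintf(", %.2f km matched", x$distance_km)))
  invisible(x)
}

#' Extract occupied trips from cleaned fixes
#'
#' One trip per maximal contiguous occupied run per taxi, keeping runs with
#' at least `min_fixes` fixes and `min_duration_s` seconds between first and
#' last fix. Sub-threshold runs are counted in a message. A minimum matched
#' distance is enforced later by [map_match()].
#'
#' @param fixes cleaned fixes data.frame.
#' @param min_fixes,min_duration_s trip filters.
#' @return list of unmatched `taxi_trip` objects.
#' @export
extract_trips <- function(fixes, min_fixes = 2L, min_duration_s = 60) {
  if (nrow(fixes) == 0L) return(list())
  trips <- list(); n_sub <- 0L
  for (idx in split(seq_len(nrow(fixes)), fixes$taxi_id)) {
    occ <- fixes$occupied[idx]
    if (!any(occ)) next
    r <- rle(occ)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      rows <- idx[starts[k]:ends[k]]
      sub <- fixes[rows, , drop = FALSE]
      dur <- as.numeric(sub$time[nrow(sub)]) - as.numeric(sub$time[1])
      if (nrow(sub) < min_fixes || dur < min_duration_s) {
        n_sub <- n_sub + 1L
      } else {
        trips[[length(trips) + 1L]] <- new_trip(fixes$taxi_id[rows[1]], sub)
      }
    }
  }
  if (n_sub > 0)
    message(sprintf("extract_trips: %d occupied runs below trip thresholds", n_sub))
  trips
}
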