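# Raw GPS fixes are a plain data.frame with columns
# taxi_id (character), time (POSIXct, naive local), lon, lat (degrees),
# heading (degrees [0, 360)), occupied (logical), sorted by (taxi_id, time).

new_fixes <- function(taxi_id, time, lon, lat, heading, occupied) {
  df <- data.frame(taxi_id = as.character(taxi_id), time = time,
                   lon = lon, lat = lat, heading = heading,
                   occupied = as.logical(occupied), stringsAsFactors = FALSE)
  df[order(df$taxi_id, df$time), , drop = FALSE]
}

#' Read raw taxi GPS fixes from CSV
#'
#' Expects columns `taxi_id, timestamp, lon, lat, heading, occupied`
#' (occupied as 0/1 or logical text). Rows with unparseable timestamps are
#' dropped with a message stating the count; output is sorted by
#' (taxi_id, timestamp). An empty file with a header yields zero fixes.
#'
#' @param path CSV path.
#' @return data.frame of fixes (possibly 0 rows).
#' @export
read_trajectory_csv <- function(path) {
  df <- data.table::fread(path, colClasses = list(character = c("taxi_id", "timestamp")),
                          data.table = FALSE, showProgress = FALSE)
  need <- c("taxi_id", "timestamp", "lon", "lat", "heading", "occupied")
  if (!all(need %in% names(df)))
    stop(sprintf("trajectory CSV missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    return(new_fixes(character(0), as.POSIXct(character(0), tz = STATION_TZ),
                     numeric(0), numeric(0), numeric(0), logical(0)))
  t <- as.POSIXct(df$timestamp, tz = STATION_TZ, format = "%Y-%m-%d %H:%M:%OS")
  retry <- is.na(t)
  if (any(retry))
    t[retry] <- as.POSIXct(df$timestamp[retry], tz = STATION_TZ,
                           format = "%Y-%m-%dT%H:%M:%OS")
  bad <- is.na(t)
  if (any(bad)) {
    message(sprintf("read_trajectory_csv: dropped %d rows with unparseable timestamps",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]; t <- t[!bad]
  }
  occ <- df$occupied
  if (!is.logical(occ))
    occ <- trimws(tolower(as.character(occ))) %in% c("1", "true", "t", "yes")
  new_fixes(df$taxi_id, t, df$lon, df$lat, df$heading, occ)
}

#' Write taxi GPS fixes to CSV
#'
#' Inverse of [read_trajectory_csv()]; occupied is written as 0/1.
#'
#' @param fixes data.frame of fixes.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(fixes, path) {
  out <- data.frame(taxi_id = fixes$taxi_id,
                    timestamp = format(fixes$time, "%Y-%m-%d %H:%M:%S"),
                    lon = fixes$lon, lat = fixes$lat,
                    heading = fixes$heading,
                    occupied = as.integer(fixes$occupied),
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path)
  invisible(path)
}
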