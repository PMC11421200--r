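# Hourly monitoring-station series. Timestamps are naive local clock times
# carried as POSIXct in the "UTC" slot (the configured timezone, UTC+8 for the
# Wuhan-style scenario, is metadata only); each value applies to the hour
# [t, t+1h) as a step function.

STATION_TZ <- "UTC"

#' Hourly station concentration series
#'
#' @param station_id character scalar.
#' @param lon,lat station coordinates, degrees.
#' @param time POSIXct vector of hour starts, strictly increasing with 1-h
#'   spacing (gaps are filled with `NA` concentrations).
#' @param pm25 hourly concentrations, ug/m^3; `NA` marks a missing hour.
#' @return an object of class `station_series`.
#' @export
station_series <- function(station_id, lon, lat, time, pm25) {
  stopifnot(length(time) == length(pm25), length(time) >= 1L)
  o <- order(time)
  time <- time[o]; pm25 <- pm25[o]
  if (anyDuplicated(time))
    stop(sprintf("station %s: duplicate hours", station_id), call. = FALSE)
  if (any(pm25 < 0, na.rm = TRUE))
    stop(sprintf("station %s: negative concentrations", station_id), call. = FALSE)
  # regularise onto a complete hourly axis so spacing is exactly 1 h
  full <- seq(time[1], time[length(time)], by = 3600)
  pm <- rep(NA_real_, length(full))
  pm[match(as.numeric(time), as.numeric(full))] <- pm25
  structure(
    list(station_id = as.character(station_id), lon = lon, lat = lat,
         time = full, pm25 = pm),
    class = "station_series"
  )
}

#' @export
print.station_series <- function(x, ...) {
  cat(sprintf("station_series %s (%.4f, %.4f): %d hours, %d missing, mean %.1f ug/m^3\n",
              x$station_id, x$lon, x$lat, length(x$time), sum(is.na(x$pm25)),
              mean(x$pm25, na.rm = TRUE)))
  invisible(x)
}

#' Read hourly station series from CSV
#'
#' Expects columns `station_id, lon, lat, timestamp, pm25` (comma-separated,
#' header required). Timestamps not on the hour are snapped down to the hour
#' start with a warning; hours with no row become missing (`NA`). Duplicate
#' (station, hour) rows and negative concentrations are rejected.
#'
#' @param path CSV path.
#' @return named list of [station_series()], one per station id.
#' @export
read_station_csv <- function(path) {
  df <- data.table::fread(path, colClasses = list(character = "station_id"),
                          data.table = FALSE, showProgress = FALSE)
  need <- c("station_id", "lon", "lat", "timestamp", "pm25")
  if (!all(need %in% names(df)))
    stop(sprintf("station CSV missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  t <- as.POSIXct(df$timestamp, tz = STATION_TZ)
  if (anyNA(t))
    stop(sprintf("station CSV: %d unparseable timestamps", sum(is.na(t))),
         call. = FALSE)
  snapped <- as.POSIXct(trunc(t, "hours"))
  n_snap <- sum(as.numeric(t) != as.numeric(snapped))
  if (n_snap > 0)
    warning(sprintf("%d station timestamps snapped down to the hour", n_snap),
            call. = FALSE)
  key <- paste(df$station_id, as.numeric(snapped))
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate (station, hour) row %d: %s %s", d,
                 df$station_id[d], format(snapped[d])), call. = FALSE)
  }
  if (any(df$pm25 < 0, na.rm = TRUE))
    stop(sprintf("negative pm25 at row(s) %s",
                 paste(which(df$pm25 < 0), collapse = ", ")), call. = FALSE)
  out <- lapply(split(seq_len(nrow(df)), df$station_id), function(idx) {
    station_series(df$station_id[idx[1]], df$lon[idx[1]], df$lat[idx[1]],
                   snapped[idx], df$pm25[idx])
  })
  out[order(names(out))]
}

#' Write station series to CSV
#'
#' Inverse of [read_station_csv()]; missing hours are written as empty pm25
#' fields so the round trip is lossless.
#'
#' @param stations list of [station_series()].
#' @param path output CSV path.
#' @export
write_station_csv <- function(stations, path) {
  rows <- lapply(stations, function(s) {
    data.frame(station_id = s$station_id, lon = s$lon, lat = s$lat,
               timestamp = format(s$time, "%Y-%m-%d %H:%M:%S"),
               pm25 = s$pm25, stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, na = "")
  invisible(path)
}
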