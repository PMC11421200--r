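# Raster-station fusion: pick the representative station (minimum variance
# of the hourly station-minus-annual difference series) and evaluate the
# fused spatio-temporal concentration field
#   C^t_(i,j) = C^t_base + (C_(i,j) - C_base),
# i.e. the annual spatial surface shifted hour by hour so that it passes
# through the representative station's hourly value.

#' Difference series of one station against the annual grid
#'
#' Computes D_t = station hourly value minus the annual-grid value at the
#' station location, over non-missing hours, with its sample (n-1) variance.
#'
#' @param station a [station_series()].
#' @param grid an [annual_grid()].
#' @return an object of class `station_fit`: list with `station_id`,
#'   `annual`, `difference` (numeric vector), `hours` (POSIXct), `variance`,
#'   `outlier` (logical, set by [flag_outlier_stations()]).
#' @export
station_difference_series <- function(station, grid) {
  annual <- grid_value(grid, station$lon, station$lat)
  if (is.na(annual))
    stop(sprintf("station %s sits on a nodata cell of the annual grid",
                 station$station_id), call. = FALSE)
  ok <- !is.na(station$pm25)
  if (sum(ok) < 2L)
    stop(sprintf("station %s has fewer than 2 non-missing hours",
                 station$station_id), call. = FALSE)
  d <- station$pm25[ok] - annual
  structure(
    list(station_id = station$station_id, annual = annual,
         difference = d, hours = station$time[ok],
         variance = stats::var(d), outlier = FALSE),
    class = "station_fit")
}

#' Flag stations with obvious outliers
#'
#' A station is flagged when any hour's difference deviates from the mean
#' difference by more than `z_threshold` standard deviations (a declared
#' z-score stand-in for "no obvious outliers").
#'
#' @param fits list of `station_fit` objects.
#' @param z_threshold z-score threshold; `Inf` disables flagging.
#' @return the fits with `outlier` updated.
#' @export
flag_outlier_stations <- function(fits, z_threshold = 5) {
  lapply(fits, function(f) {
    s <- stats::sd(f$difference)
    f$outlier <- is.finite(z_threshold) && s > 0 &&
      any(abs(f$difference - mean(f$difference)) > z_threshold * s)
    f
  })
}

#' Select the representative station
#'
#' Ranks unflagged stations by ascending difference variance (ties broken by
#' station id) and selects the minimum-variance station, unless a manual
#' `override` id is given (retained because a practitioner may prefer a
#' near-minimal station on other grounds).
#'
#' @param fits list of `station_fit` objects (after outlier flagging).
#' @param override optional station id to select regardless of rank.
#' @return list with `selected` (a `station_fit`) and `ranking` (data.frame
#'   `station_id, variance, outlier` sorted by variance among all stations).
#' @export
select_representative_station <- function(fits, override = NULL) {
  tab <- data.frame(
    station_id = vapply(fits, `[[`, character(1), "station_id"),
    variance = vapply(fits, `[[`, numeric(1), "variance"),
    outlier = vapply(fits, `[[`, logical(1), "outlier"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$variance, tab$station_id), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(override)) {
    i <- which(vapply(fits, `[[`, character(1), "station_id") == override)
    if (length(i) == 0L)
      stop(sprintf("override station '%s' not among the fits", override),
           call. = FALSE)
    return(list(selected = fits[[i]], ranking = tab))
  }
  ok <- tab[!tab$outlier, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("all stations flagged as outliers; raise z_threshold or override",
         call. = FALSE)
  i <- which(vapply(fits, `[[`, character(1), "station_id") == ok$station_id[1])
  list(selected = fits[[i]], ranking = tab)
}

#' Fit the fused spatio-temporal concentration field
#'
#' The fitting step of the rapid-assessment method: computes each station's
#' difference series against the annual grid, flags outlier stations,
#' selects the representative (base) station, and returns a field object
#' whose [predict()] method evaluates the fused concentration
#' `C^t(p) = C^t_base + (C(p) - C_base)` at any location and time. Hourly
#' base values apply as a step function over `[hour, hour+1)`; missing base
#' hours are linearly interpolated across gaps of at most `max_gap_h` hours,
#' longer gaps are excluded (evaluate to `NA`). Negative fused values clamp
#' to 0 when `clamp_negative` (counted on the object).
#'
#' @param annual an [annual_grid()].
#' @param stations list of [station_series()].
#' @param z_threshold outlier z-score threshold for station screening.
#' @param base_station optional manual override of the representative
#'   station id.
#' @param clamp_negative clamp negative fused values to zero.
#' @param max_gap_h longest missing-hour gap filled by linear interpolation.
#' @return an object of class `concentration_field`.
#' @export
concentration_field <- function(annual, stations, z_threshold = 5,
                                base_station = NULL, clamp_negative = TRUE,
                                max_gap_h = 3) {
  fits <- lapply(stations, station_difference_series, grid = annual)
  fits <- flag_outlier_stations(fits, z_threshold)
  sel <- select_representative_station(fits, override = base_station)
  base <- stations[[which(vapply(stations, `[[`, character(1), "station_id") ==
                            sel$selected$station_id)]]
  pm <- fill_short_gaps(base$pm25, max_gap_h)
  counters <- new.env(parent = emptyenv())
  counters$clamped <- 0L
  structure(
    list(annual = annual, base = base, base_filled = pm,
         base_annual_value = sel$selected$annual,
         ranking = sel$ranking, fits = fits,
         clamp_negative = clamp_negative, max_gap_h = max_gap_h,
         counters = counters),
    class = "concentration_field")
}

# Linear interpolation of interior NA runs of length <= max_gap; longer runs
# and leading/trailing NAs stay NA.
fill_short_gaps <- function(x, max_gap) {
  if (!anyNA(x) || all(is.na(x))) return(x)
  filled <- stats::approx(seq_along(x), x, xout = seq_along(x), na.rm = TRUE)$y
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- x
  for (k in which(r$values)) {
    if (r$lengths[k] <= max_gap && starts[k] > 1L && ends[k] < length(x))
      out[starts[k]:ends[k]] <- filled[starts[k]:ends[k]]
  }
  out
}

# Base-station value for the hour containing each time (step function).
base_value_at <- function(field, time) {
  h <- floor((as.numeric(time) - as.numeric(field$base$time[1])) / 3600) + 1
  out <- rep(NA_real_, length(h))
  ok <- h >= 1 & h <= length(field$base_filled)
  out[ok] <- field$base_filled[h[ok]]
  out
}

#' Evaluate the fused concentration field
#'
#' @param object a [concentration_field()].
#' @param lon,lat coordinates, degrees (vectorised).
#' @param time POSIXct times (recycled against coordinates).
#' @param ... unused.
#' @return fused concentrations, ug/m^3. `NA` for times outside the usable
#'   base series (including unfilled gaps). Errors for locations outside the
#'   grid or on nodata cells.
#' @export
predict.concentration_field <- function(object, lon, lat, time, ...) {
  n <- max(length(lon), length(lat), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); time <- rep_len(time, n)
  annual <- grid_value(object$annual, lon, lat)
  if (anyNA(annual)) {
    i <- which(is.na(annual))[1]
    stop(sprintf("nodata annual cell at (%g, %g)", lon[i], lat[i]),
         call. = FALSE)
  }
  base_t <- base_value_at(object, time)
  raw <- base_t + (annual - object$base_annual_value)
  if (object$clamp_negative) {
    neg <- which(raw < 0)
    if (length(neg)) {
      object$counters$clamped <- object$counters$clamped + length(neg)
      raw[neg] <- 0
    }
  }
  raw
}

#' Fused concentration at a point and time
#'
#' Convenience wrapper around [predict.concentration_field()].
#'
#' @param field a [concentration_field()].
#' @param lon,lat,t location (degrees) and time (POSIXct).
#' @export
fused_concentration <- function(field, lon, lat, t) {
  predict(field, lon, lat, t)
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "concentration_field: base station %s (annual %.2f ug/m^3), %d stations ranked\n  grid %d x %d @ %g deg; %d negative values clamped so far\n",
    x$base$station_id, x$base_annual_value, nrow(x$ranking),
    x$annual$n_rows, x$annual$n_cols, x$annual$cell_size, x$counters$clamped))
  invisible(x)
}

#' @export
summary.concentration_field <- function(object, ...) {
  structure(
    list(ranking = object$ranking, base_station = object$base$station_id,
         base_annual_value = object$base_annual_value,
         n_hours = length(object$base$time),
         n_missing = sum(is.na(object$base$pm25)),
         n_unusable = sum(is.na(object$base_filled)),
         clamped = object$counters$clamped),
    class = "summary.concentration_field")
}

#' @export
print.summary.concentration_field <- function(x, ...) {
  cat("Fused concentration field\n")
  cat(sprintf("  base station: %s (annual value %.2f ug/m^3)\n",
              x$base_station, x$base_annual_value))
  cat(sprintf("  base series: %d hours, %d missing, %d unusable after gap fill\n",
              x$n_hours, x$n_missing, x$n_unusable))
  cat(sprintf("  negative fused values clamped: %d\n", x$clamped))
  cat("  station ranking (ascending difference variance):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Plot the annual surface and station ranking of a fused field
#'
#' Left: the annual grid as an image with station positions (base station
#' highlighted). Right: the base station's hourly series.
#'
#' @param x a [concentration_field()].
#' @param ... passed to [graphics::image()].
#' @export
plot.concentration_field <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  g <- x$annual
  lon_c <- g$origin_lon + (seq_len(g$n_cols) - 0.5) * g$cell_size
  lat_c <- g$origin_lat + (seq_len(g$n_rows) - 0.5) * g$cell_size
  graphics::image(lon_c, lat_c, t(g$values), xlab = "lon", ylab = "lat",
                  main = "annual PM2.5", ...)
  graphics::points(x$base$lon, x$base$lat, pch = 17, cex = 1.4)
  graphics::plot(x$base$time, x$base_filled, type = "l", xlab = "hour",
                 ylab = "PM2.5 (ug/m^3)",
                 main = sprintf("base station %s", x$base$station_id))
  invisible(x)
}
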