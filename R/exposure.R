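# Trip-level exposure integration and aggregation.
#
# A matched trip, traversed at the constant speed implied between
# consecutive fix times, is cut at every grid-cell boundary crossing and
# every clock-hour boundary; each piece contributes C * dt to the exposure
# integral EI = lambda * sum(C^t_grid * dt) in ug.h/m^3. The time-weighted
# average (TWA) concentration EI / (lambda * duration) is the figure-level
# quantity in ug/m^3.

#' Exposure configuration
#'
#' @param lambda_filtration dimensionless in-cabin filtration coefficient in
#'   (0, 1]; 1 is the open-window scenario.
#' @param guideline_who_24h WHO 24-h guideline, ug/m^3.
#' @param china_thresholds strictly increasing category cut points
#'   (good/moderate/unhealthy-for-sensitive-groups/poor), ug/m^3.
#' @param ci_level confidence level for hourly summaries.
#' @return an `exposure_config` list.
#' @export
exposure_config <- function(lambda_filtration = 1, guideline_who_24h = 25,
                            china_thresholds = c(35, 75, 115),
                            ci_level = 0.95) {
  if (lambda_filtration <= 0) stop("lambda must be > 0", call. = FALSE)
  if (any(diff(china_thresholds) <= 0) || length(china_thresholds) != 3L)
    stop("china_thresholds must be three strictly increasing values",
         call. = FALSE)
  structure(list(lambda_filtration = lambda_filtration,
                 guideline_who_24h = guideline_who_24h,
                 china_thresholds = china_thresholds, ci_level = ci_level),
            class = "exposure_config")
}

#' Split a matched trip into grid/hour segments
#'
#' Cuts the trip at every crossing of a grid-cell boundary along the matched
#' path and at every clock-hour boundary, assuming constant speed between
#' consecutive fix times. The segment durations sum to the trip duration
#' exactly (up to floating point).
#'
#' @param trip a matched `taxi_trip` from [map_match()].
#' @param field a [concentration_field()].
#' @return data.frame with columns `row`, `col` (grid cell), `hour`
#'   (POSIXct hour start), `delta_t_h` (hours) and `conc` (fused ug/m^3).
#' @export
segment_trip <- function(trip, field) {
  if (is.null(trip$matched)) stop("trip is not map-matched", call. = FALSE)
  fx <- trip$fixes
  t_fix <- as.numeric(fx$time)
  s_fix <- trip$matched$fix_dist_m
  coords <- trip$matched$path_coords
  cum <- trip$matched$path_cum_m
  t_a <- t_fix[1]; t_b <- t_fix[length(t_fix)]
  if (t_b <= t_a) stop("zero-duration trip", call. = FALSE)
  g <- field$annual
  # cut distances: strictly-interior grid-line crossings of each straight
  # piece, plus every interior polyline vertex (cells can also change at a
  # vertex, e.g. when a street runs along a cell boundary)
  cross_s <- numeric(0)
  if (nrow(coords) >= 2L) {
    i <- seq_len(nrow(coords) - 1L)
    for (dim in 1:2) {
      origin <- if (dim == 1) g$origin_lon else g$origin_lat
      p0 <- coords[i, dim]; p1 <- coords[i + 1L, dim]
      lo <- pmin(p0, p1); hi <- pmax(p0, p1)
      k_lo <- ceiling((lo - origin) / g$cell_size - 1e-12)
      k_hi <- floor((hi - origin) / g$cell_size + 1e-12)
      for (seg in which(k_hi >= k_lo & p1 != p0)) {
        ks <- k_lo[seg]:k_hi[seg]
        lines_at <- origin + ks * g$cell_size
        f <- (lines_at - p0[seg]) / (p1[seg] - p0[seg])
        f <- f[f > 1e-12 & f < 1 - 1e-12]
        cross_s <- c(cross_s, cum[seg] + f * (cum[seg + 1L] - cum[seg]))
      }
    }
    if (length(cum) > 2L) cross_s <- c(cross_s, cum[2:(length(cum) - 1L)])
    cross_s <- sort(unique(cross_s))
  }
  # convert crossing distances to times, leg by leg (s(t) is monotone)
  cross_t <- numeric(0)
  for (k in seq_len(length(t_fix) - 1L)) {
    ds <- s_fix[k + 1L] - s_fix[k]
    if (ds <= 0) next
    sel <- cross_s[cross_s > s_fix[k] & cross_s < s_fix[k + 1L]]
    if (length(sel))
      cross_t <- c(cross_t, t_fix[k] + (sel - s_fix[k]) / ds * (t_fix[k + 1L] - t_fix[k]))
  }
  h0 <- ceiling(t_a / 3600) * 3600
  hours <- if (h0 <= t_b) seq(h0, t_b, by = 3600) else numeric(0)
  brk <- sort(unique(c(t_a, cross_t, hours[hours > t_a & hours < t_b], t_b)))
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  s_mid <- stats::approx(t_fix, s_fix, xout = mid, rule = 2)$y
  pos <- polyline_point_at(coords, cum, s_mid)
  rc <- grid_cell(g, pos[, 1], pos[, 2])
  if (anyNA(rc[, 1])) {
    bad <- which(is.na(rc[, 1]))[1]
    stop(sprintf("trip leaves the grid near (%g, %g)", pos[bad, 1], pos[bad, 2]),
         call. = FALSE)
  }
  tm <- as.POSIXct(mid, origin = "1970-01-01", tz = STATION_TZ)
  conc <- predict(field, pos[, 1], pos[, 2], tm)
  data.frame(row = rc[, 1], col = rc[, 2],
             hour = as.POSIXct(floor(mid / 3600) * 3600,
                               origin = "1970-01-01", tz = STATION_TZ),
             delta_t_h = diff(brk) / 3600, conc = conc)
}

#' Exposure integral of one trip
#'
#' @param trip a matched `taxi_trip`.
#' @param field a [concentration_field()].
#' @param config an [exposure_config()].
#' @return an object of class `trip_exposure`: `ei` (ug.h/m^3), `twa`
#'   (ug/m^3), the per-segment table and trip metadata.
#' @export
trip_exposure <- function(trip, field, config = exposure_config()) {
  seg <- segment_trip(trip, field)
  if (anyNA(seg$conc))
    stop("trip overlaps hours with no usable base-station value", call. = FALSE)
  lam <- config$lambda_filtration
  dur_h <- as.numeric(trip$time_end) / 3600 - as.numeric(trip$time_start) / 3600
  ei <- lam * sum(seg$conc * seg$delta_t_h)
  structure(
    list(taxi_id = trip$taxi_id, time_start = trip$time_start,
         time_end = trip$time_end, duration_h = dur_h,
         distance_km = trip$distance_km, ei = ei,
         twa = ei / (lam * dur_h), segments = seg, lambda = lam),
    class = "trip_exposure")
}

#' @export
print.trip_exposure <- function(x, ...) {
  cat(sprintf("trip_exposure %s %s: EI %.2f ug.h/m^3, TWA %.1f ug/m^3 over %.2f h\n",
              x$taxi_id, format(x$time_start), x$ei, x$twa, x$duration_h))
  invisible(x)
}

#' Exposure for a list of matched trips
#'
#' @param trips list of matched `taxi_trip` objects.
#' @inheritParams trip_exposure
#' @return list of `trip_exposure` objects.
#' @export
fleet_exposure <- function(trips, field, config = exposure_config()) {
  lapply(trips, trip_exposure, field = field, config = config)
}

day_type_of <- function(time) {
  wd <- as.POSIXlt(time)$wday
  ifelse(wd %in% c(0L, 6L), "weekend", "weekday")
}

#' Hourly exposure summary
#'
#' Each trip contributes, for each clock hour-of-day it touches, one
#' time-weighted sample (its TWA concentration within that hour, weighted by
#' the time spent). Per hour: weighted mean, normal-approximation confidence
#' interval `mean +/- z * sd / sqrt(n)` and the sample count. Hours with no
#' samples are `NA`; a single sample yields a degenerate CI at the mean.
#'
#' @param trip_exposures list of `trip_exposure` objects.
#' @param day_filter `"all"`, `"weekday"` or `"weekend"`.
#' @param ci_level confidence level.
#' @return data.frame with 24 rows: `hour`, `mean`, `ci_low`, `ci_high`, `n`.
#' @export
hourly_summary <- function(trip_exposures, day_filter = "all",
                           ci_level = 0.95) {
  day_filter <- match.arg(day_filter, c("all", "weekday", "weekend"))
  samples <- do.call(rbind, lapply(trip_exposures, function(te) {
    s <- te$segments
    if (day_filter != "all") s <- s[day_type_of(s$hour) == day_filter, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    hod <- as.POSIXlt(s$hour)$hour
    agg_w <- tapply(s$delta_t_h, hod, sum)
    agg_cw <- tapply(s$conc * s$delta_t_h, hod, sum)
    data.frame(hour = as.integer(names(agg_w)), x = as.numeric(agg_cw / agg_w),
               w = as.numeric(agg_w))
  }))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(hour = 0:23, mean = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, n = 0L)
  if (is.null(samples)) return(out)
  for (h in 0:23) {
    s <- samples[samples$hour == h, , drop = FALSE]
    n <- nrow(s)
    if (n == 0L) next
    m <- sum(s$x * s$w) / sum(s$w)
    if (n == 1L) {
      out[h + 1L, 2:5] <- list(m, m, m, 1L)
    } else {
      v <- sum(s$w * (s$x - m)^2) / sum(s$w) * n / (n - 1)
      se <- sqrt(v) / sqrt(n)
      out[h + 1L, 2:5] <- list(m, m - z * se, m + z * se, n)
    }
  }
  out
}

#' Daily and weekday/weekend exposure summaries
#'
#' Per driver-day: TWA concentration over that driver's trips of the day
#' (`sum(EI) / (lambda * sum(duration))`, trips assigned to the calendar day
#' they start). Fleet per-day value is the unweighted mean over drivers;
#' weekday/weekend means and SDs (n-1) are over the per-day fleet values.
#'
#' @param trip_exposures list of `trip_exposure` objects.
#' @return list with `driver_days` (taxi_id, date, day_type, daily_twa,
#'   total_occupied_hours, n_trips), `fleet_daily` (date, day_type, mean over
#'   drivers, n_drivers), `weekday` and `weekend` (each `c(mean, sd)`).
#' @export
daily_summaries <- function(trip_exposures) {
  df <- data.frame(
    taxi_id = vapply(trip_exposures, `[[`, character(1), "taxi_id"),
    date = as.Date(as.POSIXlt(as.POSIXct(
      vapply(trip_exposures, function(t) as.numeric(t$time_start), numeric(1)),
      origin = "1970-01-01", tz = STATION_TZ))),
    ei = vapply(trip_exposures, `[[`, numeric(1), "ei"),
    dur = vapply(trip_exposures, `[[`, numeric(1), "duration_h"),
    lambda = vapply(trip_exposures, `[[`, numeric(1), "lambda"))
  key <- paste(df$taxi_id, df$date)
  dd <- do.call(rbind, lapply(split(df, key), function(d) {
    data.frame(taxi_id = d$taxi_id[1], date = d$date[1],
               daily_twa = sum(d$ei) / (d$lambda[1] * sum(d$dur)),
               total_occupied_hours = sum(d$dur), n_trips = nrow(d))
  }))
  rownames(dd) <- NULL
  dd$day_type <- day_type_of(as.POSIXct(paste(dd$date, "12:00:00"),
                                        tz = STATION_TZ))
  fleet <- do.call(rbind, lapply(split(dd, dd$date), function(d)
    data.frame(date = d$date[1], day_type = d$day_type[1],
               mean_twa = mean(d$daily_twa), n_drivers = nrow(d))))
  rownames(fleet) <- NULL
  msd <- function(x) if (length(x) == 0L) c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(x), sd = stats::sd(x))
  list(driver_days = dd[, c("taxi_id", "date", "day_type", "daily_twa",
                            "total_occupied_hours", "n_trips")],
       fleet_daily = fleet,
       weekday = msd(fleet$mean_twa[fleet$day_type == "weekday"]),
       weekend = msd(fleet$mean_twa[fleet$day_type == "weekend"]))
}

#' Air-quality category of a 24-h concentration
#'
#' Chinese ambient-standard categories with half-open intervals:
#' `[0,35)` good, `[35,75)` moderate, `[75,115)` unhealthy for sensitive
#' groups, `[115,Inf)` poor.
#'
#' @param c concentration(s), ug/m^3, non-negative.
#' @param thresholds the three cut points.
#' @return factor with levels `good`, `moderate`, `unhealthy_sensitive`,
#'   `poor`.
#' @export
classify_air_quality <- function(c, thresholds = c(35, 75, 115)) {
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  cut(c, breaks = c(0, thresholds, Inf), right = FALSE,
      labels = c("good", "moderate", "unhealthy_sensitive", "poor"))
}

#' Compare a mean concentration with a guideline
#'
#' @param mean_c mean concentration, ug/m^3.
#' @param reference guideline value, ug/m^3, positive.
#' @return list with `ratio` (`mean_c / reference`) and `percent_excess`
#'   (`100 * (mean_c - reference) / reference`).
#' @export
guideline_comparison <- function(mean_c, reference) {
  if (any(reference <= 0)) stop("reference must be > 0", call. = FALSE)
  list(ratio = mean_c / reference,
       percent_excess = 100 * (mean_c - reference) / reference)
}

#' Drivers eligible for subgroup analysis
#'
#' Keeps drivers with at least `min_weekdays` distinct weekday driver-days
#' or at least `min_weekends` distinct weekend driver-days.
#'
#' @param driver_days the `driver_days` data.frame from [daily_summaries()].
#' @param min_weekdays,min_weekends eligibility thresholds.
#' @return character vector of eligible taxi ids (sorted).
#' @export
filter_eligible_drivers <- function(driver_days, min_weekdays = 10L,
                                    min_weekends = 4L) {
  ok <- vapply(split(driver_days, driver_days$taxi_id), function(d) {
    wd <- length(unique(d$date[d$day_type == "weekday"]))
    we <- length(unique(d$date[d$day_type == "weekend"]))
    wd >= min_weekdays || we >= min_weekends
  }, logical(1))
  sort(names(ok)[ok])
}

#' Highest- and lowest-exposure driver groups
#'
#' Ranks eligible drivers by mean daily TWA and selects the top and bottom
#' `ceiling(fraction * n)` drivers; ties are broken by driver id.
#'
#' @param driver_means data.frame `taxi_id, mean_twa` (one row per eligible
#'   driver), or a named numeric vector.
#' @param fraction group fraction in (0, 0.5].
#' @return list with `high` and `low` character vectors of taxi ids.
#' @export
select_extreme_drivers <- function(driver_means, fraction = 0.01) {
  if (is.numeric(driver_means))
    driver_means <- data.frame(taxi_id = names(driver_means),
                               mean_twa = as.numeric(driver_means))
  if (nrow(driver_means) == 0L) stop("no eligible drivers", call. = FALSE)
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must be in (0, 0.5]", call. = FALSE)
  n <- nrow(driver_means)
  k <- ceiling(fraction * n)
  # one ascending ranking; the two tails stay disjoint whenever n >= 2k
  o <- order(driver_means$mean_twa, driver_means$taxi_id)
  list(high = driver_means$taxi_id[o[n - seq_len(k) + 1L]],
       low = driver_means$taxi_id[o[seq_len(k)]])
}
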