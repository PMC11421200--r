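# Trip segmentation, exposure integration and the aggregation layer.

test_that("a trip inside one cell and hour yields a single conserving segment", {
  f <- constant_field(80)
  tr <- manual_trip(c(114.051, 114.052), c(30.351, 30.351),
                    local_time(c(600, 1500)))
  seg <- segment_trip(tr, f)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$delta_t_h, 0.25)
  expect_equal(seg$conc, 80)
})

test_that("crossing a cell border at midpoint splits time evenly", {
  f <- constant_field(80)
  # cell border at lon 114.06; constant speed, symmetric span
  tr <- manual_trip(c(114.055, 114.065), c(30.351, 30.351),
                    local_time(c(0, 1200)))
  seg <- segment_trip(tr, f)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$delta_t_h, c(1, 1) / 6, tolerance = 1e-6)
  expect_equal(seg$col, c(6L, 7L))
})

test_that("hour boundaries cut segments even without movement across cells", {
  f <- constant_field(80)
  tr <- manual_trip(c(114.051, 114.0515), c(30.351, 30.351),
                    local_time(c(3000, 4200)))  # crosses the 1-hour mark
  seg <- segment_trip(tr, f)
  expect_equal(nrow(seg), 2L)
  expect_equal(sum(seg$delta_t_h), 1200 / 3600, tolerance = 1e-12)
  expect_equal(as.numeric(seg$hour), c(0, 3600) + as.numeric(local_time(0)))
})

test_that("segment durations conserve trip duration on synthetic trips", {
  s <- mini_scenario()
  matched <- mini_matched()
  n <- min(100, length(matched))
  for (tr in matched[seq_len(n)]) {
    seg <- segment_trip(tr, s$field)
    dur <- as.numeric(tr$time_end) / 3600 - as.numeric(tr$time_start) / 3600
    expect_lt(abs(sum(seg$delta_t_h) - dur), 1e-9 * dur)
  }
})

test_that("trip exposure follows the closed forms", {
  f <- constant_field(80)
  cfg <- exposure_config(lambda_filtration = 1)
  tr <- manual_trip(c(114.051, 114.0525), c(30.351, 30.351),
                    local_time(c(0, 1800)))
  te <- trip_exposure(tr, f, cfg)
  expect_equal(te$ei, 40)
  expect_equal(te$twa, 80)
  # two cells, 0.25 h at 60 then 0.25 h at 100 -> EI 40, twa 80
  g <- constant_grid(60)
  g$values[, 7:20] <- 100
  st <- constant_station(60, lon = 114.035, lat = 30.355)  # col 4: value 60
  f2 <- concentration_field(g, list(st))
  tr2 <- manual_trip(c(114.055, 114.065), c(30.355, 30.355),
                     local_time(c(0, 1800)))
  te2 <- trip_exposure(tr2, f2, cfg)
  expect_equal(te2$ei, 0.25 * 60 + 0.25 * 100)
  expect_equal(te2$twa, 80)
})

test_that("lambda scales EI linearly and leaves TWA unchanged", {
  s <- mini_scenario()
  matched <- mini_matched()[1:20]
  te1 <- fleet_exposure(matched, s$field, exposure_config(lambda_filtration = 0.5))
  te2 <- fleet_exposure(matched, s$field, exposure_config(lambda_filtration = 1))
  expect_equal(vapply(te2, `[[`, numeric(1), "ei"),
               2 * vapply(te1, `[[`, numeric(1), "ei"), tolerance = 1e-12)
  expect_equal(vapply(te2, `[[`, numeric(1), "twa"),
               vapply(te1, `[[`, numeric(1), "twa"), tolerance = 1e-12)
})

test_that("segmented EI matches a dense Riemann-sum oracle on synthetic trips", {
  s <- mini_scenario()
  matched <- mini_matched()
  set.seed(8)
  pick <- sample(length(matched), min(100, length(matched)))
  cfg <- exposure_config()
  for (tr in matched[pick]) {
    te <- trip_exposure(tr, s$field, cfg)
    # oracle: 1-s midpoint sampling along the same matched path
    t_a <- as.numeric(tr$time_start); t_b <- as.numeric(tr$time_end)
    brk <- unique(c(seq(t_a, t_b, by = 1), t_b))
    mid <- (brk[-1] + brk[-length(brk)]) / 2
    s_mid <- stats::approx(as.numeric(tr$fixes$time), tr$matched$fix_dist_m,
                           xout = mid)$y
    pos <- dynexposure:::polyline_point_at(tr$matched$path_coords,
                                           tr$matched$path_cum_m, s_mid)
    conc <- predict(s$field, pos[, 1], pos[, 2],
                    as.POSIXct(mid, origin = "1970-01-01", tz = "UTC"))
    ei_oracle <- sum(conc * diff(brk) / 3600)
    expect_lt(abs(te$ei - ei_oracle), 1e-3 * ei_oracle)
  }
})

test_that("hourly summary: degenerate, simulated-normal and day-filter cases", {
  f <- constant_field(85)
  trips <- lapply(0:3, function(k)
    manual_trip(c(114.051, 114.052), c(30.351, 30.351),
                local_time(c(0, 900) + k * 950)))
  te <- fleet_exposure(trips, f)
  hs <- hourly_summary(te)
  expect_equal(hs$mean[1], 85)
  expect_equal(hs$ci_low[1], 85)
  expect_equal(hs$ci_high[1], 85)
  expect_true(all(is.na(hs$mean[hs$n == 0])))
  # CI half-width approximates the closed-form standard error
  set.seed(21)
  x <- rnorm(10000, 85, 5)
  fake <- lapply(seq_along(x), function(i) {
    structure(list(taxi_id = "T", segments = data.frame(
      row = 1L, col = 1L, hour = local_time(10 * 3600),
      delta_t_h = 0.01, conc = x[i])), class = "trip_exposure")
  })
  hs2 <- hourly_summary(fake)
  half <- (hs2$ci_high[11] - hs2$ci_low[11]) / 2
  expect_lt(abs(half - 1.96 * 5 / 100) / (1.96 * 5 / 100), 0.2)
  expect_equal(hs2$n[11], 10000L)
  # weekend filter on weekday-only data (2014-05-13 is a Tuesday)
  hs3 <- hourly_summary(te, day_filter = "weekend")
  expect_true(all(hs3$n == 0))
  # input order invariance
  s <- mini_scenario()
  tem <- fleet_exposure(mini_matched()[1:30], s$field)
  h_a <- hourly_summary(tem)
  h_b <- hourly_summary(rev(tem))
  expect_equal(h_a, h_b)
})

test_that("daily summaries aggregate drivers then days with n-1 SD", {
  f <- constant_field(80)
  tr <- manual_trip(c(114.051, 114.0525), c(30.351, 30.351),
                    local_time(c(0, 1800)))
  ds <- daily_summaries(fleet_exposure(list(tr), f))
  expect_equal(ds$driver_days$daily_twa, 80)
  expect_equal(ds$fleet_daily$mean_twa, 80)
  # two days with fleet values 80 and 90 -> mean 85, SD 7.071
  mk_day <- function(day, conc) {
    fd <- constant_field(conc)
    manual_trip(c(114.051, 114.0525), c(30.351, 30.351),
                local_time(c(0, 1800), start = day))
  }
  te <- list(trip_exposure(mk_day("2014-05-13", 80), constant_field(80, hours = 48)),
             trip_exposure(mk_day("2014-05-14", 90),
                           constant_field(90, hours = 24, start = "2014-05-14")))
  ds2 <- daily_summaries(te)
  expect_equal(unname(ds2$weekday[["mean"]]), 85)
  expect_equal(unname(ds2$weekday[["sd"]]), sqrt(50), tolerance = 1e-9)
  expect_equal(round(unname(ds2$weekday[["sd"]]), 3), 7.071)
})

test_that("air-quality classification uses half-open category bounds", {
  expect_equal(as.character(classify_air_quality(45.5)), "moderate")
  expect_equal(as.character(classify_air_quality(c(0, 34.99, 35, 75, 114.99, 115, 300))),
               c("good", "good", "moderate", "unhealthy_sensitive",
                 "unhealthy_sensitive", "poor", "poor"))
  expect_error(classify_air_quality(-1), "non-negative")
})

test_that("guideline comparison reproduces ratio and percent excess", {
  gc <- guideline_comparison(83.60, 25)
  expect_equal(gc$ratio, 3.344)
  expect_equal(gc$percent_excess, 234.4)
  gc2 <- guideline_comparison(83.60, 75)
  expect_equal(round(gc2$percent_excess, 1), 11.5)
  gc3 <- guideline_comparison(25, 25)
  expect_equal(gc3$ratio, 1)
  expect_equal(gc3$percent_excess, 0)
  expect_error(guideline_comparison(50, 0), "reference")
})

test_that("driver eligibility needs 10 weekdays or 4 weekend days", {
  mk_days <- function(id, n_wd, n_we) {
    wd <- as.Date("2014-05-05") + seq_len(25)  # mix of weekdays/weekends
    wd_days <- wd[format(wd, "%u") %in% as.character(1:5)][seq_len(n_wd)]
    we_days <- wd[format(wd, "%u") %in% c("6", "7")][seq_len(n_we)]
    d <- c(wd_days, we_days)
    if (length(d) == 0L) return(NULL)
    data.frame(taxi_id = id, date = d,
               day_type = ifelse(format(d, "%u") %in% c("6", "7"),
                                 "weekend", "weekday"),
               daily_twa = 50, total_occupied_hours = 5, n_trips = 10)
  }
  dd <- rbind(mk_days("A", 10, 0), mk_days("B", 9, 3), mk_days("C", 0, 4))
  expect_equal(filter_eligible_drivers(dd), c("A", "C"))
})

test_that("extreme-driver selection takes ceiling(fraction*n) from each tail", {
  means <- setNames(seq_len(200) + 0.5, sprintf("D%03d", 1:200))
  g <- select_extreme_drivers(means, 0.01)
  expect_equal(g$high, c("D200", "D199"))
  expect_equal(g$low, c("D001", "D002"))
  g2 <- select_extreme_drivers(means[1:50], 0.01)
  expect_length(g2$high, 1L)
  expect_length(g2$low, 1L)
  # all-equal means: pure id tie-break, disjoint tails
  eq <- setNames(rep(1, 10), sprintf("D%02d", 1:10))
  g3 <- select_extreme_drivers(eq, 0.1)
  expect_equal(g3$high, "D10")
  expect_equal(g3$low, "D01")
  expect_length(intersect(g3$high, g3$low), 0L)
  expect_error(select_extreme_drivers(data.frame(taxi_id = character(0),
                                                 mean_twa = numeric(0))),
               "eligible")
})
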