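# Raster-station fusion: difference series, outlier screening,
# representative-station selection and the fused field.

table2_variances <- c(a = 308.04, b = 355.41, c = 657.53, d = 183.68,
                      e = 131.97, f = 253.47, g = 238.32, h = 747.47,
                      i = 358.51)

# Build a station_fit with a prescribed variance: mean-zero two-point
# difference series d, -d has sample variance 2*d^2.
fit_with_variance <- function(id, v) {
  f <- station_difference_series(
    constant_station(50, hours = 2, id = id), constant_grid(50))
  f$difference <- c(1, -1) * sqrt(v / 2)
  f$variance <- stats::var(f$difference)
  f
}

test_that("difference series and variance follow the n-1 sample formula", {
  g <- constant_grid(45, n = 10)
  t0 <- local_time(0)
  st <- station_series("s", 114.05, 30.35, t0 + 3600 * (0:2), c(50, 60, 70))
  fit <- station_difference_series(st, g)
  expect_equal(fit$difference, c(5, 15, 25))
  expect_equal(fit$variance, 100)
  # series equal to the annual value -> all-zero differences, variance 0
  flat <- station_difference_series(constant_station(45), g)
  expect_equal(unique(flat$difference), 0)
  expect_equal(flat$variance, 0)
  # constant offset has variance 0 too
  off <- station_difference_series(constant_station(55), g)
  expect_equal(off$variance, 0)
  # missing hours are excluded
  st2 <- station_series("s", 114.05, 30.35, t0 + 3600 * (0:3),
                        c(50, NA, 60, 70))
  expect_length(station_difference_series(st2, g)$difference, 3L)
  # nodata cell errors with the station name
  gna <- constant_grid(45)
  gna$values[] <- NA
  expect_error(station_difference_series(constant_station(45), gna), "s1")
})

test_that("outlier flagging is a z-score rule on the difference series", {
  g <- constant_grid(50)
  flat <- station_difference_series(constant_station(55, hours = 48), g)
  spiky <- flat
  spiky$difference <- c(rep(0, 47), 0)
  spiky$difference[10] <- 1  # small wiggle to give nonzero sd
  spiky$difference[20] <- 60
  fits <- flag_outlier_stations(list(flat, spiky), z_threshold = 5)
  expect_false(fits[[1]]$outlier)
  expect_true(fits[[2]]$outlier)
  fits_inf <- flag_outlier_stations(list(flat, spiky), z_threshold = Inf)
  expect_false(any(vapply(fits_inf, `[[`, logical(1), "outlier")))
})

test_that("representative-station selection is minimum-variance with deterministic ties", {
  fits <- mapply(fit_with_variance, names(table2_variances), table2_variances,
                 SIMPLIFY = FALSE)
  sel <- select_representative_station(fits)
  expect_equal(sel$selected$station_id, "e")
  expect_equal(sel$ranking$station_id[1:2], c("e", "d"))
  expect_equal(sel$ranking$variance[1:2], c(131.97, 183.68), tolerance = 1e-9)
  # invariant to input order
  set.seed(3)
  sel2 <- select_representative_station(fits[sample(length(fits))])
  expect_equal(sel2$ranking, sel$ranking)
  # manual override reproduces a second-lowest choice
  sel3 <- select_representative_station(fits, override = "d")
  expect_equal(sel3$selected$station_id, "d")
  # equal variances tie-break on station id
  ties <- list(fit_with_variance("b", 10), fit_with_variance("a", 10))
  expect_equal(select_representative_station(ties)$selected$station_id, "a")
  # single unflagged station wins; all flagged errors
  one <- fit_with_variance("z", 5)
  expect_equal(select_representative_station(list(one))$selected$station_id, "z")
  flagged <- one; flagged$outlier <- TRUE
  expect_error(select_representative_station(list(flagged)), "flagged")
})

test_that("fused field reproduces the station at its own cell and shifts elsewhere", {
  vals <- matrix(45, 20, 20)
  g <- annual_grid(vals, 114, 30.3, 0.01)
  t0 <- local_time(0)
  hourly <- c(100, 20, 60)
  st <- station_series("s", 114.055, 30.355, t0 + 3600 * (0:2), hourly)
  # give the station's cell annual value 45, another cell 50
  g$values[10, 10] <- 50   # cell centre (114.095, 30.395)
  f <- concentration_field(g, list(st))
  # at the base station's own cell the terms cancel
  expect_equal(predict(f, 114.055, 30.355, t0 + c(0, 3600, 7200) + 10),
               hourly)
  # C_ij = 50, C_base = 45, hour value 100 -> 105
  expect_equal(predict(f, 114.095, 30.395, t0 + 10), 105)
  # clamping: C_ij = 10 -> raw -15 at hour 2 (value 20) -> 0, counted
  g2 <- g; g2$values[15, 15] <- 10
  f2 <- concentration_field(g2, list(st))
  expect_equal(predict(f2, 114.145, 30.445, t0 + 3600 + 10), 0)
  expect_equal(f2$counters$clamped, 1L)
  # without clamping the raw value is returned
  f3 <- concentration_field(g2, list(st), clamp_negative = FALSE)
  expect_equal(predict(f3, 114.145, 30.445, t0 + 3600 + 10), -15)
})

test_that("fusion preserves spatial anomalies and temporal shape", {
  s <- mini_scenario()
  f <- s$field
  g <- s$grid
  set.seed(11)
  n <- 1000
  lon <- runif(n, g$origin_lon + 1e-6, g$origin_lon + g$n_cols * g$cell_size - 1e-6)
  lat <- runif(n, g$origin_lat + 1e-6, g$origin_lat + g$n_rows * g$cell_size - 1e-6)
  lon2 <- runif(n, g$origin_lon + 1e-6, g$origin_lon + g$n_cols * g$cell_size - 1e-6)
  lat2 <- runif(n, g$origin_lat + 1e-6, g$origin_lat + g$n_rows * g$cell_size - 1e-6)
  tt <- local_time(runif(n, 0, 24 * 3600 - 1))
  p1 <- predict(f, lon, lat, tt); p2 <- predict(f, lon2, lat2, tt)
  a1 <- grid_value(g, lon, lat); a2 <- grid_value(g, lon2, lat2)
  no_clamp <- p1 > 0 & p2 > 0
  expect_true(any(no_clamp))
  expect_equal((p1 - p2)[no_clamp], (a1 - a2)[no_clamp], tolerance = 1e-9)
  # temporal shape: fixed location, two hours
  t_b <- local_time(runif(n, 0, 24 * 3600 - 1))
  q1 <- predict(f, lon, lat, t_b)
  b1 <- dynexposure:::base_value_at(f, tt)
  b2 <- dynexposure:::base_value_at(f, t_b)
  ok <- p1 > 0 & q1 > 0
  expect_equal((p1 - q1)[ok], (b1 - b2)[ok], tolerance = 1e-9)
})

test_that("a spatially constant grid makes the fused field equal the station series", {
  f <- constant_field(60)
  st <- f$base
  set.seed(5)
  lon <- runif(200, 114.001, 114.199); lat <- runif(200, 30.301, 30.499)
  hr <- sample(0:23, 200, TRUE)
  expect_equal(predict(f, lon, lat, local_time(hr * 3600 + 1800)),
               st$pm25[hr + 1], tolerance = 1e-12)
})

test_that("missing base hours interpolate across short gaps and drop long ones", {
  t0 <- local_time(0)
  pm <- c(10, NA, NA, 40, rep(50, 4), NA, NA, NA, NA, rep(60, 4))
  st <- station_series("s", 114.05, 30.35, t0 + 3600 * (seq_along(pm) - 1), pm)
  f <- concentration_field(constant_grid(50), list(st))
  # 2-hour gap interpolated linearly: hours 1,2 -> 20, 30
  expect_equal(predict(f, 114.05, 30.35, t0 + 3600 + 10), 20)
  expect_equal(predict(f, 114.05, 30.35, t0 + 2 * 3600 + 10), 30)
  # 4-hour gap (> max_gap_h = 3) stays missing
  expect_true(is.na(predict(f, 114.05, 30.35, t0 + 9 * 3600 + 10)))
  expect_equal(summary(f)$n_unusable, 4L)
})
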