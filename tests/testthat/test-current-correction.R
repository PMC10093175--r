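# Field sampling, swim decomposition, annotation, alignment.

test_that("bilinear sampling is exact at nodes and for linear fields", {
  f <- helper_linear_field()
  d <- as.Date("2022-01-23")
  # grid node: exact stored value
  expect_equal(sample_field(f, "u", -82, 19, d), 0.1 * (-82 + 81))
  # linear in lon: interpolation exact anywhere
  for (q in list(c(-81.77, 18.3), c(-79.1, 22.9), c(-83.99, 17.01))) {
    expect_equal(sample_field(f, "u", q[1], q[2], d), 0.1 * (q[1] + 81),
                 tolerance = 1e-12)
  }
  # uniform variable independent of position
  expect_equal(sample_field(f, "v", -80.123, 20.456, d), 0.05)
  # outside extent -> NA
  expect_true(is.na(sample_field(f, "u", -90, 20, d)))
  expect_error(sample_field(f, "nope", -80, 20, d), "unknown")
})

test_that("masked neighbors renormalize; all-missing yields NA not zero", {
  lon <- c(0, 1); lat <- c(0, 1)
  u <- array(c(2, NA, NA, NA), c(2, 2, 1))
  f <- gridded_field(lon, lat, as.Date("2022-01-22"), vars = list(u = u))
  # only one live neighbor: value = that neighbor
  expect_equal(sample_field(f, "u", 0.5, 0.5, as.Date("2022-01-22")), 2)
  u2 <- array(NA_real_, c(2, 2, 1))
  f2 <- gridded_field(lon, lat, as.Date("2022-01-22"), vars = list(u = u2))
  expect_true(is.na(sample_field(f2, "u", 0.5, 0.5,
                                 as.Date("2022-01-22"))))
})

test_that("decomposition closes exactly and zero current is the identity", {
  tr <- helper_straight_track(6)
  f0 <- helper_uniform_field(0, 0)
  dc <- decompose_track(tr, f0)
  ok <- !is.na(dc$ground_east)
  expect_equal(dc$swim_east[ok] + dc$cur_east[ok], dc$ground_east[ok],
               tolerance = 1e-9)
  expect_equal(dc$corr_lon, tr$lon, tolerance = 1e-9)
  expect_equal(dc$corr_lat, tr$lat, tolerance = 1e-9)
})

test_that("a stationary animal in uniform current has swim = -current and a collapsing corrected track", {
  f <- helper_uniform_field(0.2, 0.1, days = 8)
  tr <- helper_straight_track(6, step_north_km = 0)  # stationary
  dc <- decompose_track(tr, f)
  ok <- !is.na(dc$swim_east)
  expect_equal(dc$swim_east[ok], rep(-0.2 * 86.4, sum(ok)),
               tolerance = 1e-9)
  expect_equal(dc$swim_north[ok], rep(-0.1 * 86.4, sum(ok)),
               tolerance = 1e-9)
  # corrected trajectory drifts upstream at the swim velocity (the
  # animal's active motion), starting from the first position
  expect_equal(dc$corr_lon[1], tr$lon[1])
  d1 <- great_circle_km(dc$corr_lon[1], dc$corr_lat[1],
                        dc$corr_lon[2], dc$corr_lat[2])
  expect_equal(d1, 86.4 * sqrt(0.2^2 + 0.1^2), tolerance = 0.05)
})

test_that("recovered swim vectors match simulator truth on a mixed cohort", {
  rel_err <- c()
  for (r in 1:3) {
    kind <- if (r %% 2) "uniform" else "composite"
    spec <- current_field_spec(kind, u0 = -0.25, v0 = 0.1,
                               vortex_peak_ms = 0.35,
                               vortex_radius_km = 250, res_deg = 0.25,
                               days = 12)
    f <- build_field(spec, r)
    sp <- swimmer_spec(-81, 19.5, goal_lon = -79, goal_lat = 22,
                       mean_speed_kmday = 35, duration_days = 8)
    sm <- simulate_swimmer(sp, f, seed = 500 + r)
    tru <- sm$daily
    tr <- data.frame(id = "T1", day = tru$day, time = tru$time,
                     lon = tru$lon, lat = tru$lat)
    class(tr) <- c("regular_track", "data.frame")
    dc <- decompose_track(tr, f)
    k <- nrow(tru) - 1
    err <- sqrt((dc$swim_east[1:k] - tru$swim_east[2:(k + 1)])^2 +
                  (dc$swim_north[1:k] - tru$swim_north[2:(k + 1)])^2)
    rel_err <- c(rel_err, err / sqrt(tru$swim_east[2:(k + 1)]^2 +
                                       tru$swim_north[2:(k + 1)]^2))
  }
  expect_lt(median(rel_err), 0.05)
})

test_that("missing current propagates as missing, never zero-filled", {
  f <- helper_uniform_field(0.2, 0, days = 3)
  tr <- helper_straight_track(6)  # 6 days, field covers 3
  dc <- decompose_track(tr, f)
  expect_true(any(dc$missing_current, na.rm = TRUE))
  miss <- which(dc$missing_current)
  expect_true(all(is.na(dc$swim_east[miss])))
})

test_that("annotation: uniform SST, empty sargassum radius, full patch", {
  lon <- seq(-82, -80, 0.01); lat <- seq(19, 21, 0.01)
  day <- as.Date("2022-01-22") + 0:2
  sst <- array(27, c(length(lon), length(lat), 3))
  u <- array(0.1, dim(sst)); v <- array(0, dim(sst))
  sarg <- array(3.5, dim(sst))
  f <- gridded_field(lon, lat, day,
                     vars = list(u = u, v = v, sst = sst,
                                 sargassum = sarg))
  tr <- helper_straight_track(3, step_north_km = 5, lon = -81, lat0 = 20)
  an <- annotate_track(tr, f, sarg_radius_km = 1)
  expect_equal(an$sst, rep(27, 3))
  expect_equal(an$cur_speed_kmday, rep(0.1 * 86.4, 3), tolerance = 1e-9)
  # uniform patch fully covering the radius -> exactly the density
  expect_equal(an$sargassum, rep(3.5, 3))
  # coarse grid: no cell center within 1 km -> missing
  f2 <- helper_uniform_field(0.1, 0, days = 3, res = 0.5)
  an2 <- annotate_track(helper_straight_track(3, lon = -81.3, lat0 = 19.1),
                        f2, sarg_radius_km = 1)
  expect_true(all(is.na(an2$sargassum)))
  expect_false(any(an2$sargassum_valid))
})

test_that("alignment classifies opposing/following with the 90-degree closed rule", {
  dc <- data.frame(id = "T1", day = 1:4, date = as.Date("2022-01-22") + 1:4,
                   swim_east = c(-10, 10, 0, 10),
                   swim_north = c(0, 0, 10, 10),
                   cur_east = c(10, 10, 10, 0),
                   cur_north = c(0, 0, 0, 10))
  al <- alignment_series(dc)
  expect_equal(al$alignment, c("opposing", "following", "opposing",
                               "following"))
  expect_equal(abs(al$angle_deg), c(180, 0, 90, 45))
  # zero-magnitude vectors are skipped
  dc0 <- dc; dc0$swim_east[1] <- 0; dc0$swim_north[1] <- 0
  expect_equal(nrow(alignment_series(dc0)), 3)
})

test_that("corrected-trajectory decomposition is idempotent under a zero field", {
  f <- helper_uniform_field(0.3, -0.2, days = 8)
  z <- helper_uniform_field(0, 0, days = 8)
  tr <- helper_straight_track(6)
  dc <- decompose_track(tr, f)
  tr2 <- data.frame(id = "T1", day = tr$day, time = tr$time,
                    lon = dc$corr_lon, lat = dc$corr_lat)
  class(tr2) <- c("regular_track", "data.frame")
  dc2 <- decompose_track(tr2, z)
  ok <- !is.na(dc$swim_east)
  expect_equal(dc2$swim_east[ok], dc$swim_east[ok], tolerance = 1e-6)
  expect_equal(dc2$swim_north[ok], dc$swim_north[ok], tolerance = 1e-6)
})
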