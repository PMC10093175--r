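# Synthetic world: fields, swimmers, drifters, observation noise, cohorts.

test_that("uniform field realizes constant u/v and bounded SST", {
  f <- helper_uniform_field(u0 = 0.3, v0 = 0)
  expect_true(all(f$vars$u == 0.3))
  expect_true(all(f$vars$v == 0))
  expect_true(all(f$vars$sst >= 20 & f$vars$sst <= 33))
  expect_true(all(f$vars$sargassum >= 0))
})

test_that("vortex field is clockwise with Rankine tangential profile", {
  spec <- current_field_spec("vortex", vortex_lon = -81, vortex_lat = 20,
                             vortex_peak_ms = 0.5, vortex_radius_km = 100,
                             res_deg = 0.1, days = 2)
  f <- build_field(spec, seed = 1)
  ev <- attr(f, "evaluate")
  # center: speed ~ 0
  c0 <- ev(-81, 20)
  expect_lt(sqrt(c0$u^2 + c0$v^2), 1e-9)
  # at the core radius due east of center: tangential = peak, southward
  kmdeg <- 6371 * pi / 180
  lon_r <- -81 + 100 / (kmdeg * cos(20 * pi / 180))
  cr <- ev(lon_r, 20)
  expect_equal(sqrt(cr$u^2 + cr$v^2), 0.5, tolerance = 1e-6)
  expect_lt(cr$v, 0)  # clockwise: southward on the east side
  # far field decays
  cf <- ev(-81 + 8, 20)
  expect_lt(sqrt(cf$u^2 + cf$v^2), 0.1)
  # finite-difference curl oracle: negative (clockwise) everywhere sampled
  h <- 1e-3
  for (pt in list(c(-81.4, 20.2), c(-80.7, 19.8), c(-81, 20.6))) {
    dv_dx <- (ev(pt[1] + h, pt[2])$v - ev(pt[1] - h, pt[2])$v) /
      (2 * h * kmdeg * cos(pt[2] * pi / 180))
    du_dy <- (ev(pt[1], pt[2] + h)$u - ev(pt[1], pt[2] - h)$u) /
      (2 * h * kmdeg)
    expect_lt(dv_dx - du_dy, 0)
  }
})

test_that("deterministic swimmer in still water goes straight at its speed", {
  zf <- helper_uniform_field(0, 0)
  sp <- swimmer_spec(-81, 19, goal_lon = -81, goal_lat = 24,
                     mean_speed_kmday = 30, speed_cv = 0, kappa = Inf,
                     duration_days = 4)
  sm <- simulate_swimmer(sp, zf, seed = 1)
  expect_equal(sm$daily$lon, rep(-81, 5), tolerance = 1e-9)
  d1 <- great_circle_km(sm$daily$lon[1], sm$daily$lat[1],
                        sm$daily$lon[2], sm$daily$lat[2])
  expect_equal(d1, 30, tolerance = 1e-3)
  expect_equal(sm$daily$swim_north[-1], rep(30, 4), tolerance = 1e-9)
})

test_that("zero-swim drifter matches analytic uniform advection", {
  f <- helper_uniform_field(u0 = 0.5, v0 = 0)
  dr <- simulate_drifter(-81, 19.5, f, duration_days = 1, seed = 1)
  disp <- great_circle_km(-81, 19.5, dr$daily$lon[2], dr$daily$lat[2])
  expect_equal(disp, 0.5 * 86.4, tolerance = 1e-3)
  expect_gt(dr$daily$lon[2], -81)  # eastward
  # zero field -> stationary
  zf <- helper_uniform_field(0, 0)
  dr0 <- simulate_drifter(-81, 19.5, zf, duration_days = 1, seed = 1)
  expect_equal(dr0$daily$lon[2], -81)
  expect_equal(dr0$daily$lat[2], 19.5)
})

test_that("drifter released at vortex radius orbits with small radius drift", {
  spec <- current_field_spec("vortex", vortex_lon = -81, vortex_lat = 20,
                             vortex_peak_ms = 0.5, vortex_radius_km = 100,
                             res_deg = 0.25, days = 30,
                             lon_range = c(-84, -78), lat_range = c(17, 23))
  f <- build_field(spec, 1)
  kmdeg <- 6371 * pi / 180
  r0 <- 100
  # period of a solid-body orbit at the core radius
  period_days <- 2 * pi * r0 / (0.5 * 86.4)
  dr <- simulate_drifter(-81 + r0 / (kmdeg * cos(20 * pi / 180)), 20, f,
                         duration_days = ceiling(period_days), seed = 1)
  rad <- sqrt(((dr$fine$lon + 81) * kmdeg * cos(dr$fine$lat * pi / 180))^2 +
                ((dr$fine$lat - 20) * kmdeg)^2)
  expect_lt(abs(max(rad) - r0) / r0, 0.02)
  expect_lt(abs(min(rad) - r0) / r0, 0.02)
})

test_that("recovered daily ground velocity closes to swim + current at a finer step", {
  spec <- current_field_spec("vortex", vortex_lon = -80.8, vortex_lat = 20.2,
                             vortex_peak_ms = 0.4, vortex_radius_km = 200,
                             res_deg = 0.25, days = 10)
  f <- build_field(spec, 1)
  run <- function(dt) {
    sp <- swimmer_spec(-81, 19.5, goal_lon = -79, goal_lat = 22,
                       mean_speed_kmday = 30, speed_cv = 0, kappa = Inf,
                       duration_days = 5, dt_days = dt)
    simulate_swimmer(sp, f, seed = 9)
  }
  coarse <- run(0.05); fine <- run(0.005)
  # daily positions insensitive to 10x step refinement
  err <- great_circle_km(coarse$daily$lon, coarse$daily$lat,
                         fine$daily$lon, fine$daily$lat)
  expect_lt(max(err), 1)
  # ground displacement = mean(swim) + mean(current) per day
  for (d in 2:5) {
    g <- velocity_between(coarse$daily$lon[d - 1], coarse$daily$lat[d - 1],
                          coarse$daily$lon[d], coarse$daily$lat[d], 1)
    expect_equal(g$east,
                 coarse$daily$swim_east[d] + coarse$daily$cur_east[d],
                 tolerance = 0.5)
    expect_equal(g$north,
                 coarse$daily$swim_north[d] + coarse$daily$cur_north[d],
                 tolerance = 0.5)
  }
})

test_that("argos observation with zero ellipse scale lies on the true track", {
  zf <- helper_uniform_field(0, 0)
  sp <- swimmer_spec(-81, 19, goal_lon = -80, goal_lat = 22,
                     mean_speed_kmday = 25, duration_days = 4)
  sm <- simulate_swimmer(sp, zf, seed = 2)
  tiny <- argos_noise_spec(class_scale_km = rep(1e-9, 6))
  fx <- observe_argos(sm, tiny, id = "T1", seed = 3)
  tru_lon <- approx(as.numeric(sm$fine$time), sm$fine$lon,
                    xout = as.numeric(fx$time))$y
  expect_equal(fx$lon, tru_lon, tolerance = 1e-6)
  expect_true(all(diff(as.numeric(fx$time)) > 0))
  expect_true(all(fx$smaj_km >= fx$smin_km))
})

test_that("daily fix counts follow the negative-binomial law", {
  zf <- helper_uniform_field(0, 0, days = 110)
  sp <- swimmer_spec(-81, 19, goal_lon = -81, goal_lat = 19.5,
                     mean_speed_kmday = 1, speed_cv = 0.1, kappa = 1,
                     duration_days = 100)
  sm <- simulate_swimmer(sp, zf, seed = 4)
  spec <- argos_noise_spec(fixes_per_day_mean = 12, fixes_per_day_size = 5)
  fx <- observe_argos(sm, spec, seed = 5)
  days <- floor(as.numeric(difftime(fx$time, sm$fine$time[1],
                                    units = "days")))
  counts <- tabulate(days + 1, nbins = 100)
  # mean within 3 SE of the negative-binomial mean
  se <- sqrt(12 + 12^2 / 5) / sqrt(100)
  expect_lt(abs(mean(counts) - 12), 3 * se)
})

test_that("argos position noise reproduces the ellipse covariance", {
  # single repeated point, one class, fixed ellipse shape
  n <- 3000
  fine <- data.frame(time = as.POSIXct("2022-01-22", tz = "UTC") +
                       seq(0, n * 3600, by = 3600),
                     lon = -81, lat = 20)
  spec <- argos_noise_spec(fixes_per_day_mean = 24, fixes_per_day_size = 1e6,
                           class_names = "A", class_probs = 1,
                           class_scale_km = 4)
  fx <- observe_argos(fine, spec, seed = 6)
  kmdeg <- 6371 * pi / 180
  east <- (fx$lon + 81) * kmdeg * cos(20 * pi / 180)
  north <- (fx$lat - 20) * kmdeg
  # empirical total variance vs sum of per-fix expected ellipse variances
  expected <- mean(fx$smaj_km^2 + fx$smin_km^2)
  expect_equal(var(east) + var(north), expected, tolerance = 0.1)
})

test_that("cohorts are deterministic under seed and honor the residential count", {
  co1 <- make_cohort("jan", n_turtles = 8, n_residential = 4, seed = 31,
                     duration_days = 4, res_deg = 0.5)
  co2 <- make_cohort("jan", n_turtles = 8, n_residential = 4, seed = 31,
                     duration_days = 4, res_deg = 0.5)
  expect_identical(co1$fixes, co2$fixes)
  expect_identical(co1$covariates, co2$covariates)
  expect_equal(sum(co1$covariates$residential), 4)
  # residential fixes never leave the buffer
  res_ids <- co1$covariates$id[co1$covariates$residential]
  rf <- co1$fixes[co1$fixes$id %in% res_ids, ]
  expect_true(all(point_buffer_km(rf$lon, rf$lat, co1$island) <= 10))
  # degenerate n = 1 cohort is valid
  co3 <- make_cohort("jul", n_turtles = 1, seed = 5, duration_days = 3,
                     res_deg = 0.5)
  expect_equal(nrow(co3$covariates), 1)
})

test_that("jan-like goal bearings span at least three quadrants", {
  co <- make_cohort("jan", n_turtles = 12, n_residential = 0, seed = 7,
                    duration_days = 2, res_deg = 0.5)
  q <- unique(floor(co$covariates$goal_bearing / 90))
  expect_gte(length(q), 3)
})

test_that("von Mises sampler concentrates around its mean", {
  set.seed(8)
  x <- rvonmises(2000, pi / 3, 5)
  m <- circ_mean_sd(x)
  expect_equal(m$mean_deg, 60, tolerance = 3)
  expect_gt(m$rbar, 0.85)
  u <- rvonmises(2000, 0, 0)
  expect_lt(circ_mean_sd(u)$rbar, 0.06)
})
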