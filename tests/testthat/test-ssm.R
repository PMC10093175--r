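# State-space regularization: buffer filter, CTRW likelihood, smoother.

test_that("buffer filter conserves counts and keeps the boundary outward", {
  isl <- make_island()
  kmdeg <- 6371 * pi / 180
  # points due north of the island center at known distances from the
  # northern coast (semi-minor axis 8 km)
  lat_at <- function(d_km) 19.3 + (8 + d_km) / kmdeg
  fx <- helper_exact_fixes(0:3, rep(-81.25, 4),
                           c(lat_at(-5), lat_at(5), lat_at(10.000),
                             lat_at(30)))
  bf <- buffer_filter(fx, isl, 10)
  expect_equal(nrow(bf$retained) + bf$removed_count, nrow(fx))
  # the fix at exactly 10 km is retained (closed outward), inside ones drop
  expect_true(all(bf$retained$lat >= lat_at(10) - 1e-9))
  expect_equal(bf$removed_count, 2L)
  expect_true("T1" %in% bf$unusable)  # only 2 retained fixes
  # all inside -> empty retained set
  inside <- helper_exact_fixes(0:4, rep(-81.25, 5), rep(19.3, 5))
  bf2 <- buffer_filter(inside, isl, 10)
  expect_equal(nrow(bf2$retained), 0)
  expect_error(buffer_filter(fx, isl[1:2, ], 10), "polygon")
})

test_that("sigma_p matches the closed-form MLE with near-zero ellipses", {
  set.seed(101)
  n <- 120
  tt <- cumsum(runif(n, 0.2, 0.8))
  sigma_true <- 5
  kmdeg <- 6371 * pi / 180
  x <- cumsum(c(0, rnorm(n - 1, 0, sigma_true * sqrt(diff(tt)))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sigma_true * sqrt(diff(tt)))))
  fx <- helper_exact_fixes(tt, -81 + x / (kmdeg * cos(20 * pi / 180)),
                           20 + y / kmdeg, smaj = 1e-6)
  fit <- fit_rw(fx)
  # closed-form MLE of sigma^2 from increments (both coordinates pooled)
  s2_hat <- sum(diff(x)^2 / diff(tt) + diff(y)^2 / diff(tt)) / (2 * (n - 1))
  expect_equal(fit$sigma_p, sqrt(s2_hat), tolerance = 0.02)
  expect_true(fit$converged)
})

test_that("likelihood is locally maximal at the estimate", {
  set.seed(7)
  zf <- helper_uniform_field(0.1, 0.1, days = 12)
  sp <- swimmer_spec(-81, 19, goal_lon = -79.5, goal_lat = 21,
                     mean_speed_kmday = 30, duration_days = 8)
  fx <- observe_argos(simulate_swimmer(sp, zf, seed = 1), id = "T1",
                      seed = 2)
  fit <- fit_rw(fx)
  nll <- function(s) turtledrift:::.ssm_nll(s, fit$prep)
  expect_lte(nll(fit$sigma_p), nll(fit$sigma_p * 0.5))
  expect_lte(nll(fit$sigma_p), nll(fit$sigma_p * 2))
})

test_that("preconditions: too few fixes or too short a span error", {
  fx <- helper_exact_fixes(c(0, .1, .2), c(0, .1, .2), c(0, 0, 0))
  expect_error(fit_rw(fx), ">= 4")
  fx2 <- helper_exact_fixes(c(0, .2, .4, .6), runif(4), runif(4))
  expect_error(fit_rw(fx2), "span")
})

test_that("two exact fixes bridge linearly at the daily grid", {
  fx <- helper_exact_fixes(c(0, 0.5, 2, 2.2, 3.9, 4),
                           c(0, 0.05, 0.2, 0.22, 0.39, 0.4),
                           c(0, 0.1, 0.4, 0.44, 0.78, 0.8))
  fit <- fit_rw(fx)
  tr <- smooth_daily(fx, fit)
  # all fixes are exact and collinear with position linear in time, so
  # every daily state must lie on the line (conditional mean of a bridge)
  expect_equal(tr$lon, c(0, 0.1, 0.2, 0.3, 0.4), tolerance = 1e-6)
  expect_equal(tr$lat, 2 * tr$lon, tolerance = 1e-6)
  # smoother passes through near-exact fixes
  expect_lt(great_circle_km(tr$lon[1], tr$lat[1], 0, 0), 1e-6)
})

test_that("single fix degenerates to a one-day constant track", {
  fx <- helper_exact_fixes(0, -81, 20)
  tr <- smooth_daily(fx)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$lon, -81)
  expect_equal(tr$sd_km, 0)
})

test_that("predicted SD is maximal mid-gap and minimal at fix-dense days", {
  fx <- helper_exact_fixes(c(0, 0.2, 0.5, 1, 6, 6.3, 7),
                           c(0, 0.01, 0.02, 0.05, 0.5, 0.52, 0.6),
                           rep(0, 7), smaj = 0.5)
  fit <- fit_rw(fx)
  tr <- smooth_daily(fx, fit)
  # days 2..5 sit inside the 1->6 gap; SD there exceeds the endpoints
  gap_sd <- tr$sd_km[tr$day %in% 2:5]
  expect_gt(min(gap_sd), tr$sd_km[tr$day == 1])
  expect_gt(min(gap_sd), tr$sd_km[tr$day == 7])
  # unimodal inside the gap: rises then falls
  expect_true(which.max(gap_sd) %in% 2:3)
})

test_that("smoothing beats the nearest raw fix against simulation truth", {
  zf <- helper_uniform_field(0.15, -0.1, days = 14)
  sp <- swimmer_spec(-81, 19, goal_lon = -79, goal_lat = 22,
                     mean_speed_kmday = 35, duration_days = 10)
  rmse_sm <- rmse_raw <- numeric(5)
  for (r in 1:5) {
    sm <- simulate_swimmer(sp, zf, seed = 300 + r)
    fx <- observe_argos(sm, argos_noise_spec(), id = "T1", seed = 400 + r)
    fit <- fit_rw(fx)
    tr <- smooth_daily(fx, fit)
    tru <- sm$daily
    k <- min(nrow(tr), nrow(tru))
    # nearest raw fix to each daily truth time
    near <- vapply(seq_len(k), function(d) {
      i <- which.min(abs(as.numeric(fx$time) - as.numeric(tru$time[d])))
      great_circle_km(fx$lon[i], fx$lat[i], tru$lon[d], tru$lat[d])
    }, numeric(1))
    off <- great_circle_km(tr$lon[1:k], tr$lat[1:k],
                           tru$lon[1:k], tru$lat[1:k])
    rmse_sm[r] <- sqrt(mean(off^2)); rmse_raw[r] <- sqrt(mean(near^2))
  }
  expect_lt(mean(rmse_sm), mean(rmse_raw))
})

test_that("over-interpolation report flags long straight bridges", {
  # gap-free track -> empty report
  fx <- helper_exact_fixes(0:5, seq(0, 0.5, 0.1), rep(0, 6))
  fit <- fit_rw(fx)
  tr <- smooth_daily(fx, fit)
  expect_equal(nrow(overinterpolation_report(fx, tr)), 0)
  # 5-day gap between exact fixes: bridge is straight, flagged
  fx2 <- helper_exact_fixes(c(0, 0.5, 1, 6, 6.5, 7),
                            c(0, 0.05, 0.1, 0.6, 0.65, 0.7),
                            rep(0, 6))
  fit2 <- fit_rw(fx2)
  tr2 <- smooth_daily(fx2, fit2)
  rep2 <- overinterpolation_report(fx2, tr2)
  expect_equal(nrow(rep2), 1)
  expect_equal(rep2$gap_days, 5)
  expect_gt(rep2$straightness, 0.99)
  expect_true(rep2$flagged)
})

test_that("regularize_cohort skips unusable animals and reports removals", {
  co <- make_cohort("jan", n_turtles = 4, n_residential = 2, seed = 12,
                    duration_days = 5, res_deg = 0.5)
  reg <- regularize_cohort(co$fixes, co$island, 10)
  disp <- co$covariates$id[!co$covariates$residential]
  expect_true(all(names(reg$tracks) %in% disp))
  res <- co$covariates$id[co$covariates$residential]
  expect_true(all(res %in% reg$skipped))
})
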