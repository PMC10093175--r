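# Persistence GAMM: design construction, penalized fit, ARMA machinery,
# elimination and prediction.

small_series <- function(seed = 1, n_animals = 8, n_days = 12,
                         effect = 0, phi = 0, sd_b = 0, sd_e = 5,
                         bowl = NULL) {
  set.seed(seed)
  rows <- list()
  for (a in seq_len(n_animals)) {
    per <- if (a <= n_animals / 2) "Jan" else "Jul"
    lat <- 19 + cumsum(rnorm(n_days, 0, 0.25))
    lon <- -81 + cumsum(rnorm(n_days, 0, 0.25))
    mu <- effect * (per == "Jan")
    if (!is.null(bowl)) mu <- mu + bowl(lat, lon)
    e <- if (phi > 0)
      as.numeric(arima.sim(list(ar = phi), n_days,
                           sd = sd_e * sqrt(1 - phi^2))) else
      rnorm(n_days, 0, sd_e)
    rows[[a]] <- data.frame(
      id = sprintf("A%02d", a), day = seq_len(n_days) + 1,
      lat = lat, lon = lon,
      persistence = mu + rnorm(1, 0, sd_b) + e, period = per,
      sst = 27 - 0.35 * (lat - 19) + rnorm(n_days, 0, 0.05),
      cur_speed_kmday = 15 + 5 * sin(lon),
      sargassum = pmax(0, rnorm(n_days, 4, 6)),
      weight_kg = round(runif(1, 5, 25), 1))
  }
  do.call(rbind, rows)
}

test_that("design matrices have the expected structure", {
  d <- small_series()
  dd <- build_design(d, gamm_spec(k = 10))
  expect_equal(nrow(dd$X), nrow(d))
  expect_true(all(c("(Intercept)", "sst", "periodJan", "lat_s",
                    "lon_s") %in% colnames(dd$X)))
  expect_equal(ncol(dd$B), 10 - 3)
  expect_equal(dim(dd$S), c(7, 7))
  expect_true(all(eigen(dd$S, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  expect_equal(ncol(dd$Zb), 8)
  expect_equal(qr(cbind(dd$X, dd$B))$rank, ncol(dd$X) + ncol(dd$B))
  # duplicate locations give identical basis rows
  d2 <- d; d2$lat[2] <- d2$lat[1]; d2$lon[2] <- d2$lon[1]
  dd2 <- build_design(d2, gamm_spec(k = 10))
  expect_equal(dd2$B[1, ], dd2$B[2, ])
  # single period drops the period column with a note
  d3 <- d[d$period == "Jan", ]
  dd3 <- build_design(d3, gamm_spec(k = 10))
  expect_false(any(grepl("period", colnames(dd3$X))))
  expect_match(dd3$notes, "single period")
})

test_that("the smoother reproduces a linear surface exactly (null space)", {
  d <- small_series(2)
  d$persistence <- 3 + 2 * d$lat - 1.5 * d$lon
  f <- fit_pgamm(d, gamm_spec(fixed = character(0), k = 12,
                              random_intercept = FALSE))
  expect_lt(max(abs(f$residuals)), 1e-6)
})

test_that("with ARMA(0,0) and no random effect the fit matches a direct penalized LS oracle", {
  d <- small_series(3)
  f <- fit_pgamm(d, gamm_spec(fixed = c("sst", "period"), k = 12,
                              random_intercept = FALSE))
  dd <- f$dd
  C <- cbind(dd$X, dd$B)
  # independent oracle: augmented least squares at the fitted lambda
  Sm <- f$lambda_s * dd$S
  es <- eigen((Sm + t(Sm)) / 2, symmetric = TRUE)
  L <- es$vectors %*% diag(sqrt(pmax(es$values, 0))) %*% t(es$vectors)
  aug <- rbind(C, cbind(matrix(0, ncol(dd$B), ncol(dd$X)), L))
  theta_oracle <- qr.solve(aug, c(dd$y, rep(0, ncol(dd$B))))
  expect_equal(f$theta, as.vector(theta_oracle), tolerance = 1e-6)
})

test_that("pure-noise data yield a near-null smoother and null slopes", {
  hits <- 0
  for (r in 1:5) {
    d <- small_series(100 + r, sd_e = 5)
    f <- fit_pgamm(d, gamm_spec(k = 12))
    slopes <- f$coefficients[f$coefficients$term != "(Intercept)", ]
    hits <- hits + all(abs(slopes$estimate) < 2.5 * slopes$se)
    expect_lt(f$smoother$edf, 8)
  }
  expect_gte(hits, 4)
})

test_that("a known smooth bowl surface is recovered", {
  bowl <- function(lat, lon) 10 - 8 * ((lat - 19.5)^2 + (lon + 80.5)^2)
  d <- small_series(7, n_animals = 12, n_days = 20, sd_e = 2,
                    bowl = bowl)
  f <- fit_pgamm(d, gamm_spec(fixed = character(0), k = 20,
                              random_intercept = FALSE))
  truth <- bowl(d$lat, d$lon)
  expect_gt(cor(f$fitted, truth), 0.9)
  rng <- diff(range(truth))
  expect_lt(sqrt(mean((f$fitted - truth)^2)) / rng, 0.15)
  # grid evaluation correlates with the true surface
  g <- persistence_surface(f, n_grid = 15)
  expect_gt(cor(g$fit, bowl(g$lat, g$lon)), 0.9)
})

test_that("pooled ARMA MLE recovers an AR(1) and selection finds its order", {
  set.seed(31)
  runs <- replicate(12, as.numeric(arima.sim(list(ar = 0.7), 25)),
                    simplify = FALSE)
  fit <- arma_mle(runs, 1, 0)
  expect_equal(fit$ar, 0.7, tolerance = 0.12)
  sel_hits <- 0; white_hits <- 0
  for (r in 1:10) {
    set.seed(200 + r)
    ar_runs <- replicate(10, as.numeric(arima.sim(list(ar = 0.7), 22)),
                         simplify = FALSE)
    s <- select_arma(ar_runs)
    sel_hits <- sel_hits + (s$p >= 1 && s$q <= 1)
    wn_runs <- replicate(10, rnorm(22), simplify = FALSE)
    s0 <- select_arma(wn_runs)
    white_hits <- white_hits + (s0$p == 0 && s0$q == 0)
  }
  expect_gte(sel_hits, 9)
  expect_gte(white_hits, 9)
  # deterministic on fixed input
  s1 <- select_arma(runs); s2 <- select_arma(runs)
  expect_identical(s1[c("p", "q")], s2[c("p", "q")])
  # too-short series -> (0,0) with note
  s3 <- select_arma(list(rnorm(5)))
  expect_equal(c(s3$p, s3$q), c(0L, 0L))
  expect_match(s3$note, "short")
})

test_that("whitened residuals of a correctly specified AR(1) fit pass Ljung-Box", {
  pass <- 0
  for (r in 1:5) {
    d <- small_series(400 + r, phi = 0.5, sd_e = 6, sd_b = 2)
    f <- fit_pgamm(d, gamm_spec(fixed = "period", k = 10,
                                arma_p = 1, arma_q = 0))
    lb <- Box.test(f$whitened_residuals, lag = 10, type = "Ljung-Box")
    pass <- pass + (lb$p.value > 0.05)
  }
  expect_gte(pass, 4)
})

test_that("backward elimination keeps a strong single candidate and can empty the set", {
  d <- small_series(55, effect = 10, sd_e = 4)
  be <- backward_eliminate(d, gamm_spec(fixed = "period", k = 10))
  expect_equal(be$spec$fixed, "period")
  # elimination never raises the ML AIC above the full model
  expect_lte(min(be$trace$aic), be$trace$aic[1] + 1e-9)
  d0 <- small_series(56, effect = 0, sd_e = 4)
  be0 <- backward_eliminate(d0, gamm_spec(fixed = c("sst", "weight_kg"),
                                          k = 10))
  expect_true(length(be0$spec$fixed) <= 2)  # dropping is allowed, even to empty
})

test_that("prediction at training rows equals fitted values; random effects optional", {
  d <- small_series(8, effect = 5, sd_b = 2)
  f <- fit_pgamm(d, gamm_spec(fixed = "period", k = 10))
  pr <- predict(f, f$dd$data, include_random = TRUE)
  expect_equal(pr$fit, f$fitted, tolerance = 1e-8)
  expect_false(any(pr$population_level))
  # unknown animal falls back to population level
  nd <- f$dd$data[1:2, ]; nd$id <- "ZZZ"
  pr2 <- predict(f, nd, include_random = TRUE)
  expect_true(all(pr2$population_level))
  # extrapolation flagged
  nd2 <- f$dd$data[1, ]; nd2$lat <- nd2$lat + 50
  expect_true(predict(f, nd2)$extrapolated)
})

test_that("an independent GAMM implementation agrees on the spatial surface", {
  skip_if_not_installed("mgcv")
  bowl <- function(lat, lon) 6 * sin(2 * lat - 38) + 4 * cos(2 * lon + 162)
  d <- small_series(91, n_animals = 12, n_days = 20, sd_e = 2, bowl = bowl)
  f <- fit_pgamm(d, gamm_spec(fixed = character(0), k = 20,
                              random_intercept = FALSE))
  g <- mgcv::gam(persistence ~ s(lat, lon, k = 20), data = d)
  expect_gt(cor(f$fitted, as.numeric(fitted(g))), 0.95)
})
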