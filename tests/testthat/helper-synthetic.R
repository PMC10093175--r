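# Shared fixtures, all generated in code.

# independent haversine oracle (not the package's implementation)
oracle_haversine_km <- function(lon1, lat1, lon2, lat2, R = 6371) {
  to_r <- pi / 180
  dphi <- (lat2 - lat1) * to_r
  dlam <- (lon2 - lon1) * to_r
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_r) * cos(lat2 * to_r) * sin(dlam / 2)^2
  2 * R * asin(sqrt(pmin(pmax(a, 0), 1)))
}

# small uniform current field
helper_uniform_field <- function(u0 = 0.3, v0 = 0, days = 6,
                                 res = 0.5, seed = 1) {
  build_field(current_field_spec("uniform", u0 = u0, v0 = v0,
                                 days = days, res_deg = res), seed = seed)
}

# field with an analytic linear-in-lon u variable, handy for exactness
helper_linear_field <- function() {
  lon <- seq(-84, -78, by = 0.5)
  lat <- seq(17, 23, by = 0.5)
  days <- seq(as.Date("2022-01-22"), by = "day", length.out = 4)
  u <- array(rep(outer(lon, lat, function(x, y) 0.1 * (x + 81)),
                 length(days)),
             c(length(lon), length(lat), length(days)))
  v <- array(0.05, dim(u))
  gridded_field(lon, lat, days, vars = list(u = u, v = v))
}

# deterministic regular track along a meridian
helper_straight_track <- function(n_days = 10, step_north_km = 30,
                                  id = "T1", lon = -81, lat0 = 19) {
  kmdeg <- 6371 * pi / 180
  lat <- lat0 + (0:(n_days - 1)) * step_north_km / kmdeg
  out <- data.frame(id = id, day = 0:(n_days - 1),
                    time = as.POSIXct("2022-01-22 12:00:00",
                                      tz = "UTC") + (0:(n_days - 1)) * 86400,
                    lon = lon, lat = lat, sd_km = 0, n_fixes = 1L)
  class(out) <- c("regular_track", "data.frame")
  out
}

# minimal exact fix table (zero-size ellipses)
helper_exact_fixes <- function(times_days, lon, lat, id = "T1",
                               smaj = 1e-6) {
  data.frame(id = id,
             time = as.POSIXct("2022-01-22 00:00:00", tz = "UTC") +
               times_days * 86400,
             lon = lon, lat = lat,
             smaj_km = smaj, smin_km = smaj, eor_deg = 0, class = "3")
}

# brute-force two-sample Watson U2 via direct CDF comparison (oracle,
# independent of the package's cumulative-rank implementation)
oracle_watson_u2 <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  all_a <- sort(c(x, y))
  Fx <- vapply(all_a, function(a) mean(x <= a), numeric(1))
  Fy <- vapply(all_a, function(a) mean(y <= a), numeric(1))
  d <- Fx - Fy
  n * m / N^2 * sum((d - mean(d))^2)
}
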