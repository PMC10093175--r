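# Synthetic world: current fields, goal-directed swimmers, passive drifters,
# ARGOS-like observation noise, and scenario cohorts. Everything downstream
# (regularization, current correction, metrics, circular tests, the
# persistence model) is testable against the exact ground truth these
# generators record. All randomness flows from the seed argument of each
# top-level generator.

#' Specify a synthetic ocean-current field
#'
#' Supported regimes: `uniform` (constant background flow), `vortex`
#' (clockwise Rankine eddy: solid-body core, 1/r decay outside the radius),
#' and `composite` (uniform + vortex). The vortex emulates a broad
#' mesoscale clockwise circulation; the uniform regime a steady drift.
#'
#' @param kind one of "uniform", "vortex", "composite".
#' @param u0,v0 background flow, m s^-1 (east, north).
#' @param vortex_lon,vortex_lat vortex center (degrees).
#' @param vortex_peak_ms peak tangential speed, m s^-1 (at the radius).
#' @param vortex_radius_km radius of the solid-body core, km.
#' @param lon_range,lat_range grid extent, degrees.
#' @param res_deg grid resolution, degrees.
#' @param start date of the first daily slice.
#' @param days number of daily slices.
#' @param sst_base mean sea-surface temperature at the grid's central
#'   latitude, deg C.
#' @return a `current_field_spec` list.
#' @export
current_field_spec <- function(kind = c("uniform", "vortex", "composite"),
                               u0 = 0, v0 = 0,
                               vortex_lon = -80.5, vortex_lat = 21,
                               vortex_peak_ms = 0.5,
                               vortex_radius_km = 250,
                               lon_range = c(-85.5, -77.5),
                               lat_range = c(16.5, 23.5),
                               res_deg = 1 / 12,
                               start = as.Date("2022-01-22"),
                               days = 30,
                               sst_base = 27) {
  kind <- match.arg(kind)
  if (res_deg <= 0) stop("config error: resolution must be > 0")
  if (vortex_peak_ms < 0) stop("config error: vortex peak speed must be >= 0")
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0)
    stop("config error: empty grid extent")
  structure(list(kind = kind, u0 = u0, v0 = v0,
                 vortex_lon = vortex_lon, vortex_lat = vortex_lat,
                 vortex_peak_ms = vortex_peak_ms,
                 vortex_radius_km = vortex_radius_km,
                 lon_range = lon_range, lat_range = lat_range,
                 res_deg = res_deg, start = as.Date(start), days = days,
                 sst_base = sst_base),
            class = "current_field_spec")
}

## closed-form (u, v) in m/s for a spec, vectorized over lon/lat
.current_eval <- function(spec) {
  force(spec)
  function(lon, lat, date = NULL) {
    u <- rep(spec$u0, length(lon))
    v <- rep(spec$v0, length(lon))
    if (spec$kind == "uniform") return(list(u = u, v = v))
    if (spec$kind == "vortex") { u[] <- 0; v[] <- 0 }
    kmdeg <- EARTH_RADIUS_KM * pi / 180
    dx <- .wrap_signed(lon - spec$vortex_lon) *
      cos(.deg2rad(spec$vortex_lat)) * kmdeg
    dy <- (lat - spec$vortex_lat) * kmdeg
    r <- sqrt(dx^2 + dy^2)
    Vt <- ifelse(r < spec$vortex_radius_km,
                 spec$vortex_peak_ms * r / spec$vortex_radius_km,
                 spec$vortex_peak_ms * spec$vortex_radius_km / pmax(r, 1e-9))
    ok <- r > 1e-9
    # clockwise: at a point due east of center the flow is southward
    u[ok] <- u[ok] + Vt[ok] * dy[ok] / r[ok]
    v[ok] <- v[ok] - Vt[ok] * dx[ok] / r[ok]
    list(u = u, v = v)
  }
}

#' Build a gridded synthetic environment
#'
#' Realizes a [current_field_spec()] on its lon/lat grid: daily `u`, `v`
#' slices (m s^-1), a daily SST field (smooth latitudinal gradient plus
#' small noise, clamped to 20-33 deg C) and a sparse, patchy, non-negative
#' weekly sargassum field (g m^-2). The returned field carries the exact
#' closed-form current evaluator as attribute `"evaluate"`, used by the
#' simulators and available as an oracle.
#'
#' @param spec a [current_field_spec()].
#' @param seed integer seed for the SST noise and sargassum patches.
#' @return a `gridded_field` (see [gridded_field()]) with variables
#'   `u`, `v`, `sst` on the daily axis and `sargassum` on a weekly axis.
#' @export
build_field <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "current_field_spec"))
  set.seed(seed)
  lon <- seq(spec$lon_range[1], spec$lon_range[2], by = spec$res_deg)
  lat <- seq(spec$lat_range[1], spec$lat_range[2], by = spec$res_deg)
  if (length(lon) < 2 || length(lat) < 2) stop("config error: empty grid")
  days <- seq(spec$start, by = "day", length.out = spec$days)
  ev <- .current_eval(spec)
  g <- expand.grid(lon = lon, lat = lat)
  uv <- ev(g$lon, g$lat)
  u1 <- matrix(uv$u, length(lon), length(lat))
  v1 <- matrix(uv$v, length(lon), length(lat))
  u <- array(rep(u1, spec$days), c(length(lon), length(lat), spec$days))
  v <- array(rep(v1, spec$days), c(length(lon), length(lat), spec$days))

  # SST: latitudinal gradient around the central latitude + grid noise
  latc <- mean(spec$lat_range)
  sst1 <- matrix(spec$sst_base - 0.35 * (g$lat - latc) +
                   rnorm(nrow(g), 0, 0.08),
                 length(lon), length(lat))
  sst1 <- pmin(pmax(sst1, 20), 33)
  sst <- array(rep(sst1, spec$days), c(length(lon), length(lat), spec$days))

  # sargassum: weekly sum of random Gaussian patches, zero background
  weeks <- seq(spec$start, by = "7 days",
               length.out = max(1L, ceiling(spec$days / 7)))
  n_patch <- 8L
  sarg <- array(0, c(length(lon), length(lat), length(weeks)))
  for (w in seq_along(weeks)) {
    cx <- runif(n_patch, spec$lon_range[1], spec$lon_range[2])
    cy <- runif(n_patch, spec$lat_range[1], spec$lat_range[2])
    amp <- rexp(n_patch, rate = 1 / 40)  # g m^-2
    wdt <- runif(n_patch, 0.15, 0.5)     # degrees
    s <- matrix(0, length(lon), length(lat))
    for (k in seq_len(n_patch))
      s <- s + amp[k] * outer(exp(-(lon - cx[k])^2 / (2 * wdt[k]^2)),
                              exp(-(lat - cy[k])^2 / (2 * wdt[k]^2)))
    s[s < 1] <- 0  # sparse: drop faint tails
    sarg[, , w] <- s
  }

  f <- gridded_field(lon, lat, days,
                     vars = list(u = u, v = v, sst = sst,
                                 sargassum = structure(sarg, time = weeks)))
  attr(f, "evaluate") <- ev
  attr(f, "spec") <- spec
  f
}

#' Specify a goal-directed swimmer
#'
#' Minimal behavioral model consistent with directed active dispersal:
#' per fine step the heading is drawn from a von Mises law centered on the
#' bearing to the goal (or on the previous heading when no goal) with
#' concentration kappa, the swim speed from a gamma law with the stated
#' mean and coefficient of variation, and the position is advanced by the
#' swim velocity plus the ambient current.
#'
#' @param release_lon,release_lat release point, degrees.
#' @param goal_lon,goal_lat goal point, degrees, or NA for no goal
#'   (correlated-heading wander; kappa = 0 gives uniform random headings).
#' @param mean_speed_kmday mean swim speed, km day^-1.
#' @param speed_cv coefficient of variation of the step speeds.
#' @param kappa heading concentration (dimensionless, >= 0).
#' @param duration_days track duration, days.
#' @param dt_days fine simulation step, fraction of a day.
#' @param start_time POSIXct (UTC) release instant.
#' @return a `swimmer_spec` list.
#' @export
swimmer_spec <- function(release_lon, release_lat,
                         goal_lon = NA, goal_lat = NA,
                         mean_speed_kmday = 35, speed_cv = 0.3,
                         kappa = 8, duration_days = 15, dt_days = 0.05,
                         start_time = as.POSIXct("2022-01-22 12:00:00",
                                                 tz = "UTC")) {
  if (kappa < 0 || mean_speed_kmday < 0 || speed_cv < 0)
    stop("config error: kappa, speed and CV must be >= 0")
  structure(list(release_lon = release_lon, release_lat = release_lat,
                 goal_lon = goal_lon, goal_lat = goal_lat,
                 mean_speed_kmday = mean_speed_kmday, speed_cv = speed_cv,
                 kappa = kappa, duration_days = duration_days,
                 dt_days = dt_days, start_time = start_time),
            class = "swimmer_spec")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; kappa = 0 falls back to the
#' uniform circular law.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return angles in radians, wrapped to [0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

## m/s current at positions/date, preferring the closed-form evaluator
.field_current <- function(field, lon, lat, date) {
  ev <- attr(field, "evaluate")
  if (!is.null(ev)) return(ev(lon, lat, date))
  list(u = sample_field(field, "u", lon, lat, date),
       v = sample_field(field, "v", lon, lat, date))
}

#' Simulate a goal-directed swimmer advected by a current field
#'
#' Fine-step Euler integration of the motion model: ground velocity =
#' swim velocity + current advection at the instantaneous position. The
#' exact swim vectors used are returned step by step, and aggregated to
#' true daily positions and daily-mean swim/current vectors — the gold
#' standard that the current-correction module must recover.
#'
#' @param spec a [swimmer_spec()].
#' @param field a `gridded_field` covering the track.
#' @param seed integer seed.
#' @return list with `fine` (data.frame: time, lon, lat, swim_east,
#'   swim_north, cur_east, cur_north — velocities in km day^-1), `daily`
#'   (data.frame: day index, time, lon, lat, true daily-mean swim and
#'   current east/north), and `spec`.
#' @export
simulate_swimmer <- function(spec, field, seed = 1) {
  stopifnot(inherits(spec, "swimmer_spec"))
  set.seed(seed)
  lon_rng <- range(field$lon); lat_rng <- range(field$lat)
  if (spec$release_lon < lon_rng[1] || spec$release_lon > lon_rng[2] ||
      spec$release_lat < lat_rng[1] || spec$release_lat > lat_rng[2])
    stop("release point outside field extent")
  n_steps <- round(spec$duration_days / spec$dt_days)
  lon <- numeric(n_steps + 1); lat <- numeric(n_steps + 1)
  se <- numeric(n_steps); sn <- numeric(n_steps)
  ce <- numeric(n_steps); cn <- numeric(n_steps)
  lon[1] <- spec$release_lon; lat[1] <- spec$release_lat
  has_goal <- is.finite(spec$goal_lon) && is.finite(spec$goal_lat)
  prev_head <- stats::runif(1, 0, 2 * pi)
  shape <- if (spec$speed_cv > 0) 1 / spec$speed_cv^2 else Inf
  truncated <- FALSE
  for (i in seq_len(n_steps)) {
    t_day <- (i - 1) * spec$dt_days
    date <- as.Date(spec$start_time + t_day * 86400, tz = "UTC")
    center <- if (has_goal &&
                  (spec$goal_lon != lon[i] || spec$goal_lat != lat[i])) {
      .deg2rad(bearing_deg(lon[i], lat[i], spec$goal_lon, spec$goal_lat))
    } else prev_head
    head <- if (is.infinite(spec$kappa)) center else
      rvonmises(1, center, spec$kappa)
    prev_head <- head
    speed <- if (spec$mean_speed_kmday == 0) 0 else if (is.infinite(shape))
      spec$mean_speed_kmday else
      stats::rgamma(1, shape = shape, rate = shape / spec$mean_speed_kmday)
    se[i] <- speed * sin(head); sn[i] <- speed * cos(head)
    cur <- .field_current(field, lon[i], lat[i], date)
    ce[i] <- cur$u * KM_DAY_PER_MS; cn[i] <- cur$v * KM_DAY_PER_MS
    p <- displace(lon[i], lat[i], se[i] + ce[i], sn[i] + cn[i], spec$dt_days)
    if (p$lon < lon_rng[1] || p$lon > lon_rng[2] ||
        p$lat < lat_rng[1] || p$lat > lat_rng[2]) {
      warning("track exits field extent; truncated at step ", i)
      truncated <- TRUE
      n_steps <- i - 1L
      break
    }
    lon[i + 1] <- p$lon; lat[i + 1] <- p$lat
  }
  idx <- seq_len(n_steps + 1)
  fine <- data.frame(
    time = spec$start_time + (idx - 1) * spec$dt_days * 86400,
    lon = lon[idx], lat = lat[idx],
    swim_east = c(se[seq_len(n_steps)], NA),
    swim_north = c(sn[seq_len(n_steps)], NA),
    cur_east = c(ce[seq_len(n_steps)], NA),
    cur_north = c(cn[seq_len(n_steps)], NA))
  # daily aggregates: positions at whole-day marks, mean vectors per day
  steps_per_day <- round(1 / spec$dt_days)
  n_days <- floor(n_steps / steps_per_day)
  di <- 1 + (0:n_days) * steps_per_day
  daily <- data.frame(
    day = 0:n_days,
    time = fine$time[di], lon = fine$lon[di], lat = fine$lat[di])
  agg <- function(x) vapply(seq_len(n_days), function(d) {
    mean(x[((d - 1) * steps_per_day + 1):(d * steps_per_day)])
  }, numeric(1))
  daily$swim_east <- c(NA, agg(se)); daily$swim_north <- c(NA, agg(sn))
  daily$cur_east <- c(NA, agg(ce)); daily$cur_north <- c(NA, agg(cn))
  list(fine = fine, daily = daily, spec = spec, truncated = truncated)
}

#' Simulate a passive surface drifter
#'
#' A swimmer with zero swim speed, reporting 10-minute positions.
#'
#' @param release_lon,release_lat release point, degrees.
#' @param field a `gridded_field`.
#' @param duration_days duration, days.
#' @param seed integer seed.
#' @param start_time POSIXct (UTC) release instant.
#' @return as [simulate_swimmer()].
#' @export
simulate_drifter <- function(release_lon, release_lat, field,
                             duration_days = 10, seed = 1,
                             start_time = as.POSIXct("2022-01-22 12:00:00",
                                                     tz = "UTC")) {
  spec <- swimmer_spec(release_lon, release_lat,
                       mean_speed_kmday = 0, speed_cv = 0, kappa = 0,
                       duration_days = duration_days,
                       dt_days = 10 / (24 * 60), start_time = start_time)
  simulate_swimmer(spec, field, seed = seed)
}

#' Specify ARGOS-like observation noise
#'
#' Fix counts per day follow a negative binomial (over-dispersed, matching
#' observed per-animal means of roughly 1-17 fixes/day); each fix gets a
#' quality class, an error ellipse whose semi-major axis scales with the
#' class, and a position perturbed by a zero-mean bivariate normal with
#' that ellipse as its covariance.
#'
#' @param fixes_per_day_mean mean daily fix count.
#' @param fixes_per_day_size negative-binomial size (dispersion).
#' @param class_names quality-class tokens (best to worst).
#' @param class_probs sampling frequencies of the classes.
#' @param class_scale_km semi-major-axis scale (km, 1 SD) per class.
#' @return an `argos_noise_spec` list.
#' @export
argos_noise_spec <- function(fixes_per_day_mean = 12,
                             fixes_per_day_size = 5,
                             class_names = c("3", "2", "1", "0", "A", "B"),
                             class_probs = c(.12, .18, .22, .18, .15, .15),
                             class_scale_km = c(0.25, 0.5, 1, 2, 4, 8)) {
  stopifnot(length(class_names) == length(class_probs),
            length(class_names) == length(class_scale_km),
            all(class_scale_km > 0))
  structure(list(fixes_per_day_mean = fixes_per_day_mean,
                 fixes_per_day_size = fixes_per_day_size,
                 class_names = class_names,
                 class_probs = class_probs / sum(class_probs),
                 class_scale_km = class_scale_km),
            class = "argos_noise_spec")
}

## km east/north noise -> degrees at latitude lat
.km_to_deg <- function(east_km, north_km, lat) {
  kmdeg <- EARTH_RADIUS_KM * pi / 180
  list(dlon = east_km / (kmdeg * cos(.deg2rad(lat))), dlat = north_km / kmdeg)
}

#' Observe a true track through ARGOS-like noise
#'
#' Thin the fine-step true track to irregular fix times (negative-binomial
#' daily counts, uniform times within each day), attach a quality class and
#' an error ellipse per fix, and perturb the position by a draw from the
#' ellipse's bivariate normal. With `keep_inside` set, noise draws are
#' rejection-sampled until the observed fix stays within the given
#' buffer (used for residential animals so that observed — not only true —
#' positions remain nearshore).
#'
#' @param sim output of [simulate_swimmer()] (or a data.frame with
#'   time/lon/lat columns as `fine`).
#' @param spec an [argos_noise_spec()].
#' @param id animal identifier stored with each fix.
#' @param seed integer seed.
#' @param keep_inside optional list(polygon =, radius_km =): retain only
#'   noise draws within `radius_km` of the polygon.
#' @return data.frame of fixes: `id`, `time`, `lon`, `lat`, `smaj_km`,
#'   `smin_km`, `eor_deg` (ellipse orientation, degrees clockwise from
#'   north), `class`.
#' @export
observe_argos <- function(sim, spec = argos_noise_spec(), id = "animal1",
                          seed = 1, keep_inside = NULL) {
  fine <- if (is.data.frame(sim)) sim else sim$fine
  if (nrow(fine) < 2) stop("true track is empty")
  set.seed(seed)
  t0 <- fine$time[1]
  total_days <- as.numeric(difftime(fine$time[nrow(fine)], t0, units = "days"))
  n_days <- max(1L, floor(total_days))
  rows <- list()
  for (d in seq_len(n_days)) {
    nfix <- stats::rnbinom(1, size = spec$fixes_per_day_size,
                           mu = spec$fixes_per_day_mean)
    if (d == 1) nfix <- max(nfix, 1L)  # release day always observed
    if (nfix == 0) next
    tt <- sort(stats::runif(nfix, d - 1, d))
    cls_i <- sample(seq_along(spec$class_names), nfix, TRUE,
                    prob = spec$class_probs)
    # true position by linear interpolation of the fine track
    tlon <- stats::approx(as.numeric(fine$time), fine$lon,
                          xout = as.numeric(t0) + tt * 86400)$y
    tlat <- stats::approx(as.numeric(fine$time), fine$lat,
                          xout = as.numeric(t0) + tt * 86400)$y
    for (k in seq_len(nfix)) {
      scale <- spec$class_scale_km[cls_i[k]]
      smaj <- scale * stats::rlnorm(1, 0, 0.3)
      smin <- smaj * stats::runif(1, 0.3, 0.9)
      eor <- stats::runif(1, 0, 180)
      psi <- .deg2rad(eor)
      for (try in 1:200) {
        z <- stats::rnorm(2)
        east <- smaj * z[1] * sin(psi) + smin * z[2] * cos(psi)
        north <- smaj * z[1] * cos(psi) - smin * z[2] * sin(psi)
        dd <- .km_to_deg(east, north, tlat[k])
        olon <- wrap_lon(tlon[k] + dd$dlon); olat <- tlat[k] + dd$dlat
        if (is.null(keep_inside)) break
        if (point_buffer_km(olon, olat, keep_inside$polygon) <=
            keep_inside$radius_km) break
        if (try == 200) { olon <- tlon[k]; olat <- tlat[k] }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, time = t0 + tt[k] * 86400, lon = olon, lat = olat,
        smaj_km = smaj, smin_km = smin, eor_deg = eor,
        class = spec$class_names[cls_i[k]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic island polygon
#'
#' A deterministic elongated-ellipse coastline (about 60 x 16 km) standing
#' in for a release island. Labelled synthetic: no real coastline data.
#'
#' @param center_lon,center_lat island center, degrees.
#' @param a_km,b_km semi-axes, km (east-west, north-south).
#' @param n_vertices number of polygon vertices.
#' @return data.frame with columns `lon`, `lat` (closed ring not repeated).
#' @export
make_island <- function(center_lon = -81.25, center_lat = 19.3,
                        a_km = 30, b_km = 8, n_vertices = 48) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  kmdeg <- EARTH_RADIUS_KM * pi / 180
  data.frame(
    lon = center_lon + a_km * cos(th) / (kmdeg * cos(.deg2rad(center_lat))),
    lat = center_lat + b_km * sin(th) / kmdeg)
}

#' Distance from points to an island polygon, km
#'
#' 0 for points inside the polygon, otherwise the minimum distance to its
#' boundary segments, computed in a local equirectangular plane centered on
#' the polygon (distortion is negligible at buffer scale, tens of km).
#'
#' @param lon,lat point coordinates, degrees (vectorized).
#' @param polygon data.frame with `lon`, `lat` vertices.
#' @return distances in km.
#' @export
point_buffer_km <- function(lon, lat, polygon) {
  if (is.null(polygon) || nrow(polygon) < 3)
    stop("config error: island polygon must have >= 3 vertices")
  ring <- as.matrix(polygon[, c("lon", "lat")])
  kmdeg <- EARTH_RADIUS_KM * pi / 180
  lat0 <- mean(ring[, 2]); lon0 <- mean(ring[, 1])
  cs <- cos(.deg2rad(lat0))
  px <- .wrap_signed(lon - lon0) * cs * kmdeg
  py <- (lat - lat0) * kmdeg
  rx <- .wrap_signed(ring[, 1] - lon0) * cs * kmdeg
  ry <- (ring[, 2] - lat0) * kmdeg
  n <- length(rx)
  j <- c(2:n, 1)
  ax <- rx; ay <- ry; bx <- rx[j]; by <- ry[j]
  ex <- bx - ax; ey <- by - ay
  elen2 <- pmax(ex^2 + ey^2, 1e-12)
  km <- vapply(seq_along(px), function(p) {
    t <- pmin(pmax(((px[p] - ax) * ex + (py[p] - ay) * ey) / elen2, 0), 1)
    dx <- px[p] - (ax + t * ex); dy <- py[p] - (ay + t * ey)
    sqrt(min(dx^2 + dy^2))
  }, numeric(1))
  inside <- .point_in_polygon(lon, lat, ring)
  km[inside] <- 0
  km
}

## even-odd ray casting; planar in lon/lat is adequate at island scale
.point_in_polygon <- function(lon, lat, ring) {
  n <- nrow(ring)
  inside <- logical(length(lon))
  for (p in seq_along(lon)) {
    cnt <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if (((ring[i, 2] > lat[p]) != (ring[j, 2] > lat[p])) &&
          (lon[p] < (ring[j, 1] - ring[i, 1]) * (lat[p] - ring[i, 2]) /
             (ring[j, 2] - ring[i, 2]) + ring[i, 1]))
        cnt <- !cnt
      j <- i
    }
    inside[p] <- cnt
  }
  inside
}

#' Generate a full scenario cohort
#'
#' Builds the current/SST/sargassum fields, the island polygon, per-animal
#' covariates, true tracks and ARGOS-like fixes for one of two release
#' scenarios:
#' \describe{
#'   \item{jan}{heterogeneous radial dispersal: a strong uniform background
#'     current, per-animal goals spread around the compass, plus a
#'     residential fraction that loiters inside the 10-km island buffer
#'     for the whole track (default 16 of 30 animals); three age classes.}
#'   \item{jul}{common northward dispersal into a clockwise vortex over a
#'     weak background; all animals in the youngest age class.}
#' }
#' Residential animals' observed fixes are kept inside the buffer by
#' construction, so the 10-km dispersal classifier agrees exactly with the
#' generated labels.
#'
#' @param scenario "jan" or "jul".
#' @param n_turtles cohort size (default 30 for jan, 10 for jul).
#' @param seed integer seed; all randomness derives from it.
#' @param n_residential number of residential animals (jan default 16,
#'   jul default 0).
#' @param duration_days dispersive track duration, days.
#' @param res_deg field resolution, degrees.
#' @param noise an [argos_noise_spec()].
#' @return list with `field`, `island`, `covariates` (data.frame: id,
#'   period, age_class, weight_kg, residential, release lon/lat, goal
#'   bearing), `tracks` (named list of [simulate_swimmer()] outputs) and
#'   `fixes` (one data.frame of all animals' fixes).
#' @export
make_cohort <- function(scenario = c("jan", "jul"), n_turtles = NULL,
                        seed = 1, n_residential = NULL,
                        duration_days = 15, res_deg = 0.25,
                        noise = argos_noise_spec()) {
  scenario <- match.arg(scenario)
  if (is.null(n_turtles)) n_turtles <- if (scenario == "jan") 30L else 10L
  if (n_turtles < 1) stop("config error: n_turtles must be >= 1")
  if (is.null(n_residential))
    n_residential <- if (scenario == "jan") min(16L, n_turtles) else 0L
  if (n_residential > n_turtles)
    stop("config error: n_residential exceeds n_turtles")
  set.seed(seed)

  island <- make_island()
  start_date <- if (scenario == "jan") as.Date("2022-01-22") else
    as.Date("2022-07-20")
  extent <- list(lon = c(-88.5, -73.5), lat = c(13.5, 26.5))
  fspec <- if (scenario == "jan") {
    current_field_spec("composite", u0 = -0.35, v0 = -0.2,
                       vortex_lon = -80.2, vortex_lat = 21.3,
                       vortex_peak_ms = 0.35, vortex_radius_km = 300,
                       lon_range = extent$lon, lat_range = extent$lat,
                       start = start_date, days = duration_days + 7,
                       res_deg = res_deg, sst_base = 27)
  } else {
    current_field_spec("composite", u0 = 0.08, v0 = 0.12,
                       vortex_lon = -80.5, vortex_lat = 21.2,
                       vortex_peak_ms = 0.45, vortex_radius_km = 250,
                       lon_range = extent$lon, lat_range = extent$lat,
                       start = start_date, days = duration_days + 7,
                       res_deg = res_deg, sst_base = 29)
  }
  field <- build_field(fspec, seed = seed + 1L)

  release <- if (scenario == "jan") c(-81.27, 19.62) else c(-81.32, 19.02)
  age_pool <- if (scenario == "jan") c("1-2", "2-3", "3-4") else "1-2"
  weight_mean <- c("1-2" = 6, "2-3" = 15, "3-4" = 22)

  ids <- sprintf("%s%02d", ifelse(scenario == "jan", "T1", "T2"),
                 seq_len(n_turtles))
  resid <- rep(FALSE, n_turtles)
  if (n_residential > 0) resid[sample(n_turtles, n_residential)] <- TRUE
  age <- rep(age_pool, length.out = n_turtles)[sample(n_turtles)]
  weight <- round(weight_mean[age] * exp(stats::rnorm(n_turtles, 0, 0.12)), 1)

  # dispersive goals: jan radial (uniform bearings), jul common northward
  goal_bearing <- if (scenario == "jan")
    stats::runif(n_turtles, 0, 360) else
    wrap_deg(stats::rnorm(n_turtles, 15, 15))
  goal_dist_km <- stats::runif(n_turtles, 500, 900)

  start_time <- as.POSIXct(paste(start_date, "12:00:00"), tz = "UTC")
  tracks <- vector("list", n_turtles); names(tracks) <- ids
  fixes <- vector("list", n_turtles)
  for (i in seq_len(n_turtles)) {
    si <- seed + 100L + i
    if (resid[i]) {
      # loiterer: weak attraction to a nearshore home point, slow speeds
      home <- displace(-81.25, 19.3, 0, 0, 1)  # island center
      spec_i <- swimmer_spec(home$lon + stats::runif(1, -0.05, 0.05),
                             home$lat + stats::runif(1, -0.02, 0.02),
                             goal_lon = home$lon, goal_lat = home$lat,
                             mean_speed_kmday = 5, speed_cv = 0.4,
                             kappa = 1, duration_days = duration_days,
                             start_time = start_time)
      # residents move through near-zero current (sheltered nearshore):
      # simulate on a zero field so the loiter stays inside the buffer
      zero_spec <- current_field_spec("uniform", u0 = 0, v0 = 0,
                                      lon_range = fspec$lon_range,
                                      lat_range = fspec$lat_range,
                                      res_deg = 0.5, start = start_date,
                                      days = fspec$days)
      zero_field <- build_field(zero_spec, seed = si)
      tracks[[i]] <- simulate_swimmer(spec_i, zero_field, seed = si)
      res_noise <- noise
      res_noise$fixes_per_day_mean <- min(4, noise$fixes_per_day_mean)
      fixes[[i]] <- observe_argos(tracks[[i]], res_noise, id = ids[i],
                                  seed = si,
                                  keep_inside = list(polygon = island,
                                                     radius_km = 10))
    } else {
      goal <- displace(release[1], release[2],
                       sin(.deg2rad(goal_bearing[i])) * goal_dist_km[i],
                       cos(.deg2rad(goal_bearing[i])) * goal_dist_km[i], 1)
      spec_i <- swimmer_spec(release[1] + stats::runif(1, -0.02, 0.02),
                             release[2] + stats::runif(1, -0.02, 0.02),
                             goal_lon = goal$lon, goal_lat = goal$lat,
                             mean_speed_kmday = stats::runif(1, 25, 50),
                             speed_cv = 0.3, kappa = 8,
                             duration_days = duration_days,
                             start_time = start_time)
      tracks[[i]] <- suppressWarnings(
        simulate_swimmer(spec_i, field, seed = si))
      fixes[[i]] <- observe_argos(tracks[[i]], noise, id = ids[i], seed = si)
    }
  }
  covariates <- data.frame(
    id = ids, period = ifelse(scenario == "jan", "Jan", "Jul"),
    age_class = age, weight_kg = as.numeric(weight),
    residential = resid,
    release_lon = release[1], release_lat = release[2],
    goal_bearing = ifelse(resid, NA, goal_bearing))
  list(scenario = scenario, field = field, island = island,
       covariates = covariates, tracks = tracks,
       fixes = do.call(rbind, fixes))
}

#' Covariate testbed for persistence-model recovery studies
#'
#' Builds a realistic persistence-series covariate frame by running the
#' generator chain (cohort, true daily tracks, current decomposition,
#' environmental annotation) for two spatially exchangeable radial
#' cohorts labelled as the two tracking periods. Exchangeability matters:
#' with the real scenarios the periods occupy disjoint regions and the
#' spatial smoother absorbs the period contrast, leaving the period
#' effect only weakly identified. The response column is left to
#' [simulate_persistence_response()].
#'
#' @param seed integer seed.
#' @param n_per_period animals per period.
#' @param duration_days track duration.
#' @param sarg_radius_km sargassum extraction radius; the default 20 km
#'   matches the synthetic sargassum grid spacing so the covariate is
#'   observed on every row.
#' @return a persistence-series data.frame with covariates but a
#'   placeholder response.
#' @export
gamm_recovery_testbed <- function(seed = 1, n_per_period = 10,
                                  duration_days = 15,
                                  sarg_radius_km = 20) {
  frames <- list()
  for (sc in c("A", "B")) {
    co <- make_cohort("jan", n_turtles = n_per_period, n_residential = 0,
                      seed = seed + (sc == "B") * 1000L,
                      duration_days = duration_days, res_deg = 0.25)
    per <- if (sc == "A") "Jan" else "Jul"
    for (a in names(co$tracks)) {
      d <- co$tracks[[a]]$daily
      if (nrow(d) < 4) next
      tr <- data.frame(id = paste0(sc, a), day = d$day, time = d$time,
                       lon = d$lon, lat = d$lat)
      class(tr) <- c("regular_track", "data.frame")
      dc <- decompose_track(tr, co$field)
      an <- annotate_track(tr, co$field, sarg_radius_km = sarg_radius_km)
      ps <- persistence_series(dc, an)
      ps$period <- per
      ps$weight_kg <- co$covariates$weight_kg[co$covariates$id == a]
      frames[[paste0(sc, a)]] <- ps
    }
  }
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  out
}

#' Simulate a persistence response with known truth
#'
#' Overwrites the `persistence` column with draws from the stated truth:
#' a tracking-period effect, per-animal normal intercepts and AR(1)
#' residuals with a given marginal SD. Defaults follow the package's
#' recovery study: period effect 6.2 km/day, between-animal SD 3 km/day,
#' AR(1) coefficient 0.5, marginal residual SD 8 km/day.
#'
#' @param testbed output of [gamm_recovery_testbed()].
#' @param seed integer seed.
#' @param effect period effect (added to the "Jan" rows), km/day.
#' @param sd_b between-animal intercept SD, km/day.
#' @param phi AR(1) coefficient of the daily residuals.
#' @param sd_marg marginal residual SD, km/day.
#' @return the testbed with a simulated `persistence` column.
#' @export
simulate_persistence_response <- function(testbed, seed = 1, effect = 6.2,
                                          sd_b = 3, phi = 0.5,
                                          sd_marg = 8) {
  set.seed(seed)
  y <- numeric(nrow(testbed))
  for (a in unique(testbed$id)) {
    i <- which(testbed$id == a)
    b <- stats::rnorm(1, 0, sd_b)
    e <- as.numeric(stats::arima.sim(list(ar = phi), length(i),
                                     sd = sd_marg * sqrt(1 - phi^2)))
    y[i] <- effect * (testbed$period[i][1] == "Jan") + b + e
  }
  testbed$persistence <- y
  testbed
}
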