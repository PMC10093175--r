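# Geographic arithmetic shared by every other module.
# One fixed Earth model: a sphere of radius 6371.0 km. All interfaces take
# and return degrees; radians are internal only.

#' Earth radius (km) used throughout the package
#'
#' Spherical Earth model, radius 6371.0 km. At the scale of daily turtle
#' steps (tens of km) the difference from an ellipsoid is well below 0.5%.
#' @export
EARTH_RADIUS_KM <- 6371.0

#' Unit conversion: metres per second to kilometres per day
#'
#' 1 m s^-1 = 86.4 km day^-1 exactly. Ocean-current products report m s^-1;
#' all track velocities in this package are km day^-1.
#' @export
KM_DAY_PER_MS <- 86.4

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

## km spanned by one degree of latitude (or of longitude at the equator)
.km_per_deg <- function() EARTH_RADIUS_KM * pi / 180

#' Normalize longitudes to [-180, 180)
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return longitudes wrapped into [-180, 180).
#' @export
wrap_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Wrap angles in degrees to [0, 360)
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped into [0, 360).
#' @export
wrap_deg <- function(deg) deg %% 360

## wrap a signed angle difference to (-180, 180]
.wrap_signed <- function(deg) {
  w <- ((deg + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

.check_point <- function(lon, lat, what = "point") {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates in ", what)
  if (any(abs(lat) >= 90))
    stop("latitude out of range (-90, 90) in ", what)
  invisible(TRUE)
}

#' Construct geographic points
#'
#' Light-weight constructor for one or more lon/lat points with an optional
#' UTC timestamp. Longitudes are normalized to [-180, 180).
#'
#' @param lon,lat degrees east / degrees north (vectors recycle).
#' @param time optional POSIXct (UTC) vector.
#' @return a data.frame with columns `lon`, `lat` and optionally `time`,
#'   of class `geo_point`.
#' @export
geo_point <- function(lon, lat, time = NULL) {
  .check_point(lon, lat)
  lon <- wrap_lon(lon)
  p <- data.frame(lon = lon, lat = lat)
  if (!is.null(time)) {
    if (!inherits(time, "POSIXct")) stop("time must be POSIXct (UTC)")
    attr(time, "tzone") <- "UTC"
    p$time <- time
  }
  class(p) <- c("geo_point", "data.frame")
  p
}

#' Great-circle distance in km
#'
#' Haversine distance on the package's spherical Earth model.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @return distance(s) in km; symmetric, non-negative, zero iff the points
#'   coincide.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  .check_point(lon1, lat1, "a")
  .check_point(lon2, lat2, "b")
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- phi2 - phi1
  dlam <- .deg2rad(lon2 - lon1)
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  h <- pmin(pmax(h, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(h))
}

#' Initial great-circle bearing, degrees clockwise from true north
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @return bearing(s) in [0, 360). Coincident points have no heading and
#'   raise an error (never coerced to 0).
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  .check_point(lon1, lat1, "a")
  .check_point(lon2, lat2, "b")
  same <- lon1 == lon2 & lat1 == lat2
  if (any(same)) stop("bearing undefined for coincident points")
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  wrap_deg(.rad2deg(atan2(y, x)))
}

#' Convert a true-north heading to a magnetic heading (and back)
#'
#' Magnetic declination is a single configurable constant per dataset;
#' the default 0 makes magnetic and true frames coincide.
#'
#' @param heading_deg heading(s), degrees clockwise from true north.
#' @param declination_deg magnetic declination (degrees; positive east).
#' @return heading(s) from magnetic north, in [0, 360).
#' @export
to_magnetic <- function(heading_deg, declination_deg = 0) {
  wrap_deg(heading_deg - declination_deg)
}

#' @rdname to_magnetic
#' @export
to_true <- function(heading_deg, declination_deg = 0) {
  wrap_deg(heading_deg + declination_deg)
}

#' Mean velocity vector between two timed positions
#'
#' East/north components in km day^-1, computed in a local equirectangular
#' plane at the segment midpoint latitude. For daily steps under 200 km the
#' magnitude agrees with [great_circle_km()] per day to within 0.5%.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @param dt_days elapsed time in days; must be > 0.
#' @return a data.frame with columns `east` and `north` (km day^-1).
#' @export
velocity_between <- function(lon1, lat1, lon2, lat2, dt_days) {
  .check_point(lon1, lat1, "a")
  .check_point(lon2, lat2, "b")
  if (any(!is.finite(dt_days)) || any(dt_days <= 0))
    stop("dt_days must be positive and finite")
  kmdeg <- .km_per_deg()
  midlat <- (lat1 + lat2) / 2
  dlon <- .wrap_signed(lon2 - lon1)
  east <- dlon * cos(.deg2rad(midlat)) * kmdeg / dt_days
  north <- (lat2 - lat1) * kmdeg / dt_days
  data.frame(east = east, north = north)
}

#' Displace a point by a velocity over a time interval
#'
#' Exact inverse of [velocity_between()] for the same local equirectangular
#' convention (midpoint latitude), so
#' `velocity_between(a, displace(a, v, dt))` recovers `v` to machine
#' precision for displacements well inside 200 km.
#'
#' @param lon,lat starting coordinates in degrees (vectorized).
#' @param east,north velocity components, km day^-1.
#' @param dt_days time interval, days.
#' @return data.frame with columns `lon`, `lat` of the displaced point.
#' @export
displace <- function(lon, lat, east, north, dt_days) {
  .check_point(lon, lat)
  if (any(!is.finite(east)) || any(!is.finite(north)) ||
      any(!is.finite(dt_days)))
    stop("non-finite displacement inputs")
  kmdeg <- .km_per_deg()
  dlat <- north * dt_days / kmdeg
  lat2 <- lat + dlat
  if (any(abs(lat2) >= 90)) stop("displacement crosses a pole")
  midlat <- (lat + lat2) / 2
  dlon <- east * dt_days / (kmdeg * cos(.deg2rad(midlat)))
  data.frame(lon = wrap_lon(lon + dlon), lat = lat2)
}

#' Speed of a velocity vector
#'
#' @param east,north components in km day^-1.
#' @return magnitude in km day^-1.
#' @export
speed_kmday <- function(east, north) sqrt(east^2 + north^2)

#' Direction of a velocity vector, degrees clockwise from north
#'
#' @param east,north components in km day^-1. Zero vectors have no
#'   direction and return NA.
#' @return direction(s) in [0, 360), NA for zero vectors.
#' @export
velocity_direction_deg <- function(east, north) {
  out <- wrap_deg(.rad2deg(atan2(east, north)))
  out[east == 0 & north == 0] <- NA_real_
  out
}
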