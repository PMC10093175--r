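# Decompose daily ground motion into ocean-current advection and active
# swimming (swim = ground - current), rebuild current-corrected
# trajectories by integrating the swim vectors, and annotate daily
# positions with environmental covariates.

#' Sample a gridded field variable at a point and date
#'
#' Bilinear interpolation in lon/lat on the variable's time slice:
#' nearest day for daily variables, the containing week for weekly ones.
#' Missing-masked neighbors are excluded with renormalized weights; if all
#' four neighbors are missing the result is NA (never zero).
#'
#' @param field a `gridded_field`.
#' @param var variable name.
#' @param lon,lat query position(s), degrees.
#' @param date query date (Date or coercible).
#' @return interpolated value(s); NA with attribute lost when outside the
#'   grid or fully masked.
#' @export
sample_field <- function(field, var, lon, lat, date) {
  stopifnot(inherits(field, "gridded_field"))
  v <- field$vars[[var]]
  if (is.null(v)) stop("unknown variable '", var, "'")
  vt <- attr(v, "time"); if (is.null(vt)) vt <- field$time
  date <- as.Date(date)
  step <- if (length(vt) > 1) min(diff(as.numeric(vt))) else 1
  out <- numeric(length(lon))
  for (p in seq_along(lon)) {
    dte <- if (length(date) > 1) date[p] else date
    if (step >= 7) {
      k <- findInterval(as.numeric(dte), as.numeric(vt))
      if (k < 1 || as.numeric(dte) >= as.numeric(vt[k]) + step) k <- NA
    } else {
      k <- which.min(abs(as.numeric(vt) - as.numeric(dte)))
      if (abs(as.numeric(vt[k]) - as.numeric(dte)) > step) k <- NA
    }
    if (is.na(k)) { out[p] <- NA_real_; next }
    i <- findInterval(lon[p], field$lon)
    j <- findInterval(lat[p], field$lat)
    if (i < 1 || i >= length(field$lon) || j < 1 || j >= length(field$lat)) {
      # allow exact queries on the last node
      if (lon[p] == field$lon[length(field$lon)])
        i <- length(field$lon) - 1L
      if (lat[p] == field$lat[length(field$lat)])
        j <- length(field$lat) - 1L
      if (i < 1 || i >= length(field$lon) ||
          j < 1 || j >= length(field$lat)) { out[p] <- NA_real_; next }
    }
    tx <- (lon[p] - field$lon[i]) / (field$lon[i + 1] - field$lon[i])
    ty <- (lat[p] - field$lat[j]) / (field$lat[j + 1] - field$lat[j])
    vals <- c(v[i, j, k], v[i + 1, j, k], v[i, j + 1, k], v[i + 1, j + 1, k])
    w <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
    ok <- !is.na(vals)
    out[p] <- if (!any(ok)) NA_real_ else
      sum(vals[ok] * w[ok]) / sum(w[ok])
  }
  out
}

#' Decompose a daily track into current and swimming components
#'
#' For each consecutive pair of daily positions: ground velocity from the
#' positions, current sampled at the segment's start position and date
#' (converted m s^-1 -> km day^-1 by the exact factor 86.4), and
#' swim = ground - current. Days with a missing current sample get a
#' missing swim vector (never zero-filled). Current-corrected positions
#' are rebuilt by iteratively displacing the first regularized position by
#' the swim vectors (missing days advance by ground velocity so the
#' corrected trajectory stays aligned).
#'
#' @param track a `regular_track` (>= 2 daily positions).
#' @param field a `gridded_field` with `u` and `v`.
#' @return data.frame of class `swim_decomposition`: per day `id`, `day`,
#'   `date`, `lon`, `lat`, ground/current/swim east+north (km day^-1),
#'   `swim_speed`, `corr_lon`, `corr_lat`, `missing_current`.
#' @export
decompose_track <- function(track, field) {
  if (nrow(track) < 2) stop("track must have >= 2 daily positions")
  n <- nrow(track)
  date <- as.Date(track$time, tz = "UTC")
  gr <- velocity_between(track$lon[-n], track$lat[-n],
                         track$lon[-1], track$lat[-1], 1)
  u <- sample_field(field, "u", track$lon[-n], track$lat[-n], date[-n])
  v <- sample_field(field, "v", track$lon[-n], track$lat[-n], date[-n])
  cur_e <- u * KM_DAY_PER_MS; cur_n <- v * KM_DAY_PER_MS
  swim_e <- gr$east - cur_e; swim_n <- gr$north - cur_n
  miss <- is.na(cur_e) | is.na(cur_n)
  # rebuild corrected trajectory from the first position
  corr_lon <- numeric(n); corr_lat <- numeric(n)
  corr_lon[1] <- track$lon[1]; corr_lat[1] <- track$lat[1]
  for (i in 2:n) {
    ve <- if (miss[i - 1]) gr$east[i - 1] else swim_e[i - 1]
    vn <- if (miss[i - 1]) gr$north[i - 1] else swim_n[i - 1]
    p <- displace(corr_lon[i - 1], corr_lat[i - 1], ve, vn, 1)
    corr_lon[i] <- p$lon; corr_lat[i] <- p$lat
  }
  out <- data.frame(
    id = track$id, day = track$day, date = date,
    lon = track$lon, lat = track$lat,
    ground_east = c(gr$east, NA), ground_north = c(gr$north, NA),
    cur_east = c(cur_e, NA), cur_north = c(cur_n, NA),
    swim_east = c(swim_e, NA), swim_north = c(swim_n, NA),
    swim_speed = c(speed_kmday(swim_e, swim_n), NA),
    corr_lon = corr_lon, corr_lat = corr_lat,
    missing_current = c(miss, NA))
  class(out) <- c("swim_decomposition", "data.frame")
  out
}

#' Annotate daily positions with environmental covariates
#'
#' SST by bilinear sampling; sargassum as the mean of all grid cells whose
#' centers lie within `sarg_radius_km` of the position (empty set ->
#' missing); current speed as the magnitude of the sampled current in
#' km day^-1.
#'
#' @param track a `regular_track`.
#' @param field `gridded_field` with `u`, `v` and optionally `sst`.
#' @param sarg_field optional `gridded_field` with `sargassum` (may be the
#'   same object as `field`).
#' @param sarg_radius_km sargassum extraction radius, km (default 1).
#' @return data.frame: `id`, `day`, `date`, `sst`, `cur_speed_kmday`,
#'   `sargassum`, logical validity flags.
#' @export
annotate_track <- function(track, field, sarg_field = field,
                           sarg_radius_km = 1) {
  date <- as.Date(track$time, tz = "UTC")
  sst <- if ("sst" %in% names(field$vars))
    sample_field(field, "sst", track$lon, track$lat, date) else
    rep(NA_real_, nrow(track))
  u <- sample_field(field, "u", track$lon, track$lat, date)
  v <- sample_field(field, "v", track$lon, track$lat, date)
  sarg <- rep(NA_real_, nrow(track))
  if (!is.null(sarg_field) && "sargassum" %in% names(sarg_field$vars)) {
    sv <- sarg_field$vars$sargassum
    vt <- attr(sv, "time"); if (is.null(vt)) vt <- sarg_field$time
    step <- if (length(vt) > 1) min(diff(as.numeric(vt))) else 7
    kmdeg <- EARTH_RADIUS_KM * pi / 180
    for (p in seq_len(nrow(track))) {
      k <- findInterval(as.numeric(date[p]), as.numeric(vt))
      if (k < 1 || as.numeric(date[p]) >= as.numeric(vt[k]) + step) next
      dx <- .wrap_signed(sarg_field$lon - track$lon[p]) *
        cos(.deg2rad(track$lat[p])) * kmdeg
      dy <- (sarg_field$lat - track$lat[p]) * kmdeg
      ii <- which(abs(dx) <= sarg_radius_km)
      jj <- which(abs(dy) <= sarg_radius_km)
      if (!length(ii) || !length(jj)) next
      cells <- expand.grid(i = ii, j = jj)
      r <- sqrt(dx[cells$i]^2 + dy[cells$j]^2)
      sel <- cells[r <= sarg_radius_km, , drop = FALSE]
      if (!nrow(sel)) next
      vals <- sv[cbind(sel$i, sel$j, k)]
      if (any(!is.na(vals))) sarg[p] <- mean(vals, na.rm = TRUE)
    }
  }
  data.frame(id = track$id, day = track$day, date = date,
             sst = sst,
             cur_speed_kmday = speed_kmday(u, v) * KM_DAY_PER_MS,
             sargassum = sarg,
             sst_valid = !is.na(sst),
             current_valid = !is.na(u) & !is.na(v),
             sargassum_valid = !is.na(sarg))
}

#' Swim-versus-current alignment series
#'
#' Per-day signed angle between the swim and current vectors, degrees in
#' (-180, 180]; |angle| > 90 is classified "opposing" (the 90-degree
#' boundary included), otherwise "following". Days with a missing or
#' zero-magnitude vector are skipped.
#'
#' @param decomp a `swim_decomposition`.
#' @return data.frame: `id`, `day`, `date`, `angle_deg`, `alignment`.
#' @export
alignment_series <- function(decomp) {
  ok <- !is.na(decomp$swim_east) & !is.na(decomp$cur_east) &
    !(decomp$swim_east == 0 & decomp$swim_north == 0) &
    !(decomp$cur_east == 0 & decomp$cur_north == 0)
  d <- decomp[ok, , drop = FALSE]
  a_swim <- .rad2deg(atan2(d$swim_east, d$swim_north))
  a_cur <- .rad2deg(atan2(d$cur_east, d$cur_north))
  ang <- .wrap_signed(a_swim - a_cur)
  data.frame(id = d$id, day = d$day, date = d$date, angle_deg = ang,
             alignment = ifelse(abs(ang) >= 90, "opposing", "following"))
}
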