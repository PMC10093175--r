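# Per-day movement statistics on current-corrected trajectories: step
# lengths, turning angles, the persistence velocity V = L * cos(theta),
# initial headings, the dispersive/residential classifier and per-track
# summary tables.

#' Daily persistence-velocity series
#'
#' Step length L_t (km day^-1) is the straight-line displacement between
#' consecutive current-corrected daily positions; the turning angle
#' theta_t (radians, (-pi, pi]) is the signed angle between the swimming
#' velocity vectors of steps t-1 and t; the persistence velocity is
#' V_t = L_t * cos(theta_t) — the signed tendency to keep moving in the
#' previous direction. The first step has no turning angle and is
#' excluded; steps adjacent to a missing or zero-length swim vector get a
#' missing V.
#'
#' @param decomp a `swim_decomposition` for one animal (>= 3 corrected
#'   positions).
#' @param annotation optional [annotate_track()] result to join (by day).
#' @param covariates optional one-row-per-animal data.frame with `id` to
#'   join (weight, period, ...).
#' @return data.frame of class `persistence_series`: `id`, `day`, `date`,
#'   `lon`, `lat` (end of step, corrected), `step_km`, `turn_rad`,
#'   `persistence` plus any joined covariates.
#' @export
persistence_series <- function(decomp, annotation = NULL,
                               covariates = NULL) {
  n <- nrow(decomp)
  if (n < 3) stop("need >= 3 corrected positions for a turning angle")
  # steps s = 1..n-1 between corrected positions s and s+1
  L <- great_circle_km(decomp$corr_lon[-n], decomp$corr_lat[-n],
                       decomp$corr_lon[-1], decomp$corr_lat[-1])
  swim_dir <- atan2(decomp$swim_east, decomp$swim_north)[-n]  # per step
  zero_or_na <- is.na(decomp$swim_east[-n]) |
    (decomp$swim_east[-n] == 0 & decomp$swim_north[-n] == 0)
  ns <- n - 1
  turn <- rep(NA_real_, ns)
  for (s in 2:ns) {
    if (zero_or_na[s] || zero_or_na[s - 1]) next
    d <- (swim_dir[s] - swim_dir[s - 1]) %% (2 * pi)
    if (d > pi) d <- d - 2 * pi
    turn[s] <- d
  }
  out <- data.frame(
    id = decomp$id[-1], day = decomp$day[-1], date = decomp$date[-1],
    lon = decomp$corr_lon[-1], lat = decomp$corr_lat[-1],
    step_km = L, turn_rad = turn,
    persistence = L * cos(turn))[-1, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(annotation))
    out <- merge(out, annotation[, setdiff(names(annotation),
                                           c("date"))],
                 by = c("id", "day"), all.x = TRUE, sort = FALSE)
  if (!is.null(covariates))
    out <- merge(out, covariates, by = "id", all.x = TRUE, sort = FALSE)
  out <- out[order(out$day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("persistence_series", "data.frame")
  out
}

#' Classify animals as dispersive or residential
#'
#' The 10-km rule applied to raw (pre-filter) fixes: an animal is
#' dispersive iff any fix lies more than `radius_km` from the island
#' polygon; the exit day is the date of the first exceedance. Animals
#' with no viable fixes are labelled undetermined.
#'
#' @param fixes multi-animal fix data.frame (raw, pre-filter).
#' @param polygon island polygon.
#' @param radius_km buffer radius, km.
#' @return data.frame: `id`, `label` ("dispersive" / "residential" /
#'   "undetermined"), `exit_day` (Date or NA).
#' @export
classify_dispersal <- function(fixes, polygon, radius_km = 10) {
  ids <- unique(fixes$id)
  out <- data.frame(id = ids, label = NA_character_,
                    exit_day = as.Date(NA))
  for (i in seq_along(ids)) {
    fa <- fixes[fixes$id == ids[i], , drop = FALSE]
    fa <- fa[order(fa$time), , drop = FALSE]
    ok <- is.finite(fa$lon) & is.finite(fa$lat)
    if (!any(ok)) { out$label[i] <- "undetermined"; next }
    d <- point_buffer_km(fa$lon[ok], fa$lat[ok], polygon)
    exc <- which(d > radius_km)
    if (length(exc)) {
      out$label[i] <- "dispersive"
      out$exit_day[i] <- as.Date(fa$time[ok][exc[1]], tz = "UTC")
    } else out$label[i] <- "residential"
  }
  out
}

#' Initial heading from the first two distinct fixes
#'
#' Bearing from the first fix to the first subsequent fix at a distinct
#' position, optionally expressed from magnetic north via a configured
#' declination. Coincident leading fixes are skipped (noted via message).
#'
#' @param fixes fix data.frame for one animal.
#' @param declination_deg magnetic declination (0 = true frame).
#' @return heading in degrees [0, 360), or NA if no two distinct fixes.
#' @export
initial_heading <- function(fixes, declination_deg = 0) {
  fa <- fixes[order(fixes$time), , drop = FALSE]
  if (nrow(fa) < 2) return(NA_real_)
  j <- which(fa$lon[-1] != fa$lon[1] | fa$lat[-1] != fa$lat[1])
  if (!length(j)) return(NA_real_)
  if (j[1] > 1) message("initial_heading: skipped ", j[1] - 1,
                        " coincident fix(es)")
  b <- bearing_deg(fa$lon[1], fa$lat[1],
                   fa$lon[j[1] + 1], fa$lat[j[1] + 1])
  to_magnetic(b, declination_deg)
}

#' Per-track summary statistics
#'
#' The seven per-animal statistics of the daily-location summary table:
#' track duration (days), mean 24-h displacement +/- SD (km), mean
#' bearing (circular mean of daily bearings, degrees from true north),
#' mean SST +/- SD, mean current speed +/- SD (km day^-1), mean swimming
#' speed +/- SD (km day^-1), and total displacement (start to end of
#' track, km).
#'
#' @param track a `regular_track`.
#' @param decomp the matching `swim_decomposition` (NULL allowed).
#' @param annotation the matching [annotate_track()] result (NULL allowed).
#' @return one-row data.frame.
#' @export
track_summary <- function(track, decomp = NULL, annotation = NULL) {
  n <- nrow(track)
  dur <- if (n > 1)
    as.numeric(difftime(track$time[n], track$time[1], units = "days")) else 1
  disp <- bear <- NA_real_
  disp_sd <- NA_real_; mean_bear <- NA_real_
  if (n > 1) {
    steps <- great_circle_km(track$lon[-n], track$lat[-n],
                             track$lon[-1], track$lat[-1])
    disp <- mean(steps); disp_sd <- stats::sd(steps)
    distinct <- track$lon[-n] != track$lon[-1] |
      track$lat[-n] != track$lat[-1]
    if (any(distinct)) {
      b <- bearing_deg(track$lon[-n][distinct], track$lat[-n][distinct],
                       track$lon[-1][distinct], track$lat[-1][distinct])
      mean_bear <- circ_mean_sd(.deg2rad(b))$mean_deg
    }
  }
  msd <- function(x) if (is.null(x) || !any(!is.na(x)))
    c(NA_real_, NA_real_) else c(mean(x, na.rm = TRUE),
                                 stats::sd(x, na.rm = TRUE))
  sst <- msd(annotation$sst)
  cur <- msd(annotation$cur_speed_kmday)
  swim <- msd(if (!is.null(decomp)) decomp$swim_speed else NULL)
  data.frame(id = track$id[1], duration_days = dur,
             mean_disp_km = disp, sd_disp_km = disp_sd,
             mean_bearing_deg = mean_bear,
             mean_sst = sst[1], sd_sst = sst[2],
             mean_cur_kmday = cur[1], sd_cur_kmday = cur[2],
             mean_swim_kmday = swim[1], sd_swim_kmday = swim[2],
             total_disp_km = if (n > 1)
               great_circle_km(track$lon[1], track$lat[1],
                               track$lon[n], track$lat[n]) else 0)
}

#' Cohort summary table
#'
#' Stacks [track_summary()] rows for every animal and joins the covariate
#' table (period, age class, weight), in the standard column order of the
#' per-animal daily-location summary.
#'
#' @param tracks named list of regular tracks.
#' @param decomps named list of decompositions (may be incomplete).
#' @param annotations named list of annotations (may be incomplete).
#' @param covariates per-animal covariate data.frame with `id`.
#' @return data.frame, one row per animal.
#' @export
cohort_summary <- function(tracks, decomps = list(), annotations = list(),
                           covariates = NULL) {
  if (length(tracks) == 0) return(data.frame())
  rows <- lapply(names(tracks), function(a)
    track_summary(tracks[[a]], decomps[[a]], annotations[[a]]))
  out <- do.call(rbind, rows)
  if (!is.null(covariates))
    out <- merge(covariates[, intersect(c("id", "period", "age_class",
                                          "weight_kg"), names(covariates))],
                 out, by = "id", sort = FALSE)
  out
}
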