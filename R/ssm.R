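# Track regularization: filter irregular, elliptically noisy ARGOS fixes
# and predict daily positions by fitting a 2-D continuous-time random walk
# (Brownian motion) state-space model per animal, with the per-fix error
# ellipse as the observation covariance. Estimation is exact Kalman
# maximum likelihood over the single process parameter sigma_p
# (km day^-1/2); daily states come from an RTS smoother on the combined
# fix + daily-grid timeline.
#
# Planarization: one local tangent plane per animal at its fix centroid
# (equirectangular). Track extents up to ~1200 km keep the distortion
# well below the ARGOS error scale; documented limit.

#' Remove fixes within a coastal buffer
#'
#' Drops every fix within `radius_km` of the island polygon (boundary
#' closed outward: a fix exactly at the radius is retained). Animals left
#' with fewer than 4 retained fixes are flagged unusable.
#'
#' @param fixes fix data.frame (see [read_fixes()]).
#' @param polygon island polygon (data.frame lon/lat).
#' @param radius_km buffer radius, km (default 10).
#' @return list: `retained` (fixes), `removed_count`, `unusable` (ids with
#'   < 4 retained fixes).
#' @export
buffer_filter <- function(fixes, polygon, radius_km = 10) {
  if (nrow(fixes) == 0)
    return(list(retained = fixes, removed_count = 0L, unusable = character()))
  d <- point_buffer_km(fixes$lon, fixes$lat, polygon)
  keep <- d >= radius_km
  retained <- fixes[keep, , drop = FALSE]
  rownames(retained) <- NULL
  counts <- table(factor(retained$id, levels = unique(fixes$id)))
  list(retained = retained,
       removed_count = sum(!keep),
       unusable = names(counts)[counts < 4])
}

## error ellipse (semi-major a, semi-minor b, orientation psi degrees
## clockwise from north) -> 2x2 covariance in (east, north) km^2
.ellipse_cov <- function(a, b, psi_deg) {
  psi <- .deg2rad(psi_deg)
  s <- sin(psi); c <- cos(psi)
  matrix(c(a^2 * s^2 + b^2 * c^2, (a^2 - b^2) * s * c,
           (a^2 - b^2) * s * c, a^2 * c^2 + b^2 * s^2), 2, 2)
}

## default per-class SD (km) used when a fix has no ellipse
.default_class_sd <- c("3" = 0.25, "2" = 0.5, "1" = 1, "0" = 2,
                       "A" = 4, "B" = 8, "Z" = 15)

## planar observation setup shared by fit and smoother
.ssm_prepare <- function(fixes, class_sd = .default_class_sd) {
  stopifnot(nrow(fixes) >= 1)
  ord <- order(fixes$time)
  fixes <- fixes[ord, , drop = FALSE]
  lon0 <- mean(fixes$lon); lat0 <- mean(fixes$lat)
  kmdeg <- EARTH_RADIUS_KM * pi / 180
  cs <- cos(.deg2rad(lat0))
  x <- .wrap_signed(fixes$lon - lon0) * cs * kmdeg
  y <- (fixes$lat - lat0) * kmdeg
  t_days <- as.numeric(difftime(fixes$time, fixes$time[1], units = "days"))
  R <- vector("list", nrow(fixes))
  for (i in seq_len(nrow(fixes))) {
    a <- fixes$smaj_km[i]; b <- fixes$smin_km[i]; o <- fixes$eor_deg[i]
    if (is.null(a) || is.na(a) || is.na(b) || is.na(o)) {
      sd <- class_sd[[as.character(fixes$class[i])]]
      if (is.null(sd)) sd <- max(class_sd)
      R[[i]] <- diag(sd^2, 2)
    } else {
      R[[i]] <- .ellipse_cov(a, b, o) + diag(1e-10, 2)
    }
  }
  list(fixes = fixes, lon0 = lon0, lat0 = lat0, cs = cs, kmdeg = kmdeg,
       z = cbind(x, y), t = t_days, R = R)
}

.ssm_unproject <- function(prep, xy) {
  data.frame(lon = wrap_lon(prep$lon0 + xy[, 1] / (prep$kmdeg * prep$cs)),
             lat = prep$lat0 + xy[, 2] / prep$kmdeg)
}

## negative log-likelihood of the CTRW at process SD sigma (km day^-1/2);
## prediction-error decomposition, first fix initializes the state
.ssm_nll <- function(sigma, prep) {
  z <- prep$z; tt <- prep$t; R <- prep$R
  n <- nrow(z)
  m <- z[1, ]; P <- R[[1]]
  nll <- 0
  q <- sigma^2
  for (i in 2:n) {
    dt <- tt[i] - tt[i - 1]
    Pp <- P + diag(q * dt, 2)
    S <- Pp + R[[i]]
    v <- z[i, ] - m
    detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
    Sinv_v <- c(S[2, 2] * v[1] - S[1, 2] * v[2],
                -S[1, 2] * v[1] + S[1, 1] * v[2]) / detS
    nll <- nll + 0.5 * (log(detS) + sum(v * Sinv_v)) + log(2 * pi)
    K <- Pp %*% rbind(c(S[2, 2], -S[1, 2]), c(-S[1, 2], S[1, 1])) / detS
    m <- m + as.vector(K %*% v)
    P <- (diag(2) - K) %*% Pp
  }
  nll
}

#' Fit the continuous-time random-walk process model
#'
#' Maximum-likelihood estimate of the process SD sigma_p (km day^-1/2) of
#' a 2-D Brownian-motion movement model observed through the per-fix
#' ARGOS error ellipses, via Kalman prediction-error decomposition.
#' The 1-D likelihood in log sigma_p is maximized on three deterministic
#' bracket restarts; deterministic given inputs.
#'
#' @param fixes fix data.frame for one animal (>= 4 fixes spanning >= 2
#'   days).
#' @param class_sd named per-class default SD (km) for fixes without
#'   ellipses.
#' @return object of class `rw_fit`: `sigma_p`, `loglik`, `converged`,
#'   `n_fixes`, plus the internal planar setup.
#' @export
fit_rw <- function(fixes, class_sd = .default_class_sd) {
  if (nrow(fixes) < 4) stop("need >= 4 fixes to fit the process model")
  prep <- .ssm_prepare(fixes, class_sd)
  if (max(prep$t) < 2) stop("fixes must span >= 2 days")
  nll_log <- function(ls) .ssm_nll(exp(ls), prep)
  brackets <- list(c(log(1e-2), log(2)), c(log(2), log(60)),
                   c(log(60), log(1e3)))
  best <- NULL
  for (b in brackets) {
    o <- stats::optimize(nll_log, b, tol = 1e-4)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  sigma <- exp(best$minimum)
  edge <- best$minimum < log(1e-2) + 1e-3 || best$minimum > log(1e3) - 1e-3
  structure(list(sigma_p = sigma, loglik = -best$objective,
                 converged = !edge && is.finite(best$objective),
                 n_fixes = nrow(prep$fixes), prep = prep),
            class = "rw_fit")
}

#' @export
print.rw_fit <- function(x, ...) {
  cat("CTRW fit: sigma_p =", signif(x$sigma_p, 4), "km/day^0.5, logLik =",
      signif(x$loglik, 6), ", n =", x$n_fixes,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

## Kalman filter + RTS smoother over an arbitrary increasing timeline;
## obs_idx maps timeline nodes to fix indices (NA = prediction-only node)
.ssm_smooth <- function(prep, sigma, times) {
  z <- prep$z; tt <- prep$t; R <- prep$R
  all_t <- sort(unique(c(tt, times)))
  obs_at <- match(all_t, tt)
  n <- length(all_t)
  q <- sigma^2
  mf <- matrix(0, n, 2); Pf <- vector("list", n)
  mp <- matrix(0, n, 2); Pp <- vector("list", n)
  # init at first node (always a fix: timeline starts at first fix)
  i1 <- which(!is.na(obs_at))[1]
  m <- z[obs_at[i1], ]; P <- R[[obs_at[i1]]]
  for (i in seq_len(n)) {
    if (i == 1) {
      mpre <- m; Ppre <- P
      if (i != i1) { mpre <- m; Ppre <- P + diag(1e6, 2) }  # before first fix
    } else {
      dt <- all_t[i] - all_t[i - 1]
      mpre <- mf[i - 1, ]; Ppre <- Pf[[i - 1]] + diag(q * dt, 2)
    }
    mp[i, ] <- mpre; Pp[[i]] <- Ppre
    oi <- obs_at[i]
    if (!is.na(oi) && !(i == 1 && i == i1)) {
      S <- Ppre + R[[oi]]
      detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
      K <- Ppre %*% rbind(c(S[2, 2], -S[1, 2]), c(-S[1, 2], S[1, 1])) / detS
      v <- z[oi, ] - mpre
      mf[i, ] <- mpre + as.vector(K %*% v)
      Pf[[i]] <- (diag(2) - K) %*% Ppre
    } else {
      mf[i, ] <- mpre; Pf[[i]] <- Ppre
    }
  }
  # RTS backward pass
  ms <- mf; Ps <- Pf
  if (n > 1) for (i in (n - 1):1) {
    Ppn <- Pp[[i + 1]]
    detP <- Ppn[1, 1] * Ppn[2, 2] - Ppn[1, 2]^2
    Ppn_inv <- rbind(c(Ppn[2, 2], -Ppn[1, 2]),
                     c(-Ppn[1, 2], Ppn[1, 1])) / detP
    G <- Pf[[i]] %*% Ppn_inv
    ms[i, ] <- mf[i, ] + as.vector(G %*% (ms[i + 1, ] - mp[i + 1, ]))
    Ps[[i]] <- Pf[[i]] + G %*% (Ps[[i + 1]] - Ppn) %*% t(G)
  }
  sel <- match(times, all_t)
  list(mean = ms[sel, , drop = FALSE],
       sd = vapply(sel, function(i)
         sqrt(pmax((Ps[[i]][1, 1] + Ps[[i]][2, 2]) / 2, 0)), numeric(1)))
}

#' Smooth fixes to a daily regular track
#'
#' RTS-smoothed state estimates of the fitted random walk at a 24-h grid
#' anchored at the first retained fix, mapped back from the local plane to
#' lon/lat. The grid never extends more than `max_extend_days` beyond the
#' last fix (no free extrapolation).
#'
#' @param fixes fix data.frame for one animal.
#' @param fit an [fit_rw()] result (omitted for the degenerate single-fix
#'   case).
#' @param max_extend_days truncation limit beyond the last fix.
#' @return data.frame of class `regular_track`: `id`, `day`, `time`,
#'   `lon`, `lat`, `sd_km`, `n_fixes` (source fixes that day).
#' @export
smooth_daily <- function(fixes, fit = NULL, max_extend_days = 3) {
  if (nrow(fixes) == 1) {
    out <- data.frame(id = fixes$id[1], day = 0L, time = fixes$time[1],
                      lon = fixes$lon[1], lat = fixes$lat[1],
                      sd_km = 0, n_fixes = 1L)
    class(out) <- c("regular_track", "data.frame")
    return(out)
  }
  if (is.null(fit)) fit <- fit_rw(fixes)
  if (!fit$converged) warning("using non-converged process fit")
  prep <- fit$prep
  span <- max(prep$t)
  n_days <- floor(span)
  if (n_days > ceiling(span) + max_extend_days) {
    warning("daily grid truncated to ", max_extend_days,
            " days beyond last fix")
    n_days <- ceiling(span) + max_extend_days
  }
  grid <- 0:n_days
  sm <- .ssm_smooth(prep, fit$sigma_p, grid)
  pos <- .ssm_unproject(prep, sm$mean)
  nf <- vapply(grid, function(d) sum(prep$t >= d & prep$t < d + 1),
               integer(1))
  out <- data.frame(id = prep$fixes$id[1], day = grid,
                    time = prep$fixes$time[1] + grid * 86400,
                    lon = pos$lon, lat = pos$lat, sd_km = sm$sd,
                    n_fixes = nf)
  class(out) <- c("regular_track", "data.frame")
  out
}

#' Over-interpolation diagnostics for gappy tracks
#'
#' For every inter-fix gap longer than `gap_days`, reports the gap length
#' and the straightness (straight-line / along-path distance) of the
#' predicted daily segment spanning it; segments straighter than
#' `threshold` are flagged as potential over-interpolation.
#'
#' @param fixes fix data.frame for one animal.
#' @param track the [smooth_daily()] result for the same animal.
#' @param gap_days report gaps longer than this (days).
#' @param threshold straightness flag level.
#' @return data.frame: gap start/end time, `gap_days`, `straightness`,
#'   `flagged`. Zero rows when the track has no qualifying gap.
#' @export
overinterpolation_report <- function(fixes, track, gap_days = 2,
                                     threshold = 0.99) {
  fixes <- fixes[order(fixes$time), , drop = FALSE]
  gaps <- diff(as.numeric(fixes$time)) / 86400
  idx <- which(gaps > gap_days)
  out <- data.frame(gap_start = as.POSIXct(character(), tz = "UTC"),
                    gap_end = as.POSIXct(character(), tz = "UTC"),
                    gap_days = numeric(), straightness = numeric(),
                    flagged = logical())
  for (i in idx) {
    t0 <- fixes$time[i]; t1 <- fixes$time[i + 1]
    seg <- track[track$time >= t0 & track$time <= t1, ]
    if (nrow(seg) < 2) next
    path <- sum(great_circle_km(seg$lon[-nrow(seg)], seg$lat[-nrow(seg)],
                                seg$lon[-1], seg$lat[-1]))
    line <- great_circle_km(seg$lon[1], seg$lat[1],
                            seg$lon[nrow(seg)], seg$lat[nrow(seg)])
    s <- if (path > 0) line / path else 1
    out <- rbind(out, data.frame(gap_start = t0, gap_end = t1,
                                 gap_days = gaps[i], straightness = s,
                                 flagged = s > threshold))
  }
  rownames(out) <- NULL
  out
}

#' Regularize a whole cohort of fixes
#'
#' Convenience wrapper: per animal, applies the coastal buffer filter,
#' fits the random walk and smooths to a daily track. Animals flagged
#' unusable (< 4 retained fixes) are skipped.
#'
#' @param fixes multi-animal fix data.frame.
#' @param polygon island polygon for the buffer filter (NULL = no filter).
#' @param radius_km buffer radius.
#' @return list: `tracks` (named list of regular tracks), `fits`,
#'   `skipped` (ids), `removed_count`.
#' @export
regularize_cohort <- function(fixes, polygon = NULL, radius_km = 10) {
  if (!is.null(polygon)) {
    bf <- buffer_filter(fixes, polygon, radius_km)
    fixes <- bf$retained; removed <- bf$removed_count
    unusable <- bf$unusable
  } else {
    removed <- 0L
    counts <- table(fixes$id)
    unusable <- names(counts)[counts < 4]
  }
  ids <- setdiff(unique(fixes$id), unusable)
  tracks <- list(); fits <- list()
  for (a in ids) {
    fa <- fixes[fixes$id == a, , drop = FALSE]
    if (as.numeric(difftime(max(fa$time), min(fa$time), units = "days")) < 2) {
      unusable <- c(unusable, a); next
    }
    fit <- fit_rw(fa)
    fits[[a]] <- fit
    tracks[[a]] <- smooth_daily(fa, fit)
  }
  list(tracks = tracks, fits = fits, skipped = unusable,
       removed_count = removed)
}
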