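# On-disk artifacts: CSV fix tables, long-format CSV gridded fields,
# island polygons, tidy daily-product tables and GeoJSON trajectories.
# All timestamps are UTC ISO-8601; coordinates are always named lon/lat
# columns (CSV) or [lon, lat] order (GeoJSON). No reader mutates values.

#' Construct a gridded environmental field
#'
#' Container for lon/lat/time rasters of environmental variables. Axes
#' must be regular (within 1e-6 degree) and strictly increasing; the time
#' axis is daily, but a variable may carry its own (e.g. weekly) time axis
#' as attribute `"time"` on its array.
#'
#' @param lon,lat axis values, degrees, regular and strictly increasing.
#' @param time Date vector (daily axis).
#' @param vars named list of arrays dim (n_lon, n_lat, n_time_var);
#'   u/v in m s^-1, sst in deg C, sargassum in g m^-2.
#' @return object of class `gridded_field`.
#' @export
gridded_field <- function(lon, lat, time, vars) {
  .check_axis(lon, "lon"); .check_axis(lat, "lat")
  time <- as.Date(time)
  if (any(diff(as.numeric(time)) <= 0)) stop("time axis must be increasing")
  for (nm in names(vars)) {
    v <- vars[[nm]]
    vt <- attr(v, "time"); if (is.null(vt)) vt <- time
    if (!all(dim(v)[1:2] == c(length(lon), length(lat))) ||
        dim(v)[3] != length(vt))
      stop("variable '", nm, "' does not match the axes")
  }
  structure(list(lon = lon, lat = lat, time = time, vars = vars),
            class = "gridded_field")
}

.check_axis <- function(x, name) {
  if (length(x) < 2) stop("axis '", name, "' needs >= 2 values")
  d <- diff(x)
  if (any(d <= 0)) stop("format error: axis '", name, "' not increasing")
  if (max(d) - min(d) > 1e-6)
    stop("format error: axis '", name, "' irregular beyond 1e-6 degree")
  invisible(TRUE)
}

#' @export
print.gridded_field <- function(x, ...) {
  cat("gridded_field:", length(x$lon), "x", length(x$lat), "cells,",
      length(x$time), "days,",
      "vars:", paste(names(x$vars), collapse = ", "), "\n")
  invisible(x)
}

# -- fix tables ---------------------------------------------------------

.fix_cols <- c("id", "time", "lon", "lat", "smaj_km", "smin_km",
               "eor_deg", "class")

#' Write a fix table
#'
#' UTF-8 CSV, one row per fix, ISO-8601 UTC timestamps, error-ellipse axes
#' in km. Column dictionary: `id` (animal), `time`, `lon`, `lat`,
#' `smaj_km`/`smin_km` (ellipse semi-axes, km), `eor_deg` (ellipse
#' orientation, degrees clockwise from north), `class` (opaque ARGOS
#' quality token).
#'
#' @param fixes data.frame of fixes (as from [observe_argos()]).
#' @param path output file.
#' @export
write_fixes <- function(fixes, path) {
  stopifnot(all(.fix_cols %in% names(fixes)))
  out <- fixes[, .fix_cols]
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a fix table
#'
#' Reads the CSV dialect of [write_fixes()]. Rows are sorted by time
#' within animal; duplicate timestamps within an animal collapse to the
#' first occurrence. If a `unit` column says `m`, ellipse axes are
#' converted from metres to km. Attribute `"ingest"` reports row
#' conservation (rows read, duplicates dropped).
#'
#' @param path CSV file.
#' @return data.frame of fixes sorted (id, time), with attribute `ingest`.
#' @export
read_fixes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(raw$class)) raw$class <- as.character(raw$class)
  if (nrow(raw) == 0) {
    out <- raw
    attr(out, "ingest") <- list(rows_in = 0L, duplicates_dropped = 0L)
    return(out)
  }
  missing_cols <- setdiff(c("id", "time", "lon", "lat"), names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tm <- as.POSIXct(raw$time, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- which(is.na(tm) & !is.na(raw$time))
  if (length(bad))
    stop("unparseable timestamp at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  raw$time <- tm
  if (!is.null(raw$unit) && any(raw$unit == "m")) {
    m <- raw$unit == "m"
    raw$smaj_km[m] <- raw$smaj_km[m] / 1000
    raw$smin_km[m] <- raw$smin_km[m] / 1000
    raw$unit <- NULL
  }
  ord <- order(raw$id, raw$time)
  out <- raw[ord, , drop = FALSE]
  dup <- duplicated(out[, c("id", "time")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ingest") <- list(rows_in = nrow(raw),
                              duplicates_dropped = sum(dup))
  out
}

# -- gridded fields -----------------------------------------------------

#' Write a gridded field as long-format CSV
#'
#' Plain-text dialect for gridded environmental fields: one file per
#' field, columns `var`, `time` (ISO date), `lon`, `lat`, `value`. Axes
#' are recovered from the unique coordinate values on read; values
#' round-trip at full double precision.
#'
#' @param field a `gridded_field`.
#' @param path output CSV.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  pieces <- lapply(names(field$vars), function(nm) {
    v <- field$vars[[nm]]
    vt <- attr(v, "time"); if (is.null(vt)) vt <- field$time
    data.frame(var = nm,
               time = rep(format(vt), each = length(field$lon) *
                            length(field$lat)),
               lon = rep(field$lon, times = length(field$lat) * length(vt)),
               lat = rep(rep(field$lat, each = length(field$lon)),
                         times = length(vt)),
               value = as.vector(v))
  })
  utils::write.csv(do.call(rbind, pieces), path, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field written by [write_field()]
#'
#' Longitudes stored on a 0-360 convention are normalized to [-180, 180)
#' on read. A gap in a variable's time axis is an error naming the first
#' missing date.
#'
#' @param path CSV file.
#' @return a `gridded_field`.
#' @export
read_field <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("var", "time", "lon", "lat", "value")
  if (!all(need %in% names(raw)))
    stop("schema error: field file needs columns ",
         paste(need, collapse = ", "))
  raw$lon <- wrap_lon(raw$lon)
  lon <- sort(unique(raw$lon)); lat <- sort(unique(raw$lat))
  .check_axis(lon, "lon"); .check_axis(lat, "lat")
  vars <- list(); field_time <- NULL
  for (nm in unique(raw$var)) {
    sub <- raw[raw$var == nm, ]
    vt <- sort(unique(as.Date(sub$time)))
    step <- if (length(vt) > 1) min(diff(as.numeric(vt))) else 1
    if (length(vt) > 1) {
      gaps <- which(diff(as.numeric(vt)) != step)
      if (length(gaps))
        stop("format error: time axis gap in '", nm, "' after ",
             format(vt[gaps[1]]))
    }
    arr <- array(NA_real_, c(length(lon), length(lat), length(vt)))
    ii <- match(sub$lon, lon); jj <- match(sub$lat, lat)
    kk <- match(as.Date(sub$time), vt)
    arr[cbind(ii, jj, kk)] <- sub$value
    if (step == 1 && is.null(field_time)) field_time <- vt
    if (!(step == 1 && identical(vt, field_time))) attr(arr, "time") <- vt
    vars[[nm]] <- arr
  }
  if (is.null(field_time)) {
    # no daily variable: promote the first variable's axis
    field_time <- attr(vars[[1]], "time")
    attr(vars[[1]], "time") <- NULL
  }
  gridded_field(lon, lat, field_time, vars)
}

# -- polygons -----------------------------------------------------------

#' Write / read an island polygon as CSV (lon, lat vertex per row)
#'
#' @param polygon data.frame with `lon`, `lat`.
#' @param path CSV file.
#' @export
write_polygon <- function(polygon, path) {
  utils::write.csv(polygon[, c("lon", "lat")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polygon
#' @export
read_polygon <- function(path) {
  p <- utils::read.csv(path)
  if (!all(c("lon", "lat") %in% names(p)))
    stop("schema error: polygon file needs lon, lat columns")
  p
}

# -- daily products -----------------------------------------------------

#' Write tidy daily products and trajectory GeoJSON
#'
#' One tidy CSV (animal, date, position, ground/current/swim velocity
#' components, step, turn, persistence, SST, sargassum where present) plus
#' one GeoJSON FeatureCollection per trajectory flavor (raw daily,
#' current-corrected) with a LineString per animal. Animals with a single
#' daily position are skipped in the GeoJSON with a warning (a LineString
#' needs two points).
#'
#' @param daily data.frame of per-animal daily products; must include
#'   `id`, `date`, `lon`, `lat`; optional `corr_lon`, `corr_lat`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisible list of written paths.
#' @export
write_daily_products <- function(daily, dir, stem = "daily") {
  stopifnot(all(c("id", "date", "lon", "lat") %in% names(daily)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_products.csv"))
  utils::write.csv(daily, csv, row.names = FALSE)
  paths <- list(table = csv)
  flavors <- list(regularized = c("lon", "lat"))
  if (all(c("corr_lon", "corr_lat") %in% names(daily)))
    flavors$corrected <- c("corr_lon", "corr_lat")
  for (fl in names(flavors)) {
    cols <- flavors[[fl]]
    feats <- list()
    for (a in unique(daily$id)) {
      sub <- daily[daily$id == a & !is.na(daily[[cols[1]]]), ]
      if (nrow(sub) < 2) {
        warning("animal ", a, ": fewer than 2 positions; skipped in GeoJSON")
        next
      }
      coords <- lapply(seq_len(nrow(sub)), function(i)
        c(sub[[cols[1]]][i], sub[[cols[2]]][i]))
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(id = a, flavor = fl),
        geometry = list(type = "LineString", coordinates = coords))
    }
    gj <- list(type = "FeatureCollection", features = feats)
    p <- file.path(dir, paste0(stem, "_", fl, ".geojson"))
    jsonlite::write_json(gj, p, auto_unbox = TRUE, digits = NA)
    paths[[fl]] <- p
  }
  invisible(paths)
}

#' Read trajectory coordinates back from a GeoJSON written by
#' [write_daily_products()]
#'
#' @param path GeoJSON file.
#' @return named list (per animal) of data.frames with lon, lat.
#' @export
read_trajectories <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- list()
  for (f in gj$features) {
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(c2) unlist(c2)))
    out[[f$properties$id]] <- data.frame(lon = m[, 1], lat = m[, 2])
  }
  out
}
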