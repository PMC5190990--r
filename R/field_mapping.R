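# Survey-log I/O, microclimate de-trending, extraneous-reading filtering,
# IDW spatialization and thematic-map export (the post-processing role).

survey_columns <- function() {
  c("timestamp", "lat", "lon", "side", "vine_id", "rh", "at", "us",
    "n_satellites", paste0("ci_s", 1:15), paste0("st_s", 1:16))
}

#' Create a survey track from per-poll sensor records
#'
#' One row per poll of one row side: timestamp (seconds from survey start),
#' WGS84 position, side (`"left"`/`"right"`), optional vine identifier,
#' relative humidity (%), air temperature (C), ultrasonic distance to the
#' canopy wall (cm), GPS satellite count, the 15 CI sector values
#' (`ci_s1..ci_s15`) and the 16 ST sector values (`st_s1..st_s16`).
#'
#' @param records A data frame with the columns listed above.
#' @param frequency_hz Polling frequency metadata (default 3 Hz).
#' @param speed_kmh Nominal survey speed metadata.
#' @return The data frame with class `survey_track` and metadata attributes.
#' @export
survey_track <- function(records, frequency_hz = 3, speed_kmh = NA_real_) {
  missing_cols <- setdiff(survey_columns(), names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory survey columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) > 0L) {
    if (is.unsorted(records$timestamp)) {
      stop("timestamps must be non-decreasing", call. = FALSE)
    }
    if (any(records$lat < -90 | records$lat > 90, na.rm = TRUE) ||
        any(records$lon < -180 | records$lon > 180, na.rm = TRUE)) {
      stop("coordinates outside WGS84 bounds", call. = FALSE)
    }
    if (!all(records$side %in% c("left", "right"))) {
      stop("side must be 'left' or 'right'", call. = FALSE)
    }
  }
  attr(records, "frequency_hz") <- frequency_hz
  attr(records, "speed_kmh") <- speed_kmh
  class(records) <- c("survey_track", "data.frame")
  records
}

#' Read / write a survey log (CSV)
#'
#' The writer emits full double precision so a write/read round trip
#' reproduces every field of text-representable values exactly. The reader
#' errors on missing mandatory columns (listing them) and skips malformed
#' rows (non-finite position or timestamp, unknown side), reporting the
#' count via a message and the `"skipped"` attribute.
#'
#' @param path CSV path.
#' @param track A [survey_track()].
#' @return `read_survey_log()` returns a `survey_track`;
#'   `write_survey_log()` returns `path` invisibly.
#' @export
read_survey_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(survey_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("survey log lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # declared types: malformed cells become NA and the row is skipped below
  num_cols <- setdiff(survey_columns(), c("side", "vine_id", "n_satellites"))
  df[num_cols] <- lapply(df[num_cols],
                         function(v) suppressWarnings(as.numeric(v)))
  df$n_satellites <- suppressWarnings(as.integer(df$n_satellites))
  ok <- is.finite(df$timestamp) & is.finite(df$lat) & is.finite(df$lon) &
    df$side %in% c("left", "right")
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    message("skipped ", n_bad, " malformed survey row(s)")
    df <- df[ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  out <- survey_track(df)
  attr(out, "skipped") <- n_bad
  out
}

#' @rdname read_survey_log
#' @export
write_survey_log <- function(track, path) {
  df <- as.data.frame(track)[, survey_columns(), drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) {
    s <- formatC(v, format = "g", digits = 17)
    s[is.na(v)] <- NA
    trimws(s)
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' De-trend a microclimate series
#'
#' Calibration of relative humidity and air temperature: a moving-median
#' smoothing (window 5) followed by removal of the fitted linear time trend,
#' re-centered on the survey mean, so the output is not influenced by the
#' flow of time over a multi-hour acquisition.
#'
#' @param values Numeric series (chronological order).
#' @param times Acquisition times; defaults to the sample index.
#' @param window Moving-median window (odd, default 5).
#' @return De-trended series, same length; input is passed through with a
#'   warning when shorter than 5 points.
#' @export
detrend_microclimate <- function(values, times = seq_along(values),
                                 window = 5L) {
  if (length(values) != length(times)) stop("values/times length mismatch",
                                            call. = FALSE)
  if (length(values) < 5L) {
    warning("fewer than 5 points: series passed through unchanged")
    return(values)
  }
  sm <- stats::runmed(values, k = window, endrule = "median")
  fit <- stats::lm.fit(cbind(1, times), sm)
  as.vector(sm - fit$fitted.values + mean(sm))
}

#' Filter extraneous side readings from a survey track
#'
#' Two filters: (a) records located outside the vineyard boundary polygon
#' are dropped; (b) per side, a record whose vine-level CI (mean of the 15
#' sector values) deviates from the running 9-record median of that side by
#' more than `mad_mult` times the running median absolute deviation is
#' dropped. Dropped sides leave the partner side usable through
#' [average_sides()]'s single-side path. Filtering never invents records.
#'
#' @param track A [survey_track()].
#' @param boundary Optional polygon as a 2-column matrix / data frame of
#'   (lon, lat) vertices.
#' @param mad_mult Robust-deviation multiple (default 4).
#' @param window Running-median window (default 9 records).
#' @return The filtered `survey_track` (possibly empty); attribute
#'   `"n_dropped"` reports how many records were removed.
#' @export
filter_extraneous <- function(track, boundary = NULL, mad_mult = 4,
                              window = 9L) {
  stopifnot(inherits(track, "survey_track"))
  if (nrow(track) == 0L) return(track)
  keep <- rep(TRUE, nrow(track))
  if (!is.null(boundary)) {
    boundary <- as.matrix(boundary)
    inside <- sp::point.in.polygon(track$lon, track$lat,
                                   boundary[, 1L], boundary[, 2L]) > 0
    keep <- keep & inside
  }
  ci_cols <- paste0("ci_s", 1:15)
  vine_ci <- rowMeans(as.data.frame(track)[, ci_cols, drop = FALSE])
  for (s in c("left", "right")) {
    i <- which(track$side == s & keep)
    if (length(i) < 3L) next
    v <- vine_ci[i]
    med <- running_median(v, window)
    rmad <- running_mad(v, window)
    dev <- abs(v - med)
    out <- dev > mad_mult * rmad & dev > 0
    keep[i[out]] <- FALSE
  }
  n_drop <- sum(!keep)
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- survey_track(as.data.frame(out),
                      frequency_hz = attr(track, "frequency_hz"),
                      speed_kmh = attr(track, "speed_kmh"))
  attr(out, "n_dropped") <- n_drop
  out
}

running_median <- function(v, window) {
  n <- length(v)
  if (n >= window) return(as.vector(stats::runmed(v, k = window,
                                                  endrule = "median")))
  rep(stats::median(v), n)
}

running_mad <- function(v, window) {
  n <- length(v)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    w <- v[max(1L, i - half):min(n, i + half)]
    stats::mad(w)
  }, numeric(1L))
}

#' Inverse-distance-weighted spatialization onto a raster grid
#'
#' Interpolates located point values onto a regular grid with
#' inverse-distance weights `1 / d^power` within a search radius. A cell
#' coincident with a sample takes the sample value exactly; cells with no
#' in-radius neighbor receive the no-data sentinel.
#'
#' @param x,y Point coordinates (meters, local plane).
#' @param values Point values.
#' @param grid A list `(x0, y0, nx, ny, cell)`: lower-left cell-center
#'   origin, grid dimensions and cell size in meters. Default: bounding box
#'   of the points at 2 m cells.
#' @param power IDW exponent (default 2).
#' @param radius Search radius in meters (default `Inf`).
#' @return An object of class `raster_map`: `values` (`ny x nx` matrix, row
#'   1 = northernmost), `x0`, `y0`, `cell`, `param`, `nodata`.
#' @param param Parameter name stored with the raster.
#' @export
spatialize_idw <- function(x, y, values, grid = NULL, power = 2,
                           radius = Inf, param = "value") {
  if (length(x) == 0L) stop("empty input: nothing to spatialize", call. = FALSE)
  stopifnot(length(x) == length(y), length(x) == length(values))
  ok <- is.finite(x) & is.finite(y) & is.finite(values)
  x <- x[ok]; y <- y[ok]; values <- values[ok]
  if (length(x) == 0L) stop("no finite points to spatialize", call. = FALSE)
  if (is.null(grid)) grid <- grid_from_points(x, y, cell = 2)
  cx <- grid$x0 + (seq_len(grid$nx) - 1L) * grid$cell
  cy <- grid$y0 + (seq_len(grid$ny) - 1L) * grid$cell
  vals <- matrix(NA_real_, nrow = grid$ny, ncol = grid$nx)
  for (j in seq_len(grid$nx)) {
    dx2 <- (x - cx[j])^2
    for (i in seq_len(grid$ny)) {
      d <- sqrt(dx2 + (y - cy[i])^2)
      hit <- which(d < 1e-9)
      if (length(hit) > 0L) {
        vals[i, j] <- mean(values[hit])
        next
      }
      nb <- d <= radius
      if (!any(nb)) next
      w <- 1 / d[nb]^power
      vals[i, j] <- sum(w * values[nb]) / sum(w)
    }
  }
  # store north-up: row 1 = max y
  vals <- vals[rev(seq_len(grid$ny)), , drop = FALSE]
  structure(list(values = vals, x0 = grid$x0, y0 = grid$y0,
                 nx = grid$nx, ny = grid$ny, cell = grid$cell,
                 param = param, nodata = -9999),
            class = "raster_map")
}

#' Grid specification covering a point set
#'
#' @param x,y Point coordinates (meters).
#' @param cell Cell size in meters (default 2).
#' @param pad Padding around the bounding box, meters.
#' @return A grid list usable by [spatialize_idw()].
#' @export
grid_from_points <- function(x, y, cell = 2, pad = cell) {
  if (cell <= 0) stop("cell size must be positive", call. = FALSE)
  x0 <- min(x) - pad
  y0 <- min(y) - pad
  nx <- max(1L, ceiling((max(x) + pad - x0) / cell) + 1L)
  ny <- max(1L, ceiling((max(y) + pad - y0) / cell) + 1L)
  list(x0 = x0, y0 = y0, nx = nx, ny = ny, cell = cell)
}

#' @export
print.raster_map <- function(x, ...) {
  cat(sprintf("<raster_map> %s: %d x %d cells @ %.2f m (%d valid)\n",
              x$param, x$ny, x$nx, x$cell, sum(is.finite(x$values))))
  invisible(x)
}

#' Write a raster map as ESRI ASCII grid
#'
#' @param raster A [spatialize_idw()] result.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "raster_map"))
  v <- raster$values
  v[!is.finite(v)] <- raster$nodata
  header <- c(
    sprintf("NCOLS %d", raster$nx),
    sprintf("NROWS %d", raster$ny),
    sprintf("XLLCENTER %.6f", raster$x0),
    sprintf("YLLCENTER %.6f", raster$y0),
    sprintf("CELLSIZE %.6f", raster$cell),
    sprintf("NODATA_VALUE %d", raster$nodata))
  body <- apply(v, 1L, function(row) paste(formatC(row, format = "g",
                                                   digits = 10),
                                           collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Sampling interval along the tractor path
#'
#' Distance between consecutive polls: `(speed in m/s) / frequency`. At the
#' usual 4-8 km/h survey speeds and 3 Hz polling this is 0.37-0.74 m.
#'
#' @param speed_kmh Tractor speed, km/h (> 0).
#' @param frequency_hz Polling frequency, Hz (> 0).
#' @return Sampling interval in meters.
#' @export
sampling_interval <- function(speed_kmh, frequency_hz = 3) {
  stop_if_not_scalar_number(speed_kmh, "speed_kmh")
  stop_if_not_scalar_number(frequency_hz, "frequency_hz")
  if (speed_kmh <= 0 || frequency_hz <= 0) {
    stop("speed and frequency must be positive", call. = FALSE)
  }
  (speed_kmh * 1000 / 3600) / frequency_hz
}

# Local equirectangular projection: lon/lat degrees -> meters around origin.
lonlat_to_meters <- function(lon, lat, origin = c(mean(lon), mean(lat))) {
  m_per_deg_lat <- 111320
  list(x = (lon - origin[1L]) * m_per_deg_lat * cos(origin[2L] * pi / 180),
       y = (lat - origin[2L]) * m_per_deg_lat,
       origin = origin)
}

#' Thematic map catalog
#'
#' All map products the exporter can produce: whole-wall CI, ultrasonic
#' distance, calibrated RH and AT, the 15 CI and 16 ST sector maps, mean ST,
#' vegetation center of gravity and moment of inertia, the 5 macro-sector
#' background-corrected canopy temperatures, satellite count and the GPS
#' track.
#'
#' @return Character vector of valid catalog keys.
#' @export
map_catalog <- function() {
  c("CI", "US", "RH", "AT", paste0("CI_", 1:15), "ST", paste0("ST_", 1:16),
    "COG", "MOI", paste0("CINST_", c("Lower", "Low", "Center", "Up", "Upper")),
    "N_SAT", "TRACK")
}

# Per-record derived scalar for one catalog key.
map_values <- function(track, key, bg) {
  df <- as.data.frame(track)
  ci_mat <- as.matrix(df[, paste0("ci_s", 1:15), drop = FALSE])
  st_mat <- as.matrix(df[, paste0("st_s", 1:16), drop = FALSE])
  if (key == "CI") return(rowMeans(ci_mat))
  if (key == "US") return(df$us)
  if (key == "RH") return(detrend_microclimate(df$rh, df$timestamp))
  if (key == "AT") return(detrend_microclimate(df$at, df$timestamp))
  if (key == "ST") return(rowMeans(st_mat))
  if (key == "N_SAT") return(df$n_satellites)
  if (grepl("^CI_[0-9]+$", key)) {
    return(ci_mat[, as.integer(sub("CI_", "", key))])
  }
  if (grepl("^ST_[0-9]+$", key)) {
    return(st_mat[, as.integer(sub("ST_", "", key))])
  }
  if (key == "COG" || key == "MOI") {
    f <- if (key == "COG") center_of_gravity else moment_of_inertia
    return(vapply(seq_len(nrow(df)), function(i) {
      ci <- ci_mat[i, ]
      if (sum(ci) <= 0) return(NA_real_)
      f(ci)
    }, numeric(1L)))
  }
  if (grepl("^CINST_", key)) {
    macro <- sub("CINST_", "", key)
    ms <- macro_sector_map()[[macro]]
    st_mean <- rowMeans(st_mat[, ms$st, drop = FALSE])
    f_v <- rowMeans(ci_mat[, ms$ci, drop = FALSE]) / 1000
    tv <- (st_mean - bg$t_background * (1 - f_v)) / f_v
    tv[f_v <= 0] <- NA_real_
    return(tv)
  }
  stop("unhandled key: ", key, call. = FALSE)
}

#' Export thematic maps from a survey track
#'
#' Spatializes the requested catalog parameters onto rasters (ESRI ASCII
#' grid, one file per parameter) in a local metric plane centered on the
#' track; the GPS track itself is exported as a GeoJSON LineString with the
#' stop points. Stop records of the two sides are averaged per location
#' before spatialization.
#'
#' @param track A [survey_track()].
#' @param outdir Output directory (created if needed).
#' @param params Catalog keys (see [map_catalog()]); `"all"` selects the
#'   full catalog (about 50 products). The combined CI x ultrasonic "3D
#'   Canopy Index" is deliberately not implemented and raises an error.
#' @param cell Raster cell size in meters (default 2).
#' @param power,radius IDW parameters (see [spatialize_idw()]).
#' @param bg Background model for the macro-sector temperature maps.
#' @return Named character vector of written file paths, invisibly.
#' @export
export_maps <- function(track, outdir, params = "all", cell = 2, power = 2,
                        radius = Inf, bg = background_model()) {
  stopifnot(inherits(track, "survey_track"))
  if (identical(params, "all")) params <- map_catalog()
  if (any(params %in% c("CI3D", "3D", "3D Canopy Index", "CI_3D"))) {
    stop("the 3D Canopy Index (CI x ultrasonic combination) is not implemented",
         call. = FALSE)
  }
  unknown <- setdiff(params, map_catalog())
  if (length(unknown) > 0L) {
    stop("unknown catalog key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(map_catalog(), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(track) == 0L) stop("empty track", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  xy <- lonlat_to_meters(track$lon, track$lat)
  grid <- grid_from_points(xy$x, xy$y, cell = cell)
  paths <- character(0)
  for (key in params) {
    if (key == "TRACK") {
      p <- file.path(outdir, "track.geojson")
      write_track_geojson(track, p)
      paths[key] <- p
      next
    }
    v <- map_values(track, key, bg)
    ok <- is.finite(v)
    if (!any(ok)) {
      warning("no valid values for ", key, "; skipped")
      next
    }
    r <- spatialize_idw(xy$x[ok], xy$y[ok], v[ok], grid = grid,
                        power = power, radius = radius, param = key)
    p <- file.path(outdir, paste0(key, ".asc"))
    write_ascii_grid(r, p)
    paths[key] <- p
  }
  invisible(paths)
}

#' Write the GPS track as GeoJSON
#'
#' A FeatureCollection with one LineString (the ride path) and one Point per
#' record carrying timestamp, side, vine and satellite count.
#'
#' @param track A [survey_track()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_track_geojson <- function(track, path) {
  stopifnot(inherits(track, "survey_track"))
  coords <- lapply(seq_len(nrow(track)),
                   function(i) c(track$lon[i], track$lat[i]))
  points <- lapply(seq_len(nrow(track)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(track$lon[i], track$lat[i])),
         properties = list(timestamp = track$timestamp[i],
                           side = track$side[i],
                           vine_id = track$vine_id[i],
                           n_satellites = track$n_satellites[i]))
  })
  fc <- list(type = "FeatureCollection",
             features = c(list(list(type = "Feature",
                                    geometry = list(type = "LineString",
                                                    coordinates = coords),
                                    properties = list(name = "survey track"))),
                          points))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
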