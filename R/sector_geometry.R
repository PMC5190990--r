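#' Sensor mounting geometry
#'
#' Geometry of the upward-tilted side-view sensor relative to the canopy
#' wall. Defaults reproduce the reference setup: 250 cm row spacing, support
#' wire at 70 cm, sensor at 50 cm from the ground tilted 41 degrees to the
#' horizontal, 160 cm canopy top plus a small field-of-view margin.
#'
#' @param row_spacing Distance between rows, cm (> 0).
#' @param wire_height Height of the main support wire, cm.
#' @param sensor_height Sensor height above ground, cm (below `canopy_top`).
#' @param tilt_alpha Sensor tilt to the horizontal plane, degrees in (0, 90).
#' @param canopy_top Top of the canopy wall, cm (> `wire_height`).
#' @param fov_upper_margin Extra field-of-view above the canopy top, cm.
#' @return An object of class `sensor_geometry`.
#' @export
sensor_geometry <- function(row_spacing = 250, wire_height = 70,
                            sensor_height = 50, tilt_alpha = 41,
                            canopy_top = 160, fov_upper_margin = 10) {
  for (nm in c("row_spacing", "wire_height", "sensor_height", "tilt_alpha",
               "canopy_top", "fov_upper_margin")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (row_spacing <= 0) stop("row_spacing must be > 0", call. = FALSE)
  if (sensor_height < 0 || sensor_height >= canopy_top) {
    stop("sensor_height must satisfy 0 <= sensor_height < canopy_top",
         call. = FALSE)
  }
  if (canopy_top <= wire_height) {
    stop("canopy_top must exceed wire_height", call. = FALSE)
  }
  if (wire_height < sensor_height) {
    stop("support wire below the sensor: upward view angles undefined",
         call. = FALSE)
  }
  if (tilt_alpha <= 0 || tilt_alpha >= 90) {
    stop("tilt_alpha must lie in (0, 90) degrees", call. = FALSE)
  }
  if (fov_upper_margin < 0) stop("fov_upper_margin must be >= 0", call. = FALSE)
  structure(list(row_spacing = row_spacing, wire_height = wire_height,
                 sensor_height = sensor_height, tilt_alpha = tilt_alpha,
                 canopy_top = canopy_top, fov_upper_margin = fov_upper_margin),
            class = "sensor_geometry")
}

#' Default macro-sector map
#'
#' The five named macro-sectors where CI and surface-temperature sectors
#' overlap, used for the background-corrected canopy temperature:
#' Lower (ST 6-7 / CI 1-2), Low (ST 8-9 / CI 3-4), Center (ST 10-12 /
#' CI 5-7), Up (ST 13-14 / CI 8-9), Upper (ST 15-16 / CI 10-11).
#'
#' @return Named list; each entry has integer vectors `st` and `ci`.
#' @export
macro_sector_map <- function() {
  list(Lower  = list(st = 6:7,   ci = 1:2),
       Low    = list(st = 8:9,   ci = 3:4),
       Center = list(st = 10:12, ci = 5:7),
       Up     = list(st = 13:14, ci = 8:9),
       Upper  = list(st = 15:16, ci = 10:11))
}

#' Build the 15 CI / 16 ST canopy-wall sector layout
#'
#' The tilted sensor slices the canopy wall into sectors of equal angular
#' extent; because of the tilt, sector heights grow from the base to the
#' top. The 15 CI sectors span the wall from the support wire (CI sector 1
#' is anchored at the wire) to the canopy top plus the field-of-view margin.
#' The 16 ST sectors use the same angular step, aligned so ST sector 6
#' starts at the wire (ST 6-16 coincide with CI 1-11; ST 1-5 extend the
#' slicing below the wire and are carried as data only).
#'
#' @param geom A [sensor_geometry()].
#' @return An object of class `sector_layout`: list with `ci_bounds`
#'   (16 boundary heights, cm), `st_bounds` (17 boundary heights),
#'   `ci_mid`/`st_mid` (sector mid-heights), `macro_map` and `geom`.
#' @examples
#' lay <- build_sector_layout(sensor_geometry())
#' lay$ci_bounds[1]  # 70: CI sector 1 anchored at the wire
#' @export
build_sector_layout <- function(geom = sensor_geometry()) {
  stopifnot(inherits(geom, "sensor_geometry"))
  d <- geom$row_spacing / 2  # sensor stands off mid-row
  theta0 <- atan((geom$wire_height - geom$sensor_height) / d)
  theta_top <- atan((geom$canopy_top + geom$fov_upper_margin -
                       geom$sensor_height) / d)
  if (theta_top <= theta0) {
    stop("field of view collapsed: canopy top not above the wire",
         call. = FALSE)
  }
  ci_angles <- seq(theta0, theta_top, length.out = 16L)
  step <- (theta_top - theta0) / 15
  st_angles <- theta0 + (-5:11) * step
  h_of <- function(theta) geom$sensor_height + d * tan(theta)
  ci_bounds <- h_of(ci_angles)
  st_bounds <- h_of(st_angles)
  structure(
    list(ci_bounds = ci_bounds, st_bounds = st_bounds,
         ci_mid = (ci_bounds[-16L] + ci_bounds[-1L]) / 2,
         st_mid = (st_bounds[-17L] + st_bounds[-1L]) / 2,
         macro_map = macro_sector_map(), geom = geom),
    class = "sector_layout")
}

#' @export
print.sector_layout <- function(x, ...) {
  cat(sprintf(
    "<sector_layout> 15 CI sectors [%.1f, %.1f] cm, 16 ST sectors [%.1f, %.1f] cm\n",
    x$ci_bounds[1], x$ci_bounds[16], x$st_bounds[1], x$st_bounds[17]))
  invisible(x)
}

#' Export / import a sector layout as JSON
#'
#' @param layout A [build_sector_layout()] result.
#' @param path Output (or input) JSON path.
#' @return `write_sector_layout()` returns `path` invisibly;
#'   `read_sector_layout()` returns a `sector_layout`.
#' @export
write_sector_layout <- function(layout, path) {
  stopifnot(inherits(layout, "sector_layout"))
  jsonlite::write_json(
    list(geometry = unclass(layout$geom),
         ci_bounds = layout$ci_bounds, st_bounds = layout$st_bounds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sector_layout
#' @export
read_sector_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_sector_layout(do.call(sensor_geometry, as.list(j$geometry)))
}

#' A 15-sector Canopy Index profile
#'
#' @param values 15 CI values in `[0, 1000]`, base to top (`NA` allowed for
#'   missing sectors).
#' @param heights 15 strictly increasing sector mid-heights, cm; defaults to
#'   the mid-heights of `layout`.
#' @param layout A [build_sector_layout()] used for default heights.
#' @param id Optional vine / location identifier.
#' @return An object of class `sector_profile`.
#' @export
sector_profile <- function(values, heights = NULL,
                           layout = build_sector_layout(), id = NULL) {
  values <- as.numeric(values)
  if (length(values) != 15L) stop("a CI profile has exactly 15 sectors",
                                  call. = FALSE)
  ok <- !is.na(values)
  if (any(values[ok] < 0 | values[ok] > 1000)) {
    stop("CI values must lie in [0, 1000]", call. = FALSE)
  }
  if (is.null(heights)) heights <- layout$ci_mid
  heights <- as.numeric(heights)
  if (length(heights) != 15L || anyNA(heights) || any(diff(heights) <= 0)) {
    stop("heights must be 15 strictly increasing values", call. = FALSE)
  }
  structure(list(values = values, heights = heights, id = id),
            class = "sector_profile")
}

#' @export
print.sector_profile <- function(x, ...) {
  cat(sprintf("<sector_profile>%s 15 sectors, CI %.0f-%.0f\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Interpolate a CI profile at arbitrary heights
#'
#' A linear variation of CI between two adjacent sector mid-heights is
#' assumed: for height `x` between nodes `x_s` and `x_(s+1)`,
#' `(y - y_s)/(y_(s+1) - y_s) = (x - x_s)/(x_(s+1) - x_s)`.
#'
#' @param profile A [sector_profile()].
#' @param h Height(s) in cm; must lie within the mid-height range of sectors
#'   1-15 unless `clamp = TRUE`.
#' @param clamp If `TRUE`, heights beyond the end sectors take the end
#'   sector value instead of raising an error.
#' @return Interpolated CI value(s).
#' @export
interpolate_ci <- function(profile, h, clamp = FALSE) {
  stopifnot(inherits(profile, "sector_profile"))
  if (anyNA(profile$values)) {
    stop("profile has missing sectors; interpolation undefined", call. = FALSE)
  }
  rng <- range(profile$heights)
  if (!clamp && any(h < rng[1] | h > rng[2])) {
    stop(sprintf("height outside the interpolable range [%.1f, %.1f] cm",
                 rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(profile$heights, profile$values, xout = h, rule = 2)$y
}

#' The 18 point-quadrat heights
#'
#' Levels `C_(10n-25)` for `n = 1..18`: -15, -5, ..., 155 cm relative to the
#' main support wire.
#'
#' @return Integer vector of 18 heights (cm, wire-relative).
#' @export
pqa_levels <- function() 10L * (1:18) - 25L

#' Reposition a CI profile onto the point-quadrat levels
#'
#' Interpolates the 15-sector profile at the 18 point-quadrat heights
#' (converted to absolute heights by adding the wire height) so CI and PQA
#' metrics can be compared level by level. Levels outside the interpolable
#' range are returned as `NA` (flagged missing, not an error).
#'
#' @param profile A [sector_profile()].
#' @param levels Wire-relative heights in cm; default [pqa_levels()].
#' @param wire_height Support wire height in cm (default 70).
#' @return Named numeric vector (`CI_-15`, `CI_-5`, ..., `CI_155`).
#' @export
reposition_to_pqa_levels <- function(profile, levels = pqa_levels(),
                                     wire_height = 70) {
  stopifnot(inherits(profile, "sector_profile"))
  abs_h <- levels + wire_height
  rng <- range(profile$heights)
  inside <- abs_h >= rng[1] & abs_h <= rng[2]
  out <- rep(NA_real_, length(levels))
  if (any(inside)) out[inside] <- interpolate_ci(profile, abs_h[inside])
  names(out) <- paste0("CI_", levels)
  out
}

#' Per-vine Canopy Index
#'
#' The CI of one vine is the arithmetic mean of its 15 canopy-sector values.
#'
#' @param profile A [sector_profile()].
#' @param na_rm If `TRUE`, missing sectors are ignored instead of raising an
#'   error.
#' @return Numeric CI in `[0, 1000]`.
#' @export
vine_mean_ci <- function(profile, na_rm = FALSE) {
  stopifnot(inherits(profile, "sector_profile"))
  if (anyNA(profile$values) && !na_rm) {
    stop("profile has missing sectors (set na_rm = TRUE to ignore them)",
         call. = FALSE)
  }
  mean(profile$values, na.rm = na_rm)
}
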