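# Coupled synthetic-vineyard generator. One virtual-canopy occupancy model
# drives the rendered side-view frames, the point-quadrat insertions and the
# survey sector profiles, so image-derived CI and simulated ground truth are
# correlated mechanistically rather than by construction of the answer.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Create a virtual canopy
#'
#' The canopy is a vertical leaf-density profile `lambda(h)`: the expected
#' number of leaf contacts of a horizontal rod insertion at height `h` (cm
#' above ground). The profile is a scaled beta shape over the canopy-wall
#' span (15 cm below the support wire up to the canopy top) whose mode lies
#' in a basal band above the wire, where trellised vines concentrate foliage
#' around the fruiting zone. A smooth multiplicative patchiness field `g(x)`
#' (mean 1) modulates density along the row.
#'
#' @param vigor Peak leaf density (expected contacts per insertion at the
#'   densest height); 0 gives a bare canopy.
#' @param canopy_height Canopy top, cm above ground.
#' @param wire_height Support-wire height, cm (default 70).
#' @param patchiness Log-scale amplitude of the horizontal density field
#'   (0 = perfectly homogeneous row).
#' @param peak_band Wire-relative band (cm) containing the density peak;
#'   default 15-45 cm above the wire.
#' @param seed Integer seed; the canopy is fully reproducible given the seed.
#' @return An object of class `virtual_canopy` with functions `lambda(h)`
#'   and `patch(x)` (`x` in `[0, 1]` along the row).
#' @export
make_virtual_canopy <- function(vigor = 2, canopy_height = 160,
                                wire_height = 70, patchiness = 0.25,
                                peak_band = c(15, 45), seed = 1) {
  stop_if_not_scalar_number(vigor, "vigor")
  if (vigor < 0) stop("negative leaf density: vigor must be >= 0",
                      call. = FALSE)
  if (patchiness < 0) stop("patchiness must be >= 0", call. = FALSE)
  if (canopy_height <= wire_height) {
    stop("canopy_height must exceed wire_height", call. = FALSE)
  }
  h_lo <- wire_height - 15
  h_hi <- canopy_height
  mode_t <- (wire_height + mean(peak_band) - h_lo) / (h_hi - h_lo)
  mode_t <- min(max(mode_t, 0.05), 0.95)
  a <- 1 + 5 * mode_t
  b <- 1 + 5 * (1 - mode_t)
  peak <- mode_t^(a - 1) * (1 - mode_t)^(b - 1)
  lambda <- function(h) {
    t <- (h - h_lo) / (h_hi - h_lo)
    out <- numeric(length(h))
    ok <- t >= 0 & t <= 1
    out[ok] <- vigor * t[ok]^(a - 1) * (1 - t[ok])^(b - 1) / peak
    out
  }
  # horizontal patchiness: low-order random Fourier field, normalized to
  # mean 1 so expected contacts at height h remain lambda(h)
  coefs <- with_seed(seed, list(c = stats::rnorm(4L), s = stats::rnorm(4L)))
  raw <- function(x) {
    z <- 0
    for (j in 1:4) {
      z <- z + (coefs$c[j] * cos(2 * pi * j * x) +
                  coefs$s[j] * sin(2 * pi * j * x)) / j
    }
    exp(patchiness * z)
  }
  norm <- mean(raw(seq(0, 1, length.out = 512L)))
  patch <- function(x) raw(x) / norm
  structure(
    list(lambda = lambda, patch = patch, vigor = vigor,
         canopy_height = canopy_height, wire_height = wire_height,
         patchiness = patchiness, peak_band = peak_band,
         h_range = c(h_lo, h_hi), seed = seed),
    class = "virtual_canopy")
}

#' @export
print.virtual_canopy <- function(x, ...) {
  cat(sprintf("<virtual_canopy> vigor %.2f, wall %.0f-%.0f cm (seed %d)\n",
              x$vigor, x$h_range[1], x$h_range[2], x$seed))
  invisible(x)
}

#' Canopy occupancy
#'
#' Probability that a horizontal line of sight at height `h` (and row
#' position `x`) meets at least one leaf: `1 - exp(-lambda(h) * g(x))`,
#' the zero-probability complement of the Poisson contact model. This is
#' simultaneously the expected vegetated pixel fraction at that height and
#' one minus the expected canopy-gap fraction.
#'
#' @param canopy A [make_virtual_canopy()].
#' @param h Height(s), cm above ground.
#' @param x Optional row position(s) in `[0, 1]` for the patchiness field.
#' @return Occupancy value(s) in `[0, 1]`.
#' @export
canopy_occupancy <- function(canopy, h, x = NULL) {
  stopifnot(inherits(canopy, "virtual_canopy"))
  g <- if (is.null(x)) 1 else canopy$patch(x)
  1 - exp(-canopy$lambda(h) * g)
}

#' Render a synthetic side-view canopy frame
#'
#' Vegetation pixels fire where a Bernoulli draw at the pixel's height (and
#' row position) beats the canopy occupancy; they are colored from a green
#' hue/lightness distribution. The remaining pixels come from the sky model
#' (`"clear"` blue, `"overcast"` near-white, or a vertical `"gradient"`).
#' All channel values are scaled by the illumination factor `k` and clamped
#' to `[0, 1]`; ground-truth labels are stored with the scene.
#'
#' @param canopy A [make_virtual_canopy()].
#' @param width,height Frame size in pixels.
#' @param sky Sky model.
#' @param illumination Global brightness factor `k` in `[0.3, 1.8]`.
#' @param seed Integer seed.
#' @param h_range Heights (cm) spanned by the frame, bottom to top; default
#'   the point-quadrat span, wire - 15 cm to wire + 155 cm.
#' @param occupancy Optional occupancy override: a single value in `[0, 1]`
#'   or a function of height, replacing the canopy model (used for
#'   controlled experiments).
#' @return An object of class `synthetic_scene`: `image` ([rgb_image()]),
#'   `labels` (logical matrix, `TRUE` = vegetation), `true_fraction`,
#'   `illumination`, `sky`, `seed`.
#' @export
render_side_view <- function(canopy, width = 96, height = 160,
                             sky = c("clear", "overcast", "gradient"),
                             illumination = 1, seed = 1, h_range = NULL,
                             occupancy = NULL) {
  stopifnot(inherits(canopy, "virtual_canopy"))
  sky <- match.arg(sky)
  if (illumination < 0.3 || illumination > 1.8) {
    stop("illumination k must lie in [0.3, 1.8]", call. = FALSE)
  }
  if (is.null(h_range)) {
    h_range <- c(canopy$wire_height - 15, canopy$wire_height + 155)
  }
  rows_h <- seq(h_range[2L], h_range[1L], length.out = height)  # row 1 = top
  cols_x <- seq(0, 1, length.out = width)
  occ <- if (is.null(occupancy)) {
    (1 - exp(-outer(canopy$lambda(rows_h), canopy$patch(cols_x))))
  } else if (is.function(occupancy)) {
    matrix(occupancy(rows_h), nrow = height, ncol = width)
  } else {
    matrix(occupancy, nrow = height, ncol = width)
  }
  with_seed(seed, {
    labels <- matrix(stats::runif(height * width) < occ, height, width)
    n <- height * width
    hue <- sat <- lig <- numeric(n)
    veg <- as.vector(labels)
    nv <- sum(veg)
    if (nv > 0L) {
      hue[veg] <- stats::rnorm(nv, 110, 12) %% 360
      sat[veg] <- stats::runif(nv, 0.45, 0.75)
      lig[veg] <- stats::runif(nv, 0.18, 0.38)
    }
    ns <- n - nv
    if (ns > 0L) {
      if (sky == "clear") {
        hue[!veg] <- stats::rnorm(ns, 215, 8) %% 360
        sat[!veg] <- stats::runif(ns, 0.5, 0.8)
        lig[!veg] <- stats::runif(ns, 0.78, 0.92)
      } else if (sky == "overcast") {
        hue[!veg] <- stats::runif(ns, 0, 360)
        sat[!veg] <- stats::runif(ns, 0, 0.06)
        lig[!veg] <- stats::runif(ns, 0.82, 0.95)
      } else {
        # vertical gradient: brighter toward the top of the frame
        rowpos <- (row(labels) - 1) / max(height - 1, 1)
        hue[!veg] <- stats::rnorm(ns, 215, 10) %% 360
        sat[!veg] <- stats::runif(ns, 0.25, 0.55)
        lig[!veg] <- 0.92 - 0.25 * as.vector(rowpos)[!veg] +
          stats::runif(ns, -0.02, 0.02)
      }
    }
    rgb <- hsl_to_rgb(hue, sat, lig)
    img <- array(0, dim = c(height, width, 3L))
    img[, , 1L] <- pmin(rgb$r * illumination, 1)
    img[, , 2L] <- pmin(rgb$g * illumination, 1)
    img[, , 3L] <- pmin(rgb$b * illumination, 1)
    structure(
      list(image = rgb_image(img), labels = labels,
           true_fraction = mean(labels), illumination = illumination,
           sky = sky, seed = seed),
      class = "synthetic_scene")
  })
}

#' Simulate point-quadrat insertions from a virtual canopy
#'
#' Per insertion at wire-relative level `l`, the leaf-contact count is drawn
#' from a Poisson with mean `lambda(wire + l) * g(x)` at a random row
#' position `x`, so the expected leaf layer number at a level equals the
#' canopy's leaf density there and the expected gap fraction is
#' `exp(-lambda)`. Cluster contacts are added at rate `cluster_rate` within
#' the fruiting band; token order is randomized.
#'
#' @param canopy A [make_virtual_canopy()].
#' @param levels Wire-relative heights, cm; default the 18 standard levels.
#' @param insertions Insertions per level (>= 1).
#' @param cluster_rate Poisson rate of cluster contacts inside
#'   `cluster_band` (default 0: leaves only).
#' @param cluster_band Wire-relative band (cm) holding the clusters.
#' @param vine_id Identifier stored with the insertions.
#' @param seed Integer seed.
#' @return A [pqa_insertions()] table.
#' @export
simulate_pqa <- function(canopy, levels = pqa_levels(), insertions = 10,
                         cluster_rate = 0, cluster_band = c(5, 35),
                         vine_id = "V1", seed = 1) {
  stopifnot(inherits(canopy, "virtual_canopy"))
  if (insertions < 1) stop("need at least one insertion per level",
                           call. = FALSE)
  with_seed(seed, {
    rows <- lapply(levels, function(l) {
      h <- canopy$wire_height + l
      x <- stats::runif(insertions)
      lam <- canopy$lambda(h) * canopy$patch(x)
      n_leaf <- stats::rpois(insertions, lam)
      in_band <- l >= cluster_band[1L] && l <= cluster_band[2L]
      n_clu <- if (in_band && cluster_rate > 0) {
        stats::rpois(insertions, cluster_rate)
      } else {
        integer(insertions)
      }
      contacts <- vapply(seq_len(insertions), function(i) {
        tok <- c(rep("L", n_leaf[i]), rep("C", n_clu[i]))
        if (length(tok) > 1L) tok <- sample(tok)
        paste(tok, collapse = ";")
      }, character(1L))
      data.frame(vine_id = vine_id, level_cm = l, contacts = contacts,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    pqa_insertions(df$vine_id, df$level_cm, df$contacts)
  })
}

#' Simulate a whole-vineyard survey track
#'
#' Lays out vines on a rectangular row grid, drives the virtual tractor
#' along the rows and emits one stop per vine with left and right sector
#' profiles rendered from that vine's canopy (sector CI = 1000 x mean
#' occupancy over the sector heights plus sensor noise; sector ST = the
#' vegetation/background thermal mixture at the sector's vegetated
#' fraction). Relative humidity and air temperature carry a known linear
#' drift so the de-trending step can be exercised against truth.
#'
#' @param canopies List of [make_virtual_canopy()] objects, one per vine.
#' @param geometry A [sensor_geometry()] defining the sector layout.
#' @param vines_per_row Vines per row (layout bookkeeping).
#' @param row_spacing_m,vine_spacing_m Field layout, meters.
#' @param speed_kmh,frequency_hz Survey metadata.
#' @param origin_lonlat WGS84 origin of the field (lon, lat).
#' @param t_vegetation True canopy surface temperature, degrees C.
#' @param bg A [background_model()] for the sky contribution.
#' @param rh0,at0 Relative humidity (%) and air temperature (C) at start.
#' @param rh_drift,at_drift Linear drifts per minute.
#' @param ci_noise_sd,st_noise_sd Sensor noise (CI units / degrees C).
#' @param seed Integer seed.
#' @return A [survey_track()] with `2 * length(canopies)` stop records and a
#'   `"truth"` attribute (per-vine vigor and true mean occupancy).
#' @export
simulate_survey <- function(canopies, geometry = sensor_geometry(),
                            vines_per_row = 4L, row_spacing_m = 2.5,
                            vine_spacing_m = 2, speed_kmh = 5,
                            frequency_hz = 3,
                            origin_lonlat = c(9.6, 45.1),
                            t_vegetation = 22, bg = background_model(),
                            rh0 = 65, at0 = 24, rh_drift = 0.5,
                            at_drift = 0.05, ci_noise_sd = 12,
                            st_noise_sd = 0.3, seed = 1) {
  stopifnot(length(canopies) >= 1L,
            all(vapply(canopies, inherits, TRUE, "virtual_canopy")))
  layout <- build_sector_layout(geometry)
  n <- length(canopies)
  m_per_deg_lat <- 111320
  with_seed(seed, {
    rows_list <- list()
    t_now <- 0
    prev_xy <- c(0, 0)
    for (v in seq_len(n)) {
      row_i <- (v - 1L) %/% vines_per_row
      col_i <- (v - 1L) %% vines_per_row
      x_m <- col_i * vine_spacing_m
      y_m <- row_i * row_spacing_m
      t_now <- t_now + sqrt(sum((c(x_m, y_m) - prev_xy)^2)) /
        (speed_kmh * 1000 / 3600)
      prev_xy <- c(x_m, y_m)
      can <- canopies[[v]]
      lat <- origin_lonlat[2L] + y_m / m_per_deg_lat
      lon <- origin_lonlat[1L] +
        x_m / (m_per_deg_lat * cos(origin_lonlat[2L] * pi / 180))
      for (side in c("left", "right")) {
        x_face <- stats::runif(1L)  # row position the sensor faces
        ci <- vapply(seq_len(15L), function(s) {
          hs <- seq(layout$ci_bounds[s], layout$ci_bounds[s + 1L],
                    length.out = 7L)
          occ <- mean(canopy_occupancy(can, hs, x_face))
          min(max(1000 * occ + stats::rnorm(1L, 0, ci_noise_sd), 0), 1000)
        }, numeric(1L))
        st <- vapply(seq_len(16L), function(s) {
          hs <- seq(layout$st_bounds[s], layout$st_bounds[s + 1L],
                    length.out = 7L)
          f_v <- mean(canopy_occupancy(can, hs, x_face))
          st_mixture(t_vegetation, bg$t_background, f_v) +
            stats::rnorm(1L, 0, st_noise_sd)
        }, numeric(1L))
        minutes <- t_now / 60
        rec <- data.frame(
          timestamp = t_now, lat = lat, lon = lon, side = side,
          vine_id = sprintf("V%02d", v),
          rh = rh0 + rh_drift * minutes + stats::rnorm(1L, 0, 0.6),
          at = at0 + at_drift * minutes + stats::rnorm(1L, 0, 0.15),
          us = row_spacing_m * 100 / 2 - 15 + stats::rnorm(1L, 0, 2),
          n_satellites = sample(8:14, 1L),
          stringsAsFactors = FALSE)
        rec[paste0("ci_s", 1:15)] <- as.list(ci)
        rec[paste0("st_s", 1:16)] <- as.list(st)
        rows_list[[length(rows_list) + 1L]] <- rec
        t_now <- t_now + 1 / frequency_hz
      }
    }
    df <- do.call(rbind, rows_list)
    out <- survey_track(df, frequency_hz = frequency_hz,
                        speed_kmh = speed_kmh)
    attr(out, "truth") <- data.frame(
      vine_id = sprintf("V%02d", seq_len(n)),
      vigor = vapply(canopies, `[[`, numeric(1L), "vigor"),
      mean_occupancy = vapply(canopies, function(can) {
        hs <- seq(can$h_range[1L], can$h_range[2L], length.out = 64L)
        mean(canopy_occupancy(can, hs))
      }, numeric(1L)))
    out
  })
}

#' Simulate a multi-date synthetic vineyard
#'
#' Draws a per-vine final vigor and applies a saturating seasonal growth
#' curve (rapid early growth, peak around canopy closure, then stable) plus
#' date-specific canopy heights, mirroring a season of five survey dates.
#'
#' @param n_vines Number of vines (default 24).
#' @param n_dates Number of measuring dates (default 5).
#' @param vigor_range Range of the per-vine final peak leaf density.
#' @param seed Integer seed.
#' @return List with `canopies` (list of `n_dates` lists of `n_vines`
#'   canopies), `vigor` (per-vine final vigor) and `growth` (per-date
#'   multipliers).
#' @export
simulate_vineyard <- function(n_vines = 24L, n_dates = 5L,
                              vigor_range = c(0.6, 3.2), seed = 1) {
  growth_full <- c(0.35, 0.6, 0.9, 1, 1)
  height_full <- c(160, 175, 220, 190, 190)  # trimming lowers the top late
  growth <- growth_full[pmin(seq_len(n_dates), 5L)]
  heights <- height_full[pmin(seq_len(n_dates), 5L)]
  vigor <- with_seed(seed, stats::runif(n_vines, vigor_range[1L],
                                        vigor_range[2L]))
  canopies <- lapply(seq_len(n_dates), function(d) {
    lapply(seq_len(n_vines), function(v) {
      make_virtual_canopy(vigor = vigor[v] * growth[d],
                          canopy_height = heights[d],
                          seed = derive_seed(seed, v * 100L + d))
    })
  })
  list(canopies = canopies, vigor = vigor, growth = growth)
}

#' End-to-end synthetic calibration dataset
#'
#' For every vine and date: renders a left and a right side-view frame from
#' the vine's canopy, segments them with the full vegetation-segmentation
#' chain, averages the two sides into the image-derived CI, and runs the
#' simulated point-quadrat protocol on the same canopy. The result is the
#' merged table a field calibration would produce, with the generator truth
#' alongside.
#'
#' @param n_vines,n_dates Vineyard size (defaults 24 vines, 5 dates).
#' @param insertions_per_level Point-quadrat insertions per level.
#' @param width,height Rendered frame size in pixels.
#' @param cluster_rate Cluster-contact rate in the fruiting band.
#' @param seed Integer seed.
#' @return Data frame with one row per vine x date: `vine_id`, `date`,
#'   `ci` (image-derived, sides averaged), `cg_pct`, `lln`, `il_pct`,
#'   `true_fraction` (mean rendered vegetation fraction).
#' @export
simulate_calibration_dataset <- function(n_vines = 24L, n_dates = 5L,
                                         insertions_per_level = 6L,
                                         width = 72L, height = 120L,
                                         cluster_rate = 0.08, seed = 1) {
  vy <- simulate_vineyard(n_vines = n_vines, n_dates = n_dates, seed = seed)
  rows <- list()
  for (d in seq_len(n_dates)) {
    for (v in seq_len(n_vines)) {
      can <- vy$canopies[[d]][[v]]
      ci_sides <- numeric(2L)
      tf <- numeric(2L)
      for (k in 1:2) {
        scene <- render_side_view(can, width = width, height = height,
                                  seed = derive_seed(seed,
                                                     v * 1000L + d * 10L + k))
        mask <- segment_vegetation(scene$image)
        ci_sides[k] <- canopy_index(mask)
        tf[k] <- scene$true_fraction
      }
      ins <- simulate_pqa(can, insertions = insertions_per_level,
                          cluster_rate = cluster_rate,
                          vine_id = sprintf("V%02d", v),
                          seed = derive_seed(seed, v * 1000L + d * 10L + 7L))
      met <- pqa_metrics(ins, by = "overall")
      rows[[length(rows) + 1L]] <- data.frame(
        vine_id = sprintf("V%02d", v), date = d,
        ci = average_sides(ci_sides[1L], ci_sides[2L]),
        cg_pct = met$cg_pct, lln = met$lln, il_pct = met$il_pct,
        true_fraction = mean(tf), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
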