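#' Per-pixel color feature planes
#'
#' Computes Hue, Saturation and Lightness for every pixel of a side-view
#' canopy frame and keeps the normalized R, G, B fractions alongside. Hue is
#' in degrees `[0, 360)` with the achromatic sentinel `H = 0` when `S = 0`.
#'
#' @param image An [rgb_image()] (or anything coercible by `rgb_image()`).
#' @return An object of class `feature_planes`: a list of six matrices
#'   (`r`, `g`, `b`, `h`, `s`, `l`) sharing the image dimensions.
#' @examples
#' f <- compute_features(rgb_image(array(c(1, 0, 0), dim = c(1, 1, 3))))
#' f$h[1, 1]  # pure red -> 0 degrees
#' @export
compute_features <- function(image) {
  image <- rgb_image(image)
  d <- dim(image)
  r <- image[, , 1L]
  g <- image[, , 2L]
  b <- image[, , 3L]
  hsl <- rgb_to_hsl(as.vector(r), as.vector(g), as.vector(b))
  reshape <- function(v) matrix(v, nrow = d[1L], ncol = d[2L])
  structure(
    list(r = reshape(as.vector(r)), g = reshape(as.vector(g)),
         b = reshape(as.vector(b)), h = reshape(hsl$h),
         s = reshape(hsl$s), l = reshape(hsl$l)),
    class = "feature_planes")
}

#' Feature projection weights
#'
#' Weights of the linear combination that compresses the six per-pixel color
#' features (R, G, B, H, S, L) onto one scalar axis before thresholding. In
#' `"auto"` mode the weights are recomputed per image as the leading
#' principal axis of the standardized feature matrix.
#'
#' @param wr,wg,wb,wh,ws,wl Real coefficients; not all zero in fixed mode.
#' @param mode `"fixed"` or `"auto"` (per-image principal axis).
#' @return An object of class `feature_weights`.
#' @export
feature_weights <- function(wr = 0, wg = 0, wb = 0, wh = 0, ws = 0, wl = 0,
                            mode = c("fixed", "auto")) {
  mode <- match.arg(mode)
  w <- c(r = wr, g = wg, b = wb, h = wh, s = ws, l = wl)
  if (anyNA(w) || !is.numeric(w)) stop("weights must be numbers", call. = FALSE)
  if (mode == "fixed" && all(w == 0)) {
    stop("all-zero weights are not a valid projection", call. = FALSE)
  }
  structure(list(w = w, mode = mode), class = "feature_weights")
}

# Assemble the n x 6 standardized feature matrix. Hue is mapped to [0, 1]
# via h/360 before standardization (vegetation and sky hues do not straddle
# the circular wrap point in side-view frames).
feature_matrix <- function(features) {
  stopifnot(inherits(features, "feature_planes"))
  m <- cbind(r = as.vector(features$r), g = as.vector(features$g),
             b = as.vector(features$b), h = as.vector(features$h) / 360,
             s = as.vector(features$s), l = as.vector(features$l))
  standardize_columns(m)
}

#' Project color features onto a single scalar plane
#'
#' Standardizes each of the six features to zero mean / unit variance within
#' the image, then forms the weighted sum. In auto mode the weight vector is
#' the leading principal axis of the standardized feature matrix,
#' sign-oriented so that the lower-Lightness pixel class (foliage, not sky)
#' scores higher.
#'
#' @param features A [compute_features()] result.
#' @param weights A [feature_weights()] object; default auto mode.
#' @return A numeric matrix with the image dimensions; attribute
#'   `"weights"` carries the weight vector actually used.
#' @export
project_to_scalar <- function(features, weights = feature_weights(mode = "auto")) {
  stopifnot(inherits(features, "feature_planes"),
            inherits(weights, "feature_weights"))
  z <- feature_matrix(features)
  sds <- attr(z, "feature_sd")
  if (weights$mode == "auto") {
    if (all(sds == 0)) {
      stop("constant image: principal axis undefined in auto mode",
           call. = FALSE)
    }
    n <- nrow(z)
    cov6 <- crossprod(z) / max(n - 1, 1)
    w <- eigen(cov6, symmetric = TRUE)$vectors[, 1L]
    names(w) <- colnames(z)
    s <- as.vector(z %*% w)
    # Orient: lower Lightness scores higher; hue distance to green (120 deg)
    # breaks a Lightness tie.
    ref <- z[, "l"]
    cv <- sum(s * ref)
    if (cv == 0) {
      ref <- abs(as.vector(features$h) - 120)
      ref <- ref - mean(ref)
      cv <- sum(s * ref)
    }
    if (cv > 0) {
      w <- -w
      s <- -s
    }
  } else {
    w <- weights$w
    s <- as.vector(z %*% w)
  }
  out <- matrix(s, nrow = nrow(features$l), ncol = ncol(features$l))
  attr(out, "weights") <- w
  out
}

#' Two-class Jenks natural-breaks partition
#'
#' Partitions a set of real values into a low and a high class by the
#' contiguous split of the sorted values that minimizes the total
#' within-class sum of squared deviations from the class means (the
#' two-class special case of Jenks natural breaks). Ties are broken toward
#' the smaller low class.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return A list of class `jenks_break` with `split_index` (size of the low
#'   class in sorted order), `threshold` (largest value of the low class),
#'   `classes` (factor `"low"`/`"high"` aligned with `values`), and `ssd`
#'   (the minimized within-class sum of squared deviations).
#' @examples
#' jenks_two_class(c(1, 2, 8, 9))$ssd  # 1.0
#' @export
jenks_two_class <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  ord <- order(values)
  v <- values[ord]
  if (v[1L] == v[n]) {
    stop("degenerate input: all values identical (single class)",
         call. = FALSE)
  }
  c1 <- cumsum(v)
  c2 <- cumsum(v * v)
  k <- seq_len(n - 1L)
  ssd_low <- c2[k] - c1[k]^2 / k
  ssd_high <- (c2[n] - c2[k]) - (c1[n] - c1[k])^2 / (n - k)
  total <- ssd_low + ssd_high
  kstar <- which.min(total)  # first minimum -> smaller low class on ties
  classes <- factor(rep("high", n), levels = c("low", "high"))
  classes[ord[seq_len(kstar)]] <- "low"
  structure(
    list(split_index = kstar, threshold = v[kstar],
         classes = classes, ssd = total[kstar]),
    class = "jenks_break")
}

#' Segment a canopy frame into vegetation and background
#'
#' Full segmentation chain: HSL feature computation, projection onto one
#' scalar axis, two-class Jenks thresholding, then orientation of the two
#' classes: the class with the lower mean Lightness is labeled VEGETATION
#' (the camera points upward so the background is sky only); a Lightness tie
#' is broken toward the class whose mean hue is closer to green (120
#' degrees). Frames whose projected values collapse to a single class are
#' resolved by a sky-lightness floor: all-OTHER when the mean Lightness is
#' at or above `sky_lightness_floor`, otherwise all-VEGETATION.
#'
#' @param image An [rgb_image()] or coercible object.
#' @param weights A [feature_weights()]; the default recomputes the
#'   projection axis per image (auto mode).
#' @param sky_lightness_floor Mean-Lightness threshold used only for
#'   degenerate single-class frames (default 0.75).
#' @param min_separation Minimum goodness-of-variance fit
#'   (`1 - SSD_within / SSD_total`) of the two-class break for the frame to
#'   count as genuinely two-class. Splitting unimodal color noise cannot
#'   exceed about 0.75 (the uniform-distribution ceiling), while real
#'   vegetation/sky mixtures reach 0.9+, so the default 0.8 routes saturated
#'   (all-sky or all-canopy) frames to the single-class rule.
#' @return An object of class `vegetation_mask`: list with `labels` (logical
#'   matrix, `TRUE` = vegetation), `n_vegetation`, `n_total`, `threshold`,
#'   `weights` and `degenerate`.
#' @export
segment_vegetation <- function(image,
                               weights = feature_weights(mode = "auto"),
                               sky_lightness_floor = 0.75,
                               min_separation = 0.8) {
  image <- rgb_image(image)
  features <- compute_features(image)
  degenerate_mask <- function() {
    all_sky <- mean(features$l) >= sky_lightness_floor
    message("degenerate single-class frame: labeled all-",
            if (all_sky) "OTHER (sky)" else "VEGETATION",
            " by the sky-lightness floor rule")
    labels <- matrix(!all_sky, nrow(features$l), ncol(features$l))
    structure(list(labels = labels,
                   n_vegetation = sum(labels),
                   n_total = length(labels),
                   threshold = NA_real_, weights = NULL, degenerate = TRUE),
              class = "vegetation_mask")
  }
  z <- feature_matrix(features)
  if (all(attr(z, "feature_sd") == 0)) return(degenerate_mask())
  scalar <- project_to_scalar(features, weights)
  v <- as.vector(scalar)
  if (max(v) == min(v)) return(degenerate_mask())
  jb <- jenks_two_class(v)
  gvf <- 1 - jb$ssd / sum((v - mean(v))^2)
  if (gvf < min_separation) return(degenerate_mask())
  low <- jb$classes == "low"
  l <- as.vector(features$l)
  mean_l <- c(low = mean(l[low]), high = mean(l[!low]))
  if (mean_l["low"] != mean_l["high"]) {
    veg_is_low <- mean_l["low"] < mean_l["high"]
  } else {
    hdist <- abs(as.vector(features$h) - 120)
    veg_is_low <- mean(hdist[low]) <= mean(hdist[!low])
  }
  veg <- if (veg_is_low) low else !low
  labels <- matrix(veg, nrow = nrow(features$l), ncol = ncol(features$l))
  structure(
    list(labels = labels, n_vegetation = sum(labels), n_total = length(labels),
         threshold = jb$threshold, weights = attr(scalar, "weights"),
         degenerate = FALSE),
    class = "vegetation_mask")
}

#' @export
print.vegetation_mask <- function(x, ...) {
  cat(sprintf("<vegetation_mask> %d / %d vegetation pixels (CI = %.1f)\n",
              x$n_vegetation, x$n_total, canopy_index(x)))
  invisible(x)
}

#' Canopy Index of a vegetation mask
#'
#' `CI = 1000 * n_vegetation / n_total`, a pure number on the 0-1000 scale
#' (1000 = fully vegetated frame).
#'
#' @param mask A [segment_vegetation()] result, or a list with
#'   `n_vegetation` and `n_total` counts.
#' @return Numeric CI in `[0, 1000]`.
#' @export
canopy_index <- function(mask) {
  n_veg <- mask$n_vegetation
  n_tot <- mask$n_total
  stop_if_not_scalar_number(n_veg, "n_vegetation")
  stop_if_not_scalar_number(n_tot, "n_total")
  if (n_tot <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_veg < 0 || n_veg > n_tot) {
    stop("n_vegetation must lie in [0, n_total]", call. = FALSE)
  }
  1000 * n_veg / n_tot
}

#' Average the left and right Canopy Index of one location
#'
#' The total CI of a sampling location is the arithmetic mean of the left
#' and right row-side contributions. If exactly one side was filtered out
#' (`NA`), the surviving side is returned with attribute
#' `single_side = TRUE`.
#'
#' @param ci_left,ci_right CI values in `[0, 1000]`; `NA` marks a filtered
#'   side.
#' @return Numeric CI; attribute `single_side` is `TRUE` when only one side
#'   contributed.
#' @export
average_sides <- function(ci_left, ci_right) {
  sides <- c(ci_left, ci_right)
  if (length(sides) != 2L) stop("provide one value per side", call. = FALSE)
  ok <- !is.na(sides)
  if (!any(ok)) stop("both sides missing: no CI available", call. = FALSE)
  bad <- sides[ok] < 0 | sides[ok] > 1000
  if (any(bad)) stop("CI values must lie in [0, 1000]", call. = FALSE)
  out <- mean(sides[ok])
  attr(out, "single_side") <- sum(ok) == 1L
  out
}
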