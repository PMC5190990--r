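#' Create an RGB image object
#'
#' An `rgb_image` is a `height x width x 3` numeric array with channel values
#' in `[0, 1]`. Integer inputs in `[0, 255]` (the raw sensor convention) are
#' rescaled by 1/255. Reading from file supports 8-bit RGB PNG and JPEG.
#'
#' @param x A numeric array (`h x w x 3`, values in `[0, 1]` or integers in
#'   `[0, 255]`), a matrix (interpreted as grayscale and replicated across
#'   channels), or a path to a PNG/JPEG file.
#' @return An object of class `rgb_image`.
#' @examples
#' img <- rgb_image(array(c(255, 0, 0), dim = c(1, 1, 3)))
#' dim(img)
#' @export
rgb_image <- function(x) {
  if (is.character(x)) {
    return(read_rgb_image(x))
  }
  if (is.matrix(x)) {
    x <- array(rep(x, 3L), dim = c(nrow(x), ncol(x), 3L))
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("image must be a height x width x 3 array", call. = FALSE)
  }
  if (dim(x)[3L] == 4L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(x)[3L] != 3L) {
    stop("image must have 3 channels (R, G, B)", call. = FALSE)
  }
  if (dim(x)[1L] < 1L || dim(x)[2L] < 1L) {
    stop("degenerate input: image has zero pixels", call. = FALSE)
  }
  if (anyNA(x)) stop("image contains missing channel values", call. = FALSE)
  if (max(x) > 1) x <- x / 255
  if (min(x) < 0 || max(x) > 1) {
    stop("channel values must lie in [0, 255] (or [0, 1] as fractions)",
         call. = FALSE)
  }
  structure(x, class = "rgb_image")
}

#' Read an 8-bit RGB image from PNG or JPEG
#'
#' @param path File path ending in `.png`, `.jpg` or `.jpeg`.
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' (PNG and JPEG only)",
         call. = FALSE)
  )
  rgb_image(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 channels in [0, 1]\n", d[2], d[1]))
  invisible(x)
}

# Per-pixel RGB -> HSL, vectorized over flattened channels in [0, 1].
# H in degrees [0, 360) with achromatic sentinel 0; S, L fractions in [0, 1].
rgb_to_hsl <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  chrom <- d > 0
  s <- numeric(length(r))
  s[chrom] <- d[chrom] / (1 - abs(2 * l[chrom] - 1))
  h <- numeric(length(r))
  if (any(chrom)) {
    hr <- chrom & mx == r
    hg <- chrom & !hr & mx == g
    hb <- chrom & !hr & !hg
    h[hr] <- ((g[hr] - b[hr]) / d[hr]) %% 6
    h[hg] <- (b[hg] - r[hg]) / d[hg] + 2
    h[hb] <- (r[hb] - g[hb]) / d[hb] + 4
    h <- h * 60
  }
  list(h = h, s = s, l = l)
}

# HSL -> RGB in [0, 1]; used by the synthetic renderer.
hsl_to_rgb <- function(h, s, l) {
  h <- h %% 360
  c <- (1 - abs(2 * l - 1)) * s
  x <- c * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c / 2
  sextant <- floor(h / 60) %% 6
  r <- g <- b <- numeric(length(h))
  idx <- function(k) sextant == k
  r[idx(0)] <- c[idx(0)]; g[idx(0)] <- x[idx(0)]
  r[idx(1)] <- x[idx(1)]; g[idx(1)] <- c[idx(1)]
  g[idx(2)] <- c[idx(2)]; b[idx(2)] <- x[idx(2)]
  g[idx(3)] <- x[idx(3)]; b[idx(3)] <- c[idx(3)]
  r[idx(4)] <- x[idx(4)]; b[idx(4)] <- c[idx(4)]
  r[idx(5)] <- c[idx(5)]; b[idx(5)] <- x[idx(5)]
  list(r = pmin(pmax(r + m, 0), 1),
       g = pmin(pmax(g + m, 0), 1),
       b = pmin(pmax(b + m, 0), 1))
}

#' Write a vegetation mask to PNG with a JSON sidecar
#'
#' The mask is written as an 8-bit grayscale PNG (vegetation = 255,
#' other = 0). A JSON sidecar (`<path>.json`) records pixel counts, the
#' Canopy Index, the projection weights and the Jenks threshold used.
#'
#' @param mask A [segment_vegetation()] result.
#' @param path Output PNG path.
#' @return Invisibly, the sidecar path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "vegetation_mask"))
  png::writePNG(ifelse(mask$labels, 1, 0), target = path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(n_vegetation = mask$n_vegetation,
         n_total = mask$n_total,
         ci = canopy_index(mask),
         weights = mask$weights,
         threshold = mask$threshold,
         degenerate = mask$degenerate),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}
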