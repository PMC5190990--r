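test_that("HSL feature planes reproduce the standard transform identities", {
  px <- function(r, g, b) {
    f <- compute_features(rgb_image(array(c(r, g, b), dim = c(1, 1, 3))))
    c(h = f$h[1, 1], s = f$s[1, 1], l = f$l[1, 1])
  }
  red <- px(255, 0, 0)
  expect_equal(unname(red), c(0, 1, 0.5))
  green <- px(0, 255, 0)
  expect_equal(unname(green), c(120, 1, 0.5))
  gray <- px(128, 128, 128)
  expect_equal(unname(gray[c("s", "h")]), c(0, 0))  # achromatic sentinel
  expect_equal(unname(gray["l"]), 128 / 255, tolerance = 1e-12)

  expect_error(compute_features(array(1, dim = c(0, 4, 3))), "zero pixels")
  expect_error(rgb_image(array(300, dim = c(2, 2, 3))), "channel values")
})

test_that("scalar projection selects, combines and auto-orients features", {
  frame <- two_color_frame()
  f <- compute_features(frame)

  # single-feature selection: weight on L only reproduces standardized L
  s <- project_to_scalar(f, feature_weights(wl = 1))
  lz <- (f$l - mean(f$l)) / sd(f$l)
  expect_equal(as.vector(s), as.vector(lz), tolerance = 1e-12)

  # constant image with fixed weights -> constant plane
  cf <- compute_features(constant_frame(c(0.3, 0.5, 0.2)))
  sc <- project_to_scalar(cf, feature_weights(wr = 1, wl = 2))
  expect_equal(diff(range(sc)), 0)

  # two-color auto mode: exactly two scalar values, green class higher
  sa <- project_to_scalar(f)
  vals <- sort(unique(round(as.vector(sa), 10)))
  expect_length(vals, 2L)
  green_mask <- f$g > f$b  # canopy pixels are the greener class
  expect_true(all(sa[green_mask] > sa[!green_mask]))

  expect_error(feature_weights(), "all-zero")
  expect_error(project_to_scalar(cf), "principal axis undefined")
})

test_that("two-class Jenks break minimizes within-class SSD", {
  jb <- jenks_two_class(c(0, 10, 0, 10))
  expect_equal(jb$split_index, 2L)
  expect_equal(jb$ssd, 0)
  expect_equal(as.character(jb$classes), c("low", "high", "low", "high"))

  # brute force over the 3 splits of {1,2,8,9}: SSDs 28.67, 1.0, 28.67
  jb2 <- jenks_two_class(c(1, 2, 8, 9))
  expect_equal(jb2$split_index, 2L)
  expect_equal(jb2$ssd, 1.0)
  expect_equal(jb2$threshold, 2)

  expect_error(jenks_two_class(rep(3, 5)), "identical")
  expect_error(jenks_two_class(7), "at least 2")
})

test_that("Jenks equals the exhaustive-split oracle and is affine invariant", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:500, 1L)
    v <- if (rep %% 2 == 0) {
      c(rnorm(ceiling(n / 2), 0, 1), rnorm(floor(n / 2), 8, 1))
    } else {
      runif(n, 0, 100)
    }
    if (length(unique(v)) < 2L) next
    got <- jenks_two_class(v)
    want <- jenks_oracle(v)
    expect_equal(got$split_index, want$split_index)
    expect_equal(got$ssd, want$ssd, tolerance = 1e-8)

    # positive affine transform preserves the partition
    got2 <- jenks_two_class(2.5 * v + 7)
    expect_identical(got2$classes, got$classes)
  }
})

test_that("segmentation recovers ground truth and handles degenerate frames", {
  can <- make_virtual_canopy(vigor = 2, seed = 11)
  scene <- render_side_view(can, seed = 12)
  mask <- segment_vegetation(scene$image)
  expect_gte(mean(mask$labels == scene$labels), 0.99)

  # brightness-scaled frame: same mask on >= 98% of pixels
  dim_scene <- render_side_view(can, seed = 12, illumination = 0.7)
  dim_mask <- segment_vegetation(dim_scene$image)
  expect_gte(mean(dim_mask$labels == mask$labels), 0.98)

  # all-sky frame -> all OTHER; all-vegetation frame -> all VEGETATION
  sky <- suppressMessages(segment_vegetation(constant_frame(c(0.7, 0.8, 0.95))))
  expect_equal(sky$n_vegetation, 0L)
  expect_true(sky$degenerate)
  leafy <- suppressMessages(segment_vegetation(constant_frame(c(0.1, 0.4, 0.1))))
  expect_equal(leafy$n_vegetation, leafy$n_total)
})

test_that("canopy index scales counts to the 0-1000 range", {
  full <- list(n_vegetation = 64, n_total = 64)
  expect_equal(canopy_index(full), 1000)
  expect_equal(canopy_index(list(n_vegetation = 0, n_total = 64)), 0)
  expect_equal(canopy_index(list(n_vegetation = 250, n_total = 1000)), 250)
  expect_error(canopy_index(list(n_vegetation = 0, n_total = 0)), "positive")
  expect_error(canopy_index(list(n_vegetation = 9, n_total = 4)), "n_total")

  # union of two disjoint equal-size frames = mean of their CIs
  a <- list(n_vegetation = 30, n_total = 100)
  b <- list(n_vegetation = 70, n_total = 100)
  u <- list(n_vegetation = 100, n_total = 200)
  expect_equal(canopy_index(u), mean(c(canopy_index(a), canopy_index(b))))
})

test_that("left/right averaging honors the single-side filtering contract", {
  expect_equal(as.numeric(average_sides(400, 600)), 500)
  expect_equal(as.numeric(average_sides(0, 0)), 0)
  one <- average_sides(300, NA)
  expect_equal(as.numeric(one), 300)
  expect_true(attr(one, "single_side"))
  expect_false(attr(average_sides(300, 500), "single_side"))
  expect_error(average_sides(NA, NA), "both sides missing")
  expect_error(average_sides(1200, 100), "\\[0, 1000\\]")
})

test_that("mask PNG + sidecar round-trip preserves counts", {
  scene <- render_side_view(make_virtual_canopy(seed = 1), width = 32,
                            height = 32, seed = 2)
  mask <- segment_vegetation(scene$image)
  path <- file.path(tempdir(), "mask.png")
  sidecar <- write_mask_png(mask, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  expect_equal(meta$n_vegetation, mask$n_vegetation)
  expect_equal(meta$ci, canopy_index(mask))
  back <- png::readPNG(path)
  expect_equal(sum(back > 0.5), mask$n_vegetation)
})
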