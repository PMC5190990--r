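test_that("virtual canopies are deterministic with a basal density peak", {
  can <- make_virtual_canopy(vigor = 2.4, seed = 99)
  can2 <- make_virtual_canopy(vigor = 2.4, seed = 99)
  h <- seq(40, 170, by = 1)
  x <- seq(0, 1, by = 0.01)
  expect_identical(can$lambda(h), can2$lambda(h))
  expect_identical(can$patch(x), can2$patch(x))

  # density peak inside the configured basal band above the wire
  peak_h <- h[which.max(can$lambda(h))]
  expect_gte(peak_h, can$wire_height + can$peak_band[1])
  expect_lte(peak_h, can$wire_height + can$peak_band[2])
  expect_equal(max(can$lambda(h)), can$vigor, tolerance = 1e-3)
  expect_true(all(can$lambda(h) >= 0))
  # patchiness field has mean ~ 1 so expected contacts stay lambda(h)
  expect_equal(mean(can$patch(seq(0, 1, length.out = 512))), 1,
               tolerance = 1e-9)

  bare <- make_virtual_canopy(vigor = 0, seed = 1)
  expect_true(all(bare$lambda(h) == 0))
  expect_error(make_virtual_canopy(vigor = -1), "negative")
})

test_that("rendered scenes carry exact ground truth at occupancy extremes", {
  can <- make_virtual_canopy(seed = 4)
  sat <- render_side_view(can, width = 48, height = 64, occupancy = 1,
                          seed = 5)
  expect_equal(sat$true_fraction, 1)
  expect_equal(canopy_index(suppressMessages(segment_vegetation(sat$image))),
               1000)
  empty <- render_side_view(can, width = 48, height = 64, occupancy = 0,
                            seed = 5)
  expect_equal(empty$true_fraction, 0)
  expect_equal(canopy_index(suppressMessages(segment_vegetation(empty$image))),
               0)

  half <- render_side_view(can, width = 128, height = 128, occupancy = 0.5,
                           seed = 6)
  ci <- canopy_index(segment_vegetation(half$image))
  expect_lte(abs(ci / 1000 - half$true_fraction), 0.02)

  # determinism and error handling
  again <- render_side_view(can, width = 48, height = 64, seed = 5)
  expect_identical(unclass(render_side_view(can, width = 48, height = 64,
                                            seed = 5)$image),
                   unclass(again$image))
  expect_error(render_side_view(can, illumination = 2.5), "\\[0.3, 1.8\\]")
})

test_that("sky models stay separable from foliage for the segmenter", {
  can <- make_virtual_canopy(vigor = 2, seed = 31)
  for (sky in c("clear", "overcast", "gradient")) {
    scene <- render_side_view(can, width = 64, height = 96, sky = sky,
                              seed = 32)
    mask <- segment_vegetation(scene$image)
    expect_gte(mean(mask$labels == scene$labels), 0.98)
  }
})

test_that("simulated insertions follow the Poisson contact model", {
  bare <- make_virtual_canopy(vigor = 0, seed = 2)
  ins0 <- simulate_pqa(bare, insertions = 20, seed = 3)
  m0 <- pqa_metrics(ins0)
  expect_equal(m0$cg_pct, 100)
  expect_equal(m0$lln, 0)

  # flat-field check at the density peak: LLN ~ lambda, %CG ~ 100 exp(-lambda)
  can <- make_virtual_canopy(vigor = 2, patchiness = 0,
                             peak_band = c(25, 25), seed = 2)
  ins <- simulate_pqa(can, levels = 25, insertions = 2000, seed = 4)
  m <- pqa_metrics(ins)
  expect_equal(m$lln, 2, tolerance = 0.06)          # ~ 2 +- 3 sigma
  expect_lte(abs(m$cg_pct - 100 * exp(-2)), 2.5)

  # determinism
  expect_identical(as.data.frame(simulate_pqa(can, insertions = 5, seed = 9)),
                   as.data.frame(simulate_pqa(can, insertions = 5, seed = 9)))

  # clusters appear only inside the fruiting band and leave LLN leaf-only
  insc <- simulate_pqa(can, insertions = 400, cluster_rate = 0.5,
                       cluster_band = c(5, 35), seed = 7)
  has_cluster <- grepl("C", insc$contacts)
  expect_true(any(has_cluster))
  expect_true(all(insc$level_cm[has_cluster] >= 5 &
                    insc$level_cm[has_cluster] <= 35))
})

test_that("simulated surveys expose layout bookkeeping and known drifts", {
  canopies <- lapply(1:8, function(i) {
    make_virtual_canopy(vigor = 0.4 + 0.35 * i, seed = 40 + i)
  })
  track <- simulate_survey(canopies, vines_per_row = 4, rh_drift = 0.5,
                           seed = 44)
  expect_equal(nrow(track), 16L)  # 8 stops x 2 sides
  expect_equal(as.integer(table(track$side)), c(8L, 8L))
  expect_false(is.unsorted(track$timestamp))
  expect_true(all(track$ci_s1 >= 0 & track$ci_s1 <= 1000))

  # injected RH drift is removed by de-trending
  dt <- detrend_microclimate(track$rh, track$timestamp)
  residual <- ols_oracle(track$timestamp, dt)
  expect_lt(abs(residual["slope"]), 1e-6)

  # truth bookkeeping rides along
  truth <- attr(track, "truth")
  expect_equal(nrow(truth), 8L)
  expect_true(all(diff(truth$vigor) > 0))

  # high-vigor half maps to a higher CI raster mean than the low half
  lowhi <- c(lapply(1:6, function(i) make_virtual_canopy(0.5, seed = i)),
             lapply(1:6, function(i) make_virtual_canopy(3, seed = 50 + i)))
  tr2 <- simulate_survey(lowhi, vines_per_row = 3, seed = 45)
  outdir <- file.path(tempdir(), "halves")
  p <- export_maps(tr2, outdir, params = "CI", cell = 2)
  asc <- readLines(p[["CI"]])
  vals <- matrix(scan(text = asc[-(1:6)], quiet = TRUE),
                 nrow = length(asc) - 6, byrow = TRUE)
  vals[vals == -9999] <- NA
  # rows 1-2 of the layout are low vigor (south), rows 3-4 high (north);
  # raster row 1 is northernmost
  n <- nrow(vals)
  north_mean <- mean(vals[seq_len(n %/% 2), ], na.rm = TRUE)
  south_mean <- mean(vals[(n %/% 2 + 1):n, ], na.rm = TRUE)
  expect_gt(north_mean, south_mean)
})

test_that("the vineyard generator couples CI and ground truth over dates", {
  vy <- simulate_vineyard(n_vines = 4, n_dates = 3, seed = 5)
  expect_length(vy$canopies, 3L)
  expect_length(vy$canopies[[1]], 4L)
  # growth curve: canopy densifies over the early season
  v1 <- vapply(vy$canopies, function(d) d[[2]]$vigor, numeric(1))
  expect_true(all(diff(v1) > 0))

  d <- simulate_calibration_dataset(n_vines = 5, n_dates = 2,
                                    insertions_per_level = 4,
                                    width = 48, height = 80, seed = 6)
  expect_equal(nrow(d), 10L)
  expect_true(all(d$ci >= 0 & d$ci <= 1000))
  expect_true(all(d$cg_pct >= 0 & d$cg_pct <= 100))
  # image-derived CI tracks the rendered truth (absolute fraction scale)
  expect_lte(max(abs(d$ci / 1000 - d$true_fraction)), 0.03)
})
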