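test_that("survey logs round-trip bit-exactly and reject bad input", {
  df <- make_survey_df(10)
  track <- survey_track(df)
  path <- file.path(tempdir(), "survey.csv")
  write_survey_log(track, path)
  back <- read_survey_log(path)
  for (nm in names(df)) expect_identical(back[[nm]], df[[nm]])
  expect_equal(attr(back, "skipped"), 0L)

  # one corrupt row is skipped with a count, the rest survive
  lines <- readLines(path)
  lines[3] <- gsub("^[0-9.]+,", "not_a_time,", lines[3])
  writeLines(lines, path)
  expect_message(partial <- read_survey_log(path), "skipped 1")
  expect_equal(nrow(partial), 9L)
  expect_equal(attr(partial, "skipped"), 1L)

  # missing mandatory columns are reported by name
  df2 <- df; df2$us <- NULL; df2$rh <- NULL
  path2 <- file.path(tempdir(), "bad.csv")
  utils::write.csv(df2, path2, row.names = FALSE)
  expect_error(read_survey_log(path2), "us")
  expect_error(survey_track(df2), "rh")
  expect_error(survey_track(transform(df, timestamp = rev(timestamp))),
               "non-decreasing")

  # generator bookkeeping: 24 vines x 2 sides = 48 stop records
  canopies <- lapply(1:24, function(i) {
    make_virtual_canopy(vigor = 1 + i / 10, seed = i)
  })
  big <- simulate_survey(canopies, seed = 2)
  expect_equal(nrow(big), 48L)
  expect_equal(sort(unique(big$side)), c("left", "right"))
  path3 <- file.path(tempdir(), "big.csv")
  write_survey_log(big, path3)
  back3 <- read_survey_log(path3)
  for (nm in survey_columns_for_test()) {
    expect_identical(back3[[nm]], as.data.frame(big)[[nm]])
  }
})

test_that("microclimate de-trending removes the linear time drift", {
  ramp <- seq(20, 30, length.out = 40)
  out <- detrend_microclimate(ramp)
  expect_equal(out, rep(mean(ramp), 40), tolerance = 1e-9)

  const <- rep(55, 25)
  expect_equal(detrend_microclimate(const), const)

  set.seed(17)
  t <- seq_len(200)
  noisy <- 60 + 0.05 * t + rnorm(200, 0, 0.3)
  dt <- detrend_microclimate(noisy, t)
  refit <- ols_oracle(t, dt)
  expect_lt(abs(refit["slope"]), 1e-6)
  # mean essentially unchanged
  expect_equal(mean(dt), mean(stats::runmed(noisy, 5)), tolerance = 1e-9)

  expect_warning(short <- detrend_microclimate(c(1, 5, 3)), "fewer than 5")
  expect_equal(short, c(1, 5, 3))
})

test_that("extraneous-reading filter drops outliers and out-of-boundary stops", {
  df <- make_survey_df(20, ci_base = 600)
  track <- survey_track(df)

  # homogeneous CI inside no boundary: nothing dropped
  clean <- filter_extraneous(track)
  expect_equal(nrow(clean), 20L)
  expect_equal(attr(clean, "n_dropped"), 0L)

  # one left-side record reading CI ~ 0 amid ~600: that side dropped
  bad <- df
  bad[5, paste0("ci_s", 1:15)] <- 0  # row 5 is a "left" record
  tr_bad <- survey_track(bad)
  filt <- filter_extraneous(tr_bad)
  expect_equal(attr(filt, "n_dropped"), 1L)
  expect_false(any(filt$timestamp == 5 & filt$side == "left"))
  expect_true(any(filt$timestamp == 6 & filt$side == "right"))

  # boundary polygon excludes the headland records
  inside <- sp::point.in.polygon(df$lon, df$lat,
                                 c(9.60005, 9.60025, 9.60025, 9.60005),
                                 c(45.10005, 45.10005, 45.10025, 45.10025)) > 0
  poly <- cbind(c(9.60005, 9.60025, 9.60025, 9.60005),
                c(45.10005, 45.10005, 45.10025, 45.10025))
  cut <- filter_extraneous(track, boundary = poly)
  expect_equal(nrow(cut), sum(inside))
  expect_true(all(cut$timestamp %in% df$timestamp[inside]))
})

test_that("IDW spatialization matches the per-cell brute-force oracle", {
  grid <- list(x0 = 0, y0 = 0, nx = 6, ny = 5, cell = 2)

  r1 <- spatialize_idw(3.3, 4.4, 42, grid = grid)
  expect_true(all(r1$values == 42))

  # cell equidistant from two samples -> plain average
  r2 <- spatialize_idw(c(0, 4), c(0, 0), c(10, 20), grid = grid)
  expect_equal(r2$values[5, 2], 15)  # cell center (2, 0)
  # coincident sample cell takes the sample value exactly
  expect_equal(r2$values[5, 1], 10)

  set.seed(23)
  px <- runif(40, 0, 10); py <- runif(40, 0, 8); pv <- runif(40, 0, 100)
  r3 <- spatialize_idw(px, py, pv, grid = grid, power = 2, radius = 6)
  cx <- grid$x0 + (seq_len(grid$nx) - 1) * grid$cell
  cy <- grid$y0 + (seq_len(grid$ny) - 1) * grid$cell
  for (j in seq_len(grid$nx)) {
    for (i in seq_len(grid$ny)) {
      want <- idw_oracle(px, py, pv, cx[j], cy[i], power = 2, radius = 6)
      expect_equal(r3$values[grid$ny - i + 1, j], want, tolerance = 1e-10)
    }
  }
  # interpolation stays within the data range
  expect_gte(min(r3$values, na.rm = TRUE), min(pv))
  expect_lte(max(r3$values, na.rm = TRUE), max(pv))
  # no in-radius neighbor -> no-data
  r4 <- spatialize_idw(100, 100, 7, grid = grid, radius = 5)
  expect_true(all(is.na(r4$values)))
  expect_error(spatialize_idw(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("sampling interval reproduces the printed 0.3-0.8 m polling band", {
  expect_equal(sampling_interval(4, 3), 4 * 1000 / 3600 / 3, tolerance = 1e-12)
  expect_equal(round(sampling_interval(4, 3), 3), 0.370)
  expect_equal(round(sampling_interval(8, 3), 3), 0.741)
  expect_true(sampling_interval(4, 3) >= 0.3 && sampling_interval(4, 3) <= 0.8)
  expect_true(sampling_interval(8, 3) >= 0.3 && sampling_interval(8, 3) <= 0.8)
  expect_equal(sampling_interval(3.6, 1), 1.0)
  expect_error(sampling_interval(0, 3), "positive")
  expect_error(sampling_interval(4, -1), "positive")
})

test_that("map export covers the catalog and rejects unknown products", {
  canopies <- lapply(1:8, function(i) {
    make_virtual_canopy(vigor = 0.5 + i / 4, seed = i)
  })
  track <- simulate_survey(canopies, seed = 3)
  outdir <- file.path(tempdir(), "maps")

  paths <- export_maps(track, outdir, params = "CI")
  expect_true(file.exists(paths[["CI"]]))
  asc <- readLines(paths[["CI"]])
  expect_match(asc[1], "^NCOLS")
  body <- scan(text = asc[-(1:6)], quiet = TRUE)
  expect_gte(sum(body != -9999), 1)

  all_paths <- export_maps(track, outdir, params = "all")
  expect_length(all_paths, length(map_catalog()))  # 45 products
  expect_length(map_catalog(), 45L)
  expect_true(file.exists(all_paths[["TRACK"]]))
  gj <- jsonlite::read_json(all_paths[["TRACK"]])
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(gj$features[[1]]$geometry$type, "LineString")
  expect_length(gj$features, nrow(track) + 1L)

  expect_error(export_maps(track, outdir, params = "3D Canopy Index"),
               "not implemented")
  expect_error(export_maps(track, outdir, params = "BOGUS"), "valid keys")
})
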