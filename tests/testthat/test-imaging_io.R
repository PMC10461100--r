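test_that("integer camera stacks round-trip through TIFF bit for bit", {
  set.seed(11)
  frames <- array(sample(0:4095, 100 * 8 * 8, replace = TRUE),
                  dim = c(100, 8, 8))
  st <- movie_stack(frames, frame_rate_hz = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_identical(back$frames, st$frames * 1.0)
  expect_equal(back$frame_rate_hz, 5)       # from the sidecar
  expect_equal(back$frame_count, 100)
})

test_that("non-integer stacks round-trip at 32-bit stored precision", {
  set.seed(12)
  frames <- array(runif(20 * 4 * 4, 0, 5000), dim = c(20, 4, 4))
  st <- movie_stack(frames, frame_rate_hz = 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_lt(max(abs(back$frames - frames)), 5000 * 2^-31)
})

test_that("degenerate stack inputs are rejected with named properties", {
  expect_error(read_stack("no/such/file.tif"), "not found")
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0, 4, 4), path)
  expect_error(read_stack(path, frame_rate_hz = 5), "single-frame")
  path2 <- withr::local_tempfile(fileext = ".tif")
  rgb <- array(0.5, dim = c(4, 4, 3))
  tiff::writeTIFF(list(rgb, rgb), path2)
  expect_error(read_stack(path2, frame_rate_hz = 5), "non-grayscale")
  expect_error(movie_stack(array(-1, dim = c(2, 2, 2))), "non-negative")
})

test_that("extract_trace averages ROI pixels per frame", {
  frames <- array(100, dim = c(100, 6, 6))
  st <- movie_stack(frames)
  roi <- roi_mask(matrix(TRUE, 6, 6))
  rec <- extract_trace(st, roi, stimulus_id = "odorant_01")
  expect_equal(rec$trace, rep(100, 100))
  expect_equal(rec$fly_id, "roi1")

  # two pixels at 80 and 120 average to 100
  frames2 <- array(0, dim = c(10, 2, 2))
  frames2[, 1, 1] <- 80; frames2[, 2, 2] <- 120
  mask <- matrix(FALSE, 2, 2); mask[1, 1] <- TRUE; mask[2, 2] <- TRUE
  rec2 <- extract_trace(movie_stack(frames2), roi_mask(mask),
                        stimulus_id = "odorant_01",
                        stimulus_onset_frame = 5, stimulus_offset_frame = 6)
  expect_equal(rec2$trace, rep(100, 10))
})

test_that("extract_trace equals the brute-force masked mean on random stacks", {
  set.seed(21)
  for (rep in 1:5) {
    frames <- array(runif(30 * 5 * 7, 0, 1000), dim = c(30, 5, 7))
    mask <- matrix(runif(35) < 0.4, 5, 7)
    if (!any(mask)) mask[1, 1] <- TRUE
    rec <- extract_trace(movie_stack(frames), roi_mask(mask),
                         stimulus_id = "x", stimulus_onset_frame = 16,
                         stimulus_offset_frame = 20)
    oracle <- numeric(30)
    for (t in 1:30) {
      acc <- 0; npx <- 0
      for (i in 1:5) for (j in 1:7) if (mask[i, j]) {
        acc <- acc + frames[t, i, j]; npx <- npx + 1
      }
      oracle[t] <- acc / npx
    }
    expect_equal(rec$trace, oracle, tolerance = 1e-12)
  }
})

test_that("ROI misuse is caught", {
  st <- movie_stack(array(1, dim = c(5, 4, 4)))
  expect_error(roi_mask(matrix(FALSE, 4, 4)), "no TRUE pixel")
  expect_error(extract_trace(st, roi_mask(matrix(TRUE, 3, 3)),
                             stimulus_id = "x"),
               "does not match")
})

test_that("polygon JSON and label-TIFF ROIs rasterize to the same mask", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(list(label = "antennaL", x = c(2, 5, 5, 2), y = c(2, 2, 6, 6))),
    path, auto_unbox = TRUE)
  rois <- read_rois(path, shape = c(8, 8))
  expect_length(rois, 1)
  expect_equal(rois[[1]]$label, "antennaL")
  expect_true(all(rois[[1]]$mask[2:6, 2:5]))
  expect_false(any(rois[[1]]$mask[, 7:8]))

  lab <- matrix(0L, 8, 8); lab[2:6, 2:5] <- 1L
  tpath <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lab / 255, tpath, bits.per.sample = 8)
  rois2 <- read_rois(tpath)
  expect_equal(rois2[[1]]$mask, rois[[1]]$mask)
})

test_that("trace tables round-trip with full metadata", {
  sc <- quiet_scenario(seed = 5)
  recs <- list(
    simulate_recording(sc, "odorant_01", fly_id = "flyA"),
    simulate_recording(sc, "solvent", fly_id = "flyA"),
    simulate_blank(sc, fly_id = "flyA"))
  tp <- withr::local_tempfile(fileext = ".csv")
  write_traces(recs, tp)
  back <- read_traces(tp)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$trace, recs[[i]]$trace)
    expect_equal(back[[i]]$stimulus_id, recs[[i]]$stimulus_id)
    expect_equal(back[[i]]$is_blank, recs[[i]]$is_blank)
    expect_equal(back[[i]]$is_solvent, recs[[i]]$is_solvent)
    expect_equal(back[[i]]$fly_id, recs[[i]]$fly_id)
  }
})

test_that("corrupt trace tables name the offending recording and frame", {
  sc <- quiet_scenario(seed = 6)
  recs <- list(simulate_recording(sc, "odorant_01", fly_id = "flyA"))
  tp <- withr::local_tempfile(fileext = ".csv")
  write_traces(recs, tp)
  tab <- read.csv(tp)

  drop50 <- tab[tab$frame != 50, ]
  p1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(drop50, p1, row.names = FALSE)
  expect_error(read_traces(p1, paste0(sub("\\.csv$", "", tp), "_meta.csv")),
               "flyA_odorant_01.*frame 50")

  dup <- rbind(tab, tab[tab$frame == 7, ])
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, p2, row.names = FALSE)
  expect_error(read_traces(p2, paste0(sub("\\.csv$", "", tp), "_meta.csv")),
               "duplicate frame 7")
})

test_that("a simulated 16-recording panel survives the CSV round trip", {
  sc <- quiet_scenario(seed = 7)
  panel <- simulate_panel(sc, n_flies = 1)
  tp <- withr::local_tempfile(fileext = ".csv")
  write_traces(c(panel$recordings, panel$blanks), tp)
  back <- read_traces(tp)
  expect_length(back, 16)  # 14 odorants + solvent + blank
  ids <- vapply(back, `[[`, character(1), "stimulus_id")
  expect_setequal(ids[!is.na(ids)],
                  c("solvent", names(sc$tuning)))
})
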