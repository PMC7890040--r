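test_that("TIFF stacks round-trip losslessly and preserve shape", {
  set.seed(11)
  arr <- array(sample(0:65535, 16 * 12 * 5, replace = TRUE), dim = c(16, 12, 5))
  movie <- time_lapse(arr, frame_rate_hz = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(movie, path)
  back <- read_stack(path, frame_rate_hz = 2)
  expect_identical(dim(back$frames), dim(arr))
  expect_equal(back$frames, arr, ignore_attr = TRUE)
  expect_equal(back$frame_rate_hz, 2)
})

test_that("single-page TIFFs and malformed movies are rejected", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8, 8), path)
  expect_error(read_stack(path, 2), "not a time series")
  expect_error(read_stack(file.path(tempdir(), "nope.tif"), 2), "not found")
  expect_error(time_lapse(array(0, c(4, 4, 1)), 2), "not a time series")
  expect_error(time_lapse(array(0, c(4, 4, 3)), 0), "frame_rate_hz")
  expect_error(time_lapse(list(matrix(0, 3, 3), matrix(0, 4, 4)), 2),
               "inconsistent")
})

test_that("ROI labels follow the ROIID-EventStart scheme and regenerate exactly", {
  expect_equal(roi_label("0000", 35), "0000-35")
  expect_equal(roi_label(c(0, 1), c(35, 35)), c("0000-35", "0001-35"))
  parsed <- parse_roi_label("0012-161")
  expect_equal(parsed$roi_id, "0012")
  expect_equal(parsed$event_start_frame, 161L)
  expect_error(parse_roi_label("12-x"), "malformed")
  expect_error(parse_roi_label("00001-3"), "malformed")
  expect_error(roi_label("12", 3), "4 digits")
  # labels regenerate bit-identically
  set.seed(4)
  ids <- sprintf("%04d", sample(0:9999, 50))
  starts <- sample(1:500, 50, replace = TRUE)
  lab <- roi_label(ids, starts)
  p <- parse_roi_label(lab)
  expect_identical(roi_label(p$roi_id, p$event_start_frame), lab)
})

test_that("ROI sets round-trip through CSV for random records", {
  set.seed(7)
  n <- 100
  rois <- tibble::tibble(
    roi_id = sprintf("%04d", seq_len(n) - 1),
    center_row = sample(1:512, n, replace = TRUE),
    center_col = sample(1:512, n, replace = TRUE),
    size_px = sample(c(3L, 5L, 7L), n, replace = TRUE),
    event_start_frame = sample(1:200, n, replace = TRUE)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_set(rois, path)
  back <- read_roi_set(path)
  expect_equal(back[names(rois)], rois)
  expect_identical(back$label, roi_label(back$roi_id, back$event_start_frame))
  expect_error(write_roi_set(dplyr::mutate(rois, size_px = 4L), path), "odd")
})

test_that("trace tables are frames-by-ROIs CSVs that round-trip to 6 decimals", {
  tr <- cbind(`0000-35` = c(1.1234567, 2, 3), `0001-40` = c(4, 5.5, 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_table(tr, path)
  lines <- readLines(path)
  expect_length(lines, 4L)  # header + 3 frames
  expect_equal(strsplit(lines[1], ",")[[1]], c("0000-35", "0001-40"))
  back <- read_trace_table(path)
  expect_equal(back, tr, tolerance = 1e-6, ignore_attr = TRUE)

  # unequal lengths rejected; empty set gives a header-only file
  expect_error(write_trace_table(list(a = 1:3, b = 1:4), path), "unequal")
  write_trace_table(list(), path)
  expect_equal(ncol(read_trace_table(path)), 0L)
})

test_that("analysis configs parse into paradigm and detection params", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "paradigm:",
    "  frame_rate_hz: 2", "  baseline_frames: 30",
    "  stim_start_frame: 61", "  stim_len_frames: 50",
    "  nh4_start_frame: 160",
    "detection:",
    "  snr: 20", "  normalization: baseline_subtraction",
    "  smoothing_radius_px: 2"
  ), path)
  cfg <- read_analysis_config(path)
  expect_s3_class(cfg$paradigm, "acquisition_paradigm")
  expect_equal(cfg$paradigm$nh4_start_frame, 160L)
  expect_equal(cfg$params$snr, 20)
  expect_equal(cfg$params$normalization$method, "baseline_subtraction")
  expect_equal(cfg$params$normalization$smoothing_radius_px, 2L)
})
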