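test_that("paradigm arithmetic converts durations, rounds windows, caps overlap", {
  expect_equal(frames_for_duration(24, 2), 48L)
  expect_equal(frames_for_duration(0, 7), 0L)
  expect_equal(frames_for_duration(80, 2), 160L)
  expect_error(frames_for_duration(-1, 2), ">= 0")

  expect_equal(round_stim_window(48), 50L)
  expect_equal(round_stim_window(50), 50L)
  expect_equal(round_stim_window(1), 10L)

  expect_equal(max_overlap_for_roi(3), 3L)
  expect_equal(max_overlap_for_roi(1), 0L)
  expect_equal(max_overlap_for_roi(5), 8L)
})

test_that("paradigm invariants are enforced", {
  expect_error(acquisition_paradigm(2, 30, 20, 50, 160), "baseline_frames")
  expect_error(acquisition_paradigm(2, 30, 61, 120, 160), "before nh4")
  p <- acquisition_paradigm(2, 30, 61, 50, 160)
  expect_equal(p$n_stimulations, 1L)
  expect_error(detection_params(snr = 300), "snr")
  expect_error(detection_params(roi_size_px = 4), "odd")
  expect_error(detection_params(roi_size_px = 3, max_overlap_px = 4), "third")
})

test_that("sd_projection equals the per-pixel sample SD", {
  const <- time_lapse(array(5, c(4, 4, 10)), 2)
  expect_equal(sd_projection(const, 1:10), matrix(0, 4, 4))

  two <- time_lapse(array(c(0, 2), c(1, 1, 2)), 2)
  expect_equal(sd_projection(two, 1:2)[1, 1], sqrt(2))

  set.seed(21)
  for (k in 1:5) {
    a <- array(rnorm(8 * 8 * 20, 100, 12), c(8, 8, 20))
    m <- time_lapse(a, 2)
    w <- sort(sample(1:20, 9))
    expect_equal(sd_projection(m, w), oracle_sd_projection(a, w),
                 tolerance = 1e-9)
  }
  # multiple blocks combine by pixel-wise maximum
  a <- array(rnorm(6 * 6 * 30), c(6, 6, 30))
  m <- time_lapse(a, 2)
  expect_equal(sd_projection(m, list(1:10, 21:30)),
               pmax(oracle_sd_projection(a, 1:10), oracle_sd_projection(a, 21:30)),
               tolerance = 1e-9)
  expect_error(sd_projection(m, 5L), "length")
})

test_that("find_candidate_maxima matches the flood-fill prominence oracle", {
  expect_equal(nrow(find_candidate_maxima(matrix(1, 8, 8), 10)), 0L)

  # a single Gaussian bump yields exactly one maximum at its center
  g <- outer(dnorm(1:15, 8, 2), dnorm(1:15, 8, 2))
  mx <- find_candidate_maxima(g, 50)
  expect_equal(nrow(mx), 1L)
  expect_equal(c(mx$row, mx$col), c(8L, 8L))

  # two bumps joined by a saddle: prominence decides which survive
  set.seed(31)
  for (k in 1:200) {
    x <- matrix(rnorm(100), 10, 10)
    if (k %% 2 == 0) x <- dcvfusion:::cpp_gaussian_blur(x, 1)  # smoother images too
    thr <- runif(1, 20, 120)
    got <- find_candidate_maxima(x, thr)
    want <- oracle_prominent_maxima(x, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$row, want$row)
      expect_equal(got$col, want$col)
      expect_equal(got$prominence, want$prominence, tolerance = 1e-9)
    }
  }
})

test_that("plateau maxima collapse to their rounded centroid", {
  x <- matrix(0, 9, 9)
  x[4:5, 6] <- 10          # 2-pixel plateau, centroid row 4.5 -> 5
  mx <- find_candidate_maxima(x, 100)
  expect_equal(nrow(mx), 1L)
  expect_equal(c(mx$row, mx$col), c(5L, 6L))

  x2 <- matrix(0, 9, 9)
  x2[3:5, 3:5] <- 7        # 3x3 plateau, centroid (4,4)
  mx2 <- find_candidate_maxima(x2, 100)
  expect_equal(c(mx2$row, mx2$col), c(4L, 4L))
})

test_that("place_rois keeps the higher-scoring ROI when overlap exceeds the cap", {
  # two maxima 1 px apart, 3x3 ROIs share 6 px > 3 -> only the best kept
  mx <- tibble::tibble(row = c(10L, 11L), col = c(10L, 10L), score = c(9, 5))
  rois <- place_rois(mx, 3, 3, c(32, 32))
  expect_equal(nrow(rois), 1L)
  expect_equal(rois$center_row, 10L)
  expect_equal(rois$roi_id, "0000")

  # 3 px apart: disjoint, both kept, numbered in score order
  mx2 <- tibble::tibble(row = c(10L, 13L), col = c(10L, 10L), score = c(9, 5))
  rois2 <- place_rois(mx2, 3, 3, c(32, 32))
  expect_equal(rois2$roi_id, c("0000", "0001"))

  expect_equal(nrow(place_rois(mx[0, ], 3, 3, c(32, 32))), 0L)
  expect_error(place_rois(mx, 33, 3, c(32, 32)), "larger than image")
})

test_that("assign_event_start applies the rolling-statistics rule", {
  p <- small_paradigm()  # baseline 20, stim 41..70, nh4 90
  base <- rep(100, 120)

  tr <- base; tr[40:60] <- 110  # step before the stimulation window
  expect_true(is.na(assign_event_start(c(base[1:39], rep(100, 81)), p, 2)))

  tr <- base; tr[45:55] <- 110
  expect_equal(assign_event_start(tr, p, 2), 45L)

  # noisy trace: oracle recomputation of the rolling threshold
  set.seed(41)
  tr <- rnorm(120, 100, 2); tr[50:60] <- tr[50:60] + 30
  got <- assign_event_start(tr, p, 2)
  found <- NA
  for (f in 41:89) {
    w <- tr[(f - 20):(f - 1)]
    if (tr[f] > mean(w) + 2 * sd(w)) { found <- f; break }
  }
  expect_equal(got, found)

  # never above threshold -> NA (ROI discarded)
  expect_true(is.na(assign_event_start(rep(100, 120), p, 2)))
  # step strictly before stim start is not an event
  tr2 <- base; tr2[30] <- 200
  expect_true(is.na(assign_event_start(tr2, p, 5)))
})

test_that("detection is deterministic and ROIs never overlap beyond the cap", {
  s <- small_sim(2)
  d1 <- detect_fusion_events(s$movie, s$paradigm)
  d2 <- detect_fusion_events(s$movie, s$paradigm)
  expect_identical(d1$rois, d2$rois)
  expect_identical(d1$traces, d2$traces)

  r <- d1$rois
  if (nrow(r) > 1) {
    for (i in seq_len(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
      ov <- dcvfusion:::roi_overlap_px(r$center_row[i], r$center_col[i],
                                       r$center_row[j], r$center_col[j],
                                       3L, dim(s$movie$frames)[1:2])
      expect_lte(ov, d1$params$max_overlap_px)
    }
  }
})

test_that("detection in baseline-subtraction mode ignores global intensity offsets", {
  s <- small_sim(3)
  pb <- detection_params(normalization = normalization_params("baseline_subtraction"))
  d1 <- detect_fusion_events(s$movie, s$paradigm, pb)
  shifted <- s$movie
  shifted$frames <- shifted$frames + 500
  d2 <- detect_fusion_events(shifted, s$paradigm, pb)
  cols <- c("roi_id", "center_row", "center_col", "event_start_frame", "label")
  expect_identical(d1$rois[cols], d2$rois[cols])
  expect_equal(d1$rois$score, d2$rois$score, tolerance = 1e-9)
})

test_that("recall and precision hold on the default scenario across seeds", {
  stats <- purrr::map_dfr(1:10, function(s) {
    sim <- simulate_movie(recall_scenario(s))
    evaluate_detection(detect_fusion_events(sim$movie, sim$paradigm),
                       sim$truth$events)
  })
  expect_gte(mean(stats$recall), 0.9)
  expect_gte(mean(stats$precision), 0.8)
})

test_that("detection under bw_opening tolerates an uneven illumination field", {
  flat <- simulate_movie(simulation_scenario(width = 160, height = 160,
                                             n_vesicles = 80, n_events = 40,
                                             illumination_gradient_strength = 0,
                                             seed = 6))
  grad <- simulate_movie(simulation_scenario(width = 160, height = 160,
                                             n_vesicles = 80, n_events = 40,
                                             illumination_gradient_strength = 0.35,
                                             seed = 6))
  rf <- evaluate_detection(detect_fusion_events(flat$movie, flat$paradigm),
                           flat$truth$events)$recall
  rg <- evaluate_detection(detect_fusion_events(grad$movie, grad$paradigm),
                           grad$truth$events)$recall
  expect_lte(abs(rf - rg), 0.1)
})
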