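test_that("event histograms bin start times and conserve the event count", {
  ev <- tibble::tibble(start_time_s = c(30.0, 30.4))
  h <- event_histogram(ev, 0.5, 100)
  expect_equal(sum(h$count), 2L)
  expect_equal(h$count[h$bin_start_s == 30], 2L)  # same bin

  h0 <- event_histogram(ev[0, ], 0.5, 100)
  expect_true(all(h0$count == 0))

  set.seed(43)
  for (k in 1:20) {
    times <- runif(sample(1:120, 1), 0, 99.9)
    hh <- event_histogram(tibble::tibble(start_time_s = times), 1.5, 100)
    expect_equal(sum(hh$count), length(times))
  }
  expect_error(event_histogram(ev, 0, 100), "bin_s")
})

test_that("cumulative counts are prefix sums that invert back to the histogram", {
  expect_equal(cumulative_counts(c(2, 0, 3)), c(2, 2, 5))
  cc <- cumulative_counts(c(2, 0, 3), normalize = TRUE)
  expect_equal(cc[3], 1)
  h <- c(4, 0, 1, 7)
  expect_equal(diff(c(0, cumulative_counts(h))), h)
})

test_that("QC flags trigger on missing NH4 response and on saturation", {
  # clean small movie: no flags
  s <- small_sim(1)
  cell <- fixture("small_cell1",
                  analyze_cell(s$movie, s$paradigm, cell_id = "c1"))
  expect_equal(cell$pool$qc_flags, "")

  # planted saturating patch outside the soma -> saturation flag
  ssat <- fixture("sat_small",
                  simulate_movie(small_scenario(5, saturated_patch = TRUE)))
  pe <- estimate_pool(ssat$movie, ssat$paradigm)
  expect_gt(pe$n_saturated_px, 0)
  expect_true("nh4_saturation" %in% pe$qc_flags)
  qc <- qc_evaluate(ssat$movie, ssat$paradigm, pe)
  expect_true(qc$triggered[qc$flag == "nh4_saturation"])

  # no NH4 step -> no dequenching response, so no detectable puncta
  s0 <- fixture("no_nh4_dark",
                simulate_movie(small_scenario(6, n_events = 0L,
                                              nh4_step = FALSE)))
  pe0 <- estimate_pool(s0$movie, s0$paradigm)
  qc0 <- qc_evaluate(s0$movie, s0$paradigm, pe0)
  expect_true(qc0$triggered[qc0$flag == "no_nh4_puncta"])
})

test_that("batch collection equals per-cell runs and is order-independent", {
  dir <- withr::local_tempdir()
  sims <- lapply(1:3, function(s) small_sim(s))
  for (i in 1:3)
    write_stack(sims[[i]]$movie, file.path(dir, sprintf("cell%d.tif", i)))

  got <- collect_folder(dir, sims[[1]]$paradigm, frame_rate_hz = 2)
  expect_equal(sort(unique(got$vesicles$cell_id)),
               sort(unique(got$pools$cell_id)))
  expect_equal(nrow(got$pools), 3L)

  # totals per cell equal per-cell single runs
  for (i in 1:3) {
    single <- analyze_cell(sims[[i]]$movie, sims[[i]]$paradigm,
                           cell_id = sprintf("cell%d", i))
    batch_ev <- dplyr::filter(got$vesicles, cell_id == sprintf("cell%d", i))
    expect_equal(nrow(batch_ev), nrow(single$events))
    expect_equal(batch_ev$peak_dff, single$events$peak_dff)
    expect_equal(
      dplyr::filter(got$pools, cell_id == sprintf("cell%d", i))$raw_pool,
      single$pool$raw_pool)
  }

  # n_events in the pool table equals rows in the vesicle table
  counts <- dplyr::count(got$vesicles, cell_id)
  expect_equal(got$pools$n_events,
               counts$n[match(got$pools$cell_id, counts$cell_id)])
})

test_that("stored ROI sets are re-measured instead of re-detected", {
  dir <- withr::local_tempdir()
  s <- small_sim(1)
  det <- fixture("small_det1", detect_fusion_events(s$movie, s$paradigm))
  write_stack(s$movie, file.path(dir, "cellA.tif"))
  write_roi_set(det$rois, file.path(dir, "cellA_rois.csv"))
  got <- collect_folder(dir, s$paradigm, frame_rate_hz = 2)
  expect_equal(got$pools$n_events, nrow(det$rois))
  expect_equal(sort(got$vesicles$label), sort(det$rois$label))
})

test_that("cells missing a synapse mask are skipped with a warning", {
  dir <- withr::local_tempdir()
  s <- small_sim(1)
  write_stack(s$movie, file.path(dir, "lonely.tif"))
  expect_warning(
    got <- collect_folder(dir, s$paradigm, synaptic = TRUE, frame_rate_hz = 2),
    "mask missing")
  expect_equal(nrow(got$pools), 0L)
})
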