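test_that("nh4_max_projection is the baseline-subtracted max over the NH4 window", {
  flat <- time_lapse(array(7, c(5, 5, 20)), 2)
  expect_equal(nh4_max_projection(flat, 15, 5, rescale = FALSE),
               matrix(0, 5, 5))
  expect_error(nh4_max_projection(flat, 20, 5), "empty NH4 window")

  # single vesicle stepping from 0 to 80 at NH4
  a <- array(10, c(9, 9, 20)); a[5, 5, 15:20] <- 90
  m <- time_lapse(a, 2)
  proj <- nh4_max_projection(m, 15, 5, rescale = FALSE)
  expect_equal(proj[5, 5], 80)
  expect_equal(sum(proj > 0), 1L)

  set.seed(17)
  for (k in 1:5) {
    a <- array(rnorm(8 * 8 * 30, 100, 10), c(8, 8, 30))
    m <- time_lapse(a, 2)
    brute <- apply(a[, , 20:30], c(1, 2), max) -
      apply(a[, , 1:6], c(1, 2), mean)
    expect_equal(nh4_max_projection(m, 20, 6, rescale = FALSE), brute,
                 tolerance = 1e-12)
  }
})

test_that("auto SNR tracks mean + 3 SD of the projection background", {
  set.seed(19)
  noise <- matrix(abs(rnorm(256 * 256, 50, 10)), 256, 256)
  got <- auto_snr_from_nh4(noise)
  expect_lt(abs(got - (mean(noise) + 3 * sd(noise))) /
              (mean(noise) + 3 * sd(noise)), 0.2)

  # noiseless puncta on zero background: positive, below the punctum height
  img <- matrix(0, 32, 32)
  img[8, 8] <- 200; img[20, 25] <- 200
  got2 <- auto_snr_from_nh4(img)
  expect_gt(got2, 0)
  expect_lt(got2, 200)

  expect_error(auto_snr_from_nh4(matrix(0, 8, 8)), "all-zero")
})

test_that("all three pool estimates recover a well-separated vesicle pool", {
  cell <- pool_cell(1)
  pe <- cell$pool_estimate
  expect_lt(abs(pe$raw_pool - 150) / 150, 0.10)
  expect_lt(abs(pe$fused_corrected - 150) / 150, 0.10)
  expect_lt(abs(pe$puncta_corrected - 150) / 150, 0.10)
})

test_that("clustered vesicles push the corrected estimates above the raw count", {
  s <- fixture("clustered", simulate_movie(
    simulation_scenario(n_events = 30L, event_unit_matched = TRUE,
                        cluster_sites = 20L, cluster_size = 3L, seed = 1)))
  det <- detect_fusion_events(s$movie, s$paradigm)
  ev <- measure_events(det)
  pe <- estimate_pool(s$movie, s$paradigm, ev)
  expect_gt(pe$fused_corrected, pe$raw_pool)
  expect_gt(pe$puncta_corrected, pe$raw_pool)
})

test_that("puncta-corrected pool is invariant to a global brightness rescale", {
  s <- pool_sim(1)
  params <- detection_params()
  ev <- pool_cell(1)$events
  pe1 <- pool_cell(1)$pool_estimate
  bright <- s$movie
  bright$frames <- bright$frames * 2
  pe2 <- estimate_pool(bright, s$paradigm, ev, params)
  expect_lt(abs(pe2$puncta_corrected - pe1$puncta_corrected) /
              pe1$puncta_corrected, 0.05)
})

test_that("a movie without NH4 puncta is flagged and excluded from pools", {
  s <- fixture("no_nh4_small",
               simulate_movie(small_scenario(4, n_events = 0L, n_vesicles = 5L,
                                             nh4_step = FALSE,
                                             vesicle_brightness = 0)))
  pe <- estimate_pool(s$movie, s$paradigm)
  expect_true("no_nh4_puncta" %in% pe$qc_flags)
  expect_error(release_fraction(5, pe, "fused"), "zero or undefined")
})

test_that("release fraction is events over the selected pool", {
  expect_equal(release_fraction(50, 1000), 0.05)
  expect_equal(release_fraction(0, 1000), 0)
  pe <- pool_cell(1)$pool_estimate
  expect_equal(release_fraction(10, pe, "raw"), 10 / pe$raw_pool)
  expect_error(release_fraction(5, 0), "zero")
})
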