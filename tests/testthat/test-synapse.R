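test_that("blank images give an empty mask", {
  m <- make_synapse_mask(matrix(5, 32, 32), 3)
  expect_false(any(m$mask))
  expect_error(make_synapse_mask(matrix(5, 32, 32), 16), "half the image")
})

test_that("marker puncta are segmented and a smooth gradient is excluded", {
  set.seed(23)
  h <- 96; w <- 96
  grad <- outer(seq(20, 60, length.out = h), seq(1, 1.5, length.out = w))
  img <- grad
  centers <- cbind(sample(seq(8, h - 8, by = 12)), sample(seq(8, w - 8, by = 12)))
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(h) - centers[i, 1])^2, (seq_len(w) - centers[i, 2])^2, "+")
    img <- img + 300 * exp(-d2 / (2 * 1.2^2))
  }
  img <- img + rnorm(h * w, 0, 4)

  msk <- make_synapse_mask(img, 3)
  # truth: where the rendered punctum signal exceeds ~10% of its peak
  # (sigma 1.2 -> radius ~2.6 px)
  truth <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(h) - centers[i, 1])^2, (seq_len(w) - centers[i, 2])^2, "+")
    truth <- truth | d2 <= 6.5
  }
  iou <- sum(msk$mask & truth) / sum(msk$mask | truth)
  expect_gte(iou, 0.7)
  # every punctum present as its own component, background gradient not
  expect_true(all(msk$mask[centers]))
  expect_equal(max(dcvfusion:::cpp_label_components(msk$mask)), nrow(centers))

  # dark-object convention: the inverted image segments identically
  msk_dark <- make_synapse_mask(max(img) + min(img) - img, 3, objects = "dark")
  expect_equal(msk_dark$mask, msk$mask)
})

test_that("triangle threshold matches the geometric oracle", {
  set.seed(29)
  for (k in 1:200) {
    # unimodal background with a bright tail, random shape
    x <- c(rnorm(2000, 50, runif(1, 2, 15)), runif(sample(10:200, 1), 80, 255))
    expect_equal(triangle_threshold(x), oracle_triangle_threshold(x),
                 tolerance = 1e-12)
  }
  # bimodal 8-bit histogram: the threshold separates the two modes
  bi <- c(rnorm(5000, 30, 5), rnorm(300, 200, 8))
  thr <- triangle_threshold(bi)
  expect_gt(mean(bi[1:5000] < thr), 0.99)       # background below
  expect_gt(mean(bi[5001:5300] > thr), 0.99)    # foreground above
})

test_that("distance_to_mask matches the exhaustive scan and is a metric", {
  mask <- matrix(FALSE, 10, 10); mask[4, 5] <- TRUE
  expect_equal(distance_to_mask(c(4, 5), mask), 0)
  mask2 <- matrix(FALSE, 10, 10); mask2[4, 5] <- TRUE  # (1,1) -> (4,5): 3-4-5
  expect_equal(distance_to_mask(c(1, 1), mask2), 5)

  set.seed(37)
  for (k in 1:200) {
    m <- matrix(runif(64) < 0.15, 8, 8)
    if (!any(m)) m[sample(64, 1)] <- TRUE
    pt <- c(sample(8, 1), sample(8, 1))
    expect_equal(distance_to_mask(pt, m), oracle_distance_to_mask(pt, m))
    # zero iff inside
    expect_equal(distance_to_mask(pt, m) == 0, m[pt[1], pt[2]])
  }
  expect_error(distance_to_mask(c(1, 1), matrix(FALSE, 4, 4)), "empty mask")
})

test_that("events are classified synaptic within the distance tolerance", {
  mask <- matrix(FALSE, 20, 20); mask[10, 10] <- TRUE
  ev <- tibble::tibble(center_row = c(10L, 10L, 10L), center_col = c(10L, 11L, 20L),
                       synaptic = NA, dist_to_synapse_px = NA_real_)
  out <- classify_synaptic(ev, mask, tolerance_px = 1)
  expect_equal(out$synaptic, c(TRUE, TRUE, FALSE))
  expect_equal(out$dist_to_synapse_px, c(0, 1, 10))
})

test_that("the planted synaptic fraction is recovered through the mask pipeline", {
  cell <- pool_cell(1)
  truth <- pool_sim(1)$truth$events
  frac_true <- mean(truth$synaptic)
  frac_got <- mean(cell$events$synaptic)
  expect_lt(abs(frac_got - frac_true), 0.1)
})
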