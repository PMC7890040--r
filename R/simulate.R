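# Synthetic pHluorin movie generator with exact ground truth.
#
# The scene emulates a single autaptic neuron on an astrocyte island: faint
# diffuse signal, brighter neurites radiating from a bright soma, quenched
# stationary vesicle puncta (~3 px), stimulus-locked fusion events with an
# instantaneous rise and exponential decay, a global NH4Cl dequenching step
# revealing every labeled vesicle within 2 frames, a smooth multiplicative
# illumination field, and mixed Poisson-Gaussian camera noise on a constant
# offset. All randomness derives from a single seed.

#' Simulation scenario
#'
#' Default values reproduce the reference acquisition paradigm (2 Hz, 30-frame
#' rolling baseline, stimulation frames 61-110, NH4Cl from frame 160 of 200)
#' and the reported phenomenology: 30-200 stimulus-locked events of 1.5-3
#' dF/F0, ~3 px puncta, and a desk-scaled pool of 150 labeled vesicles.
#'
#' @param width,height Image size in pixels.
#' @param n_frames Movie length in frames.
#' @param frame_rate_hz Acquisitions per second.
#' @param baseline_frames,stim_start_frame,stim_len_frames,nh4_start_frame
#'   Paradigm bookkeeping (see [acquisition_paradigm()]).
#' @param n_vesicles Number of labeled vesicles (the true pool).
#' @param n_events Number of fusion events (<= `n_vesicles`).
#' @param event_amplitude_range dF/F0 amplitude range, drawn uniformly.
#' @param event_decay_tau_s Exponential decay constant of events, seconds.
#' @param event_tail_frames Frames after the stimulation window in which events
#'   may still start (0: strictly stimulus-locked).
#' @param event_unit_matched If `TRUE`, events are rendered with the same peak
#'   brightness as a dequenched vesicle instead of the dF/F0 draw (pool
#'   calibration scenarios).
#' @param punctum_sigma_px Gaussian sigma of vesicle/event puncta (~1 px gives
#'   ~3 px puncta).
#' @param vesicle_brightness Peak added counts of a dequenched vesicle.
#' @param quenched_fraction Pre-NH4 brightness of a quenched vesicle, as a
#'   fraction of `vesicle_brightness`.
#' @param fused_retain Fused vesicles still dequench during NH4 (default
#'   `TRUE`).
#' @param cluster_sites,cluster_size Number of multi-vesicle cluster sites and
#'   vesicles per cluster (for pool-correction scenarios).
#' @param n_synapses Number of synapse marker puncta (0: no marker image).
#' @param synaptic_event_fraction Fraction of events placed at synapse sites
#'   (`NA`: placement ignores synapses).
#' @param neurite_brightness,soma_brightness,diffuse_brightness Scene
#'   fluorescence levels in counts.
#' @param camera_offset Constant camera offset in counts.
#' @param illumination_gradient_strength Relative amplitude of the smooth
#'   multiplicative illumination field.
#' @param noise_gaussian_sd Read-noise SD in counts.
#' @param poisson_gain Counts per photoelectron for the Poisson component.
#' @param nh4_step Render the NH4Cl dequenching step (default `TRUE`).
#' @param saturated_patch Plant a patch outside the soma that saturates during
#'   NH4 (QC scenario).
#' @param saturation_level Bit-depth maximum (clamp and saturation target).
#' @param vesicle_min_sep_px,event_min_sep_px Minimum separation between
#'   vesicles / between fusion sites.
#' @param seed Integer seed fixing every random draw.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(width = 256L, height = 256L, n_frames = 200L,
                                frame_rate_hz = 2,
                                baseline_frames = 30L, stim_start_frame = 61L,
                                stim_len_frames = 50L, nh4_start_frame = 160L,
                                n_vesicles = 150L, n_events = 60L,
                                event_amplitude_range = c(1.5, 3),
                                event_decay_tau_s = 2,
                                event_tail_frames = 0L,
                                event_unit_matched = FALSE,
                                punctum_sigma_px = 1,
                                vesicle_brightness = 300,
                                quenched_fraction = 0.05,
                                fused_retain = TRUE,
                                cluster_sites = 0L, cluster_size = 3L,
                                n_synapses = 0L,
                                synaptic_event_fraction = NA_real_,
                                neurite_brightness = 150,
                                soma_brightness = 600,
                                diffuse_brightness = 30,
                                camera_offset = 100,
                                illumination_gradient_strength = 0.2,
                                noise_gaussian_sd = 3, poisson_gain = 2,
                                nh4_step = TRUE, saturated_patch = FALSE,
                                saturation_level = 65535,
                                vesicle_min_sep_px = 8,
                                event_min_sep_px = 6,
                                seed = 1L) {
  if (n_events > n_vesicles + cluster_sites * cluster_size)
    stopf("n_events must not exceed the number of vesicles")
  if (any(event_amplitude_range <= 0)) stopf("amplitudes must be positive")
  sc <- as.list(environment())
  structure(sc, class = "simulation_scenario")
}

# Smooth random multiplicative illumination field with mean ~1.
illumination_field <- function(h, w, strength) {
  coarse <- matrix(runif(16), 4, 4)
  big <- matrix(0, h, w)
  ri <- pmin(4L, pmax(1L, ceiling(seq_len(h) / h * 4)))
  ci <- pmin(4L, pmax(1L, ceiling(seq_len(w) / w * 4)))
  big[] <- coarse[cbind(rep(ri, times = w), rep(ci, each = h))]
  big <- cpp_gaussian_blur(big, min(h, w) / 8)
  big <- (big - mean(big)) / max(abs(big - mean(big)) + 1e-12)
  1 + strength * big
}

# Neurite skeleton: smooth random walks from the soma outwards.
neurite_mask <- function(h, w, soma, n_branches = 16L) {
  mask <- matrix(FALSE, h, w)
  for (b in seq_len(n_branches)) {
    ang <- runif(1, 0, 2 * pi)
    r <- soma$row; c <- soma$col
    for (step in seq_len(max(h, w))) {
      ang <- ang + rnorm(1, 0, 0.25)
      r <- r + sin(ang); c <- c + cos(ang)
      ri <- round(r); ci <- round(c)
      if (ri < 2 || ri > h - 1 || ci < 2 || ci > w - 1) break
      mask[ri, ci] <- TRUE
    }
  }
  mask
}

# Gaussian punctum kernel with peak 1, truncated at 3.5 sigma.
punctum_kernel <- function(sigma) {
  hw <- ceiling(3.5 * sigma)
  d <- outer((-hw:hw)^2, (-hw:hw)^2, "+")
  exp(-d / (2 * sigma^2))
}

# Add amp * kernel at (row, col), clipped at image borders.
add_punctum <- function(img, row, col, amp, kern) {
  hw <- (nrow(kern) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  r0 <- max(1L, row - hw); r1 <- min(h, row + hw)
  c0 <- max(1L, col - hw); c1 <- min(w, col + hw)
  kr <- (r0:r1) - row + hw + 1L
  kc <- (c0:c1) - col + hw + 1L
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * kern[kr, kc, drop = FALSE]
  img
}

# Sample n points from candidate pixels with a minimum pairwise separation.
sample_separated <- function(cand, n, min_sep) {
  sel <- matrix(numeric(0), 0, 2)
  ord <- sample(nrow(cand))
  for (i in ord) {
    p <- cand[i, ]
    if (nrow(sel) == 0L ||
        min((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2) >= min_sep^2) {
      sel <- rbind(sel, p)
      if (nrow(sel) == n) break
    }
  }
  if (nrow(sel) < n)
    stopf("could not place %d points with separation %g (placed %d)",
          n, min_sep, nrow(sel))
  sel
}

#' Simulate a pHluorin time-lapse movie with ground truth
#'
#' Renders the scenario into a 16-bit-style movie, the exact per-vesicle and
#' per-event ground truth, and (when `n_synapses > 0`) a synapse-marker image.
#' Event amplitudes are calibrated so that the mean 3 x 3 ROI trace at the
#' event center rises by `amplitude * F0` over its own baseline (camera offset
#' included), i.e. the programmed dF/F0 is recoverable from the rendered
#' movie. Bit-identical for a fixed seed.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `movie` ([time_lapse()]), `truth` (list of `vesicles`,
#'   `events`, `synapses` tibbles), `synapse_image` (matrix or `NULL`) and
#'   `paradigm` ([acquisition_paradigm()]).
#' @export
simulate_movie <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  withr::with_seed(sc$seed, simulate_movie_impl(sc))
}

simulate_movie_impl <- function(sc) {
  h <- sc$height; w <- sc$width; nt <- sc$n_frames
  kern <- punctum_kernel(sc$punctum_sigma_px)
  s9 <- sum(punctum_kernel(sc$punctum_sigma_px)[
    (nrow(kern) %/% 2):(nrow(kern) %/% 2 + 2),
    (ncol(kern) %/% 2):(ncol(kern) %/% 2 + 2)])

  # --- static scene ----------------------------------------------------------
  soma <- list(row = round(h / 2 + runif(1, -h / 8, h / 8)),
               col = round(w / 2 + runif(1, -w / 8, w / 8)))
  soma_img <- matrix(0, h, w)
  soma_img <- add_punctum(soma_img, soma$row, soma$col, sc$soma_brightness,
                          punctum_kernel(6))
  skel <- neurite_mask(h, w, soma)
  neur <- cpp_gaussian_blur(skel * sc$neurite_brightness, 1)
  base_fluo <- sc$diffuse_brightness + neur + soma_img

  # candidate vesicle sites: on neurites, away from borders
  cand <- which(cpp_gaussian_blur(skel * 1, 1.5) > 0.02, arr.ind = TRUE)
  margin <- 6
  cand <- cand[cand[, 1] > margin & cand[, 1] < h - margin &
               cand[, 2] > margin & cand[, 2] < w - margin, , drop = FALSE]

  ves <- sample_separated(cand, sc$n_vesicles, sc$vesicle_min_sep_px)
  vesicles <- tibble(row = as.integer(ves[, 1]), col = as.integer(ves[, 2]),
                     cluster = 1L)
  if (sc$cluster_sites > 0L) {
    extra <- purrr::map(seq_len(sc$cluster_sites), function(i) {
      # turn vesicle i into a cluster by adding close-packed companions
      off <- matrix(sample(c(-1L, 0L, 1L), 2 * (sc$cluster_size - 1L),
                           replace = TRUE), ncol = 2)
      tibble(row = vesicles$row[i] + off[, 1], col = vesicles$col[i] + off[, 2],
             cluster = i + 1L)
    })
    vesicles <- dplyr::bind_rows(vesicles, dplyr::bind_rows(extra))
  }

  # synapse sites + marker image
  synapses <- tibble(row = integer(0), col = integer(0))
  synapse_image <- NULL
  if (sc$n_synapses > 0L) {
    syn <- sample_separated(cand, sc$n_synapses, 5)
    synapses <- tibble(row = as.integer(syn[, 1]), col = as.integer(syn[, 2]))
    marker <- 0.15 * base_fluo
    skern <- punctum_kernel(1.2)
    for (i in seq_len(nrow(synapses)))
      marker <- add_punctum(marker, synapses$row[i], synapses$col[i], 400, skern)
    marker <- marker + rnorm(h * w, 0, 5)
    synapse_image <- round(pmax(pmin(marker + sc$camera_offset,
                                     sc$saturation_level), 0))
  }

  # --- fusion events ---------------------------------------------------------
  illum <- illumination_field(h, w, sc$illumination_gradient_strength)
  n_ev <- sc$n_events
  events <- tibble(row = integer(0), col = integer(0), start_frame = integer(0),
                   amplitude = numeric(0), peak_counts = numeric(0),
                   synaptic = logical(0))
  if (n_ev > 0L) {
    if (!is.na(sc$synaptic_event_fraction) && nrow(synapses) > 0L) {
      n_syn <- round(sc$synaptic_event_fraction * n_ev)
      syn_idx <- sample(nrow(synapses), n_syn)
      at_syn <- as.matrix(synapses[syn_idx, c("row", "col")])
      # extra-synaptic sites: vesicles far from every synapse
      dd <- outer(vesicles$row, synapses$row, "-")^2 +
            outer(vesicles$col, synapses$col, "-")^2
      far <- which(apply(dd, 1, min) > (sc$event_min_sep_px + 2)^2)
      ex <- as.matrix(vesicles[sample(far, n_ev - n_syn), c("row", "col")])
      sites <- rbind(at_syn, ex)
      syn_flag <- rep(c(TRUE, FALSE), c(n_syn, n_ev - n_syn))
    } else {
      pick <- sample_separated(as.matrix(vesicles[, c("row", "col")]), n_ev,
                               sc$event_min_sep_px)
      sites <- pick
      syn_flag <- rep(NA, n_ev)
    }
    amp <- runif(n_ev, sc$event_amplitude_range[1], sc$event_amplitude_range[2])
    last_start <- min(sc$stim_start_frame + sc$stim_len_frames - 1L +
                        sc$event_tail_frames, sc$nh4_start_frame - 1L)
    starts <- sample(sc$stim_start_frame:last_start, n_ev, replace = TRUE)
    # peak counts calibrated so the 3x3 ROI-mean dF/F0 equals the draw
    peak <- numeric(n_ev)
    for (i in seq_len(n_ev)) {
      r <- sites[i, 1]; c <- sites[i, 2]
      f0_roi <- mean((illum * base_fluo)[(r - 1):(r + 1), (c - 1):(c + 1)]) +
        sc$camera_offset
      peak[i] <- if (sc$event_unit_matched) sc$vesicle_brightness
                 else amp[i] * f0_roi * 9 / s9 / illum[r, c]
      if (sc$event_unit_matched)
        amp[i] <- peak[i] * illum[r, c] * s9 / 9 / f0_roi
    }
    events <- tibble(row = as.integer(sites[, 1]), col = as.integer(sites[, 2]),
                     start_frame = as.integer(starts), amplitude = amp,
                     peak_counts = peak, synaptic = syn_flag)
  }

  # --- render ----------------------------------------------------------------
  quenched <- matrix(0, h, w)
  dequench <- matrix(0, h, w)
  vkern <- kern
  for (i in seq_len(nrow(vesicles))) {
    quenched <- add_punctum(quenched, vesicles$row[i], vesicles$col[i],
                            sc$quenched_fraction * sc$vesicle_brightness, vkern)
    dq <- if (sc$fused_retain || !vesicle_fused(vesicles, events, i))
      sc$vesicle_brightness else sc$quenched_fraction * sc$vesicle_brightness
    dequench <- add_punctum(dequench, vesicles$row[i], vesicles$col[i], dq, vkern)
  }

  pre <- illum * (base_fluo + quenched)
  post <- if (sc$nh4_step) illum * (base_fluo + dequench) else pre
  mid <- (pre + post) / 2  # dequenching completes within 2 frames

  frames <- array(0, dim = c(h, w, nt))
  if (!sc$nh4_step) {
    frames[] <- as.vector(pre)
  } else {
    frames[, , seq_len(sc$nh4_start_frame - 1L)] <- as.vector(pre)
    frames[, , sc$nh4_start_frame] <- mid
    if (sc$nh4_start_frame < nt)
      frames[, , (sc$nh4_start_frame + 1L):nt] <- as.vector(post)
  }

  tau_f <- sc$event_decay_tau_s * sc$frame_rate_hz
  hw <- (nrow(kern) - 1L) %/% 2L
  for (i in seq_len(nrow(events))) {
    r <- events$row[i]; c <- events$col[i]; s <- events$start_frame[i]
    r0 <- max(1L, r - hw); r1 <- min(h, r + hw)
    c0 <- max(1L, c - hw); c1 <- min(w, c + hw)
    ksub <- kern[(r0:r1) - r + hw + 1L, (c0:c1) - c + hw + 1L, drop = FALSE]
    for (t in s:nt) {
      a <- events$peak_counts[i] * exp(-(t - s) / tau_f) * illum[r, c]
      if (a < 1) break
      frames[r0:r1, c0:c1, t] <- frames[r0:r1, c0:c1, t] + a * ksub
    }
  }

  if (sc$saturated_patch) {
    # bright square far from the soma, saturating only during NH4
    pr <- if (soma$row > h / 2) 10:20 else (h - 20):(h - 10)
    pc <- if (soma$col > w / 2) 10:20 else (w - 20):(w - 10)
    for (t in sc$nh4_start_frame:nt)
      frames[pr, pc, t] <- frames[pr, pc, t] + 2 * sc$saturation_level
  }

  signal <- frames + sc$camera_offset
  noisy <- rpois(length(signal), signal / sc$poisson_gain) * sc$poisson_gain +
    rnorm(length(signal), 0, sc$noise_gaussian_sd)
  frames <- array(pmin(pmax(round(noisy), 0), sc$saturation_level),
                  dim = dim(signal))

  paradigm <- acquisition_paradigm(sc$frame_rate_hz, sc$baseline_frames,
                                   sc$stim_start_frame, sc$stim_len_frames,
                                   sc$nh4_start_frame)
  list(
    movie = time_lapse(frames, sc$frame_rate_hz),
    truth = list(vesicles = vesicles, events = events, synapses = synapses),
    synapse_image = synapse_image,
    paradigm = paradigm
  )
}

vesicle_fused <- function(vesicles, events, i) {
  if (nrow(events) == 0L) return(FALSE)
  any(events$row == vesicles$row[i] & events$col == vesicles$col[i])
}

#' Named default scenarios
#'
#' Fixtures shared across the test suite:
#' * `clean`: the reference paradigm with 60 stimulus-locked events of 1.5-3
#'   dF/F0 and a 150-vesicle pool;
#' * `noisy`: the same scene with threefold read noise (exercises the
#'   baseline-subtraction branch);
#' * `null`: no fusion events (false-positive control);
#' * `pool`: 150 well-separated vesicles, 30 events with matched unit
#'   intensity and a 50% synaptic fraction (pool/release/synaptic recovery);
#' * `clustered_pool`: `pool` plus 20 three-vesicle cluster sites;
#' * `saturated`: `clean` plus a saturating patch outside the soma;
#' * `no_nh4`: no NH4Cl step and no events (QC exclusion 2a).
#'
#' @param seed Seed applied to every scenario.
#' @return Named list of [simulation_scenario()] objects.
#' @export
default_scenarios <- function(seed = 1L) {
  list(
    clean = simulation_scenario(seed = seed),
    noisy = simulation_scenario(noise_gaussian_sd = 9, seed = seed),
    null = simulation_scenario(n_events = 0L, seed = seed),
    pool = simulation_scenario(n_events = 30L, event_unit_matched = TRUE,
                               n_synapses = 40L,
                               synaptic_event_fraction = 0.5, seed = seed),
    clustered_pool = simulation_scenario(n_events = 30L,
                                         event_unit_matched = TRUE,
                                         cluster_sites = 20L, cluster_size = 3L,
                                         seed = seed),
    saturated = simulation_scenario(saturated_patch = TRUE, seed = seed),
    no_nh4 = simulation_scenario(n_events = 0L, nh4_step = FALSE, seed = seed)
  )
}

#' Match detected events to simulator ground truth
#'
#' Greedy nearest-pair matching: candidate (true, detected) pairs within
#' `dist_tol_px` are accepted in order of increasing distance, each event used
#' at most once.
#'
#' @param detection A `dcv_detection` or its ROI tibble.
#' @param truth_events Ground-truth events tibble from [simulate_movie()].
#' @param dist_tol_px Maximum center distance for a match.
#' @return One-row tibble: `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, `frac_start_within_1`, `mean_abs_start_error`.
#' @export
evaluate_detection <- function(detection, truth_events, dist_tol_px = 2) {
  rois <- if (inherits(detection, "dcv_detection")) detection$rois else detection
  nt <- nrow(truth_events); nd <- nrow(rois)
  if (nt == 0L || nd == 0L) {
    return(tibble(n_true = nt, n_detected = nd, n_matched = 0L,
                  recall = ifelse(nt == 0L, NA_real_, 0),
                  precision = ifelse(nd == 0L, NA_real_, 0),
                  frac_start_within_1 = NA_real_,
                  mean_abs_start_error = NA_real_))
  }
  d <- sqrt(outer(truth_events$row, rois$center_row, "-")^2 +
            outer(truth_events$col, rois$center_col, "-")^2)
  pairs <- which(d <= dist_tol_px, arr.ind = TRUE)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  err <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (used_t[i] || used_d[j]) next
    used_t[i] <- TRUE; used_d[j] <- TRUE
    err <- c(err, abs(rois$event_start_frame[j] - truth_events$start_frame[i]))
  }
  m <- sum(used_t)
  tibble(n_true = nt, n_detected = nd, n_matched = m,
         recall = m / nt, precision = m / nd,
         frac_start_within_1 = if (m) mean(err <= 1L) else NA_real_,
         mean_abs_start_error = if (m) mean(err) else NA_real_)
}
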