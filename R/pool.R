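# Total labeled DCV pool estimation from the NH4Cl dequenching window.

#' NH4Cl maximum-intensity projection
#'
#' Per-pixel maximum over the frames from NH4Cl onset to the end of the movie,
#' after subtracting the per-pixel mean of the pre-NH4 baseline window
#' (frames 1..`baseline_frames`), optionally min-max rescaled to 0-255.
#'
#' @param movie A [time_lapse()] object.
#' @param nh4_start_frame First frame of NH4Cl superfusion (< movie length).
#' @param baseline_frames Pre-NH4 baseline window length.
#' @param rescale Rescale to 0-255 (default `TRUE`).
#' @return 2-D numeric matrix.
#' @export
nh4_max_projection <- function(movie, nh4_start_frame, baseline_frames,
                               rescale = TRUE) {
  stopifnot(inherits(movie, "time_lapse"))
  nt <- n_frames(movie)
  if (nh4_start_frame >= nt) stopf("empty NH4 window (nh4_start_frame >= movie length)")
  d <- dim(movie$frames)
  base <- baseline_image(movie$frames, baseline_frames)
  w <- nh4_start_frame:nt
  m <- matrix(movie$frames[, , w], ncol = length(w))
  proj <- matrix(do.call(pmax, asplit(m, 2)), d[1], d[2]) - base
  if (rescale) rescale_0_255(proj) else proj
}

#' Automatic SNR (prominence) from the NH4Cl response
#'
#' Used when the pool SNR parameter is 0: the projection's background is taken
#' as the pixels below its Triangle threshold, and the prominence is set to
#' `mean + 3 * SD` of that background. When the thresholded "background" fails
#' to behave like one -- it holds less than half the image (the threshold
#' landed inside the bulk) or has zero spread (flat, e.g. noiseless zeros) --
#' the statistics fall back to the whole projection. A documented heuristic;
#' the reference tool's exact statistic is unstated.
#'
#' @param projection Rescaled (0-255) NH4 max projection.
#' @return Prominence value.
#' @export
auto_snr_from_nh4 <- function(projection) {
  if (all(projection == 0)) stopf("all-zero projection")
  thr <- triangle_threshold(projection)
  bg <- projection[projection < thr]
  if (length(bg) < 0.5 * length(projection) || length(bg) < 2L || sd(bg) == 0)
    bg <- as.numeric(projection)
  mean(bg) + 3 * sd(bg)
}

# Sum of an image over a (2w+1)^2 window around a center.
window_integral <- function(img, row, col, w) {
  d <- dim(img)
  sum(img[max(1L, row - w):min(d[1], row + w),
          max(1L, col - w):min(d[2], col + w)])
}

# Mean of the pixels below the image's Triangle threshold (the background
# level); 0 when the image is constant.
background_level <- function(img) {
  if (max(img) == min(img)) return(0)
  bg <- img[img < triangle_threshold(img)]
  if (length(bg) < 2L) 0 else mean(bg)
}

#' Estimate the total pHluorin-labeled DCV pool
#'
#' Three estimates per cell:
#' * `raw_pool`: count of prominence maxima in the NH4 max projection
#'   (prominence = `params$snr`, or [auto_snr_from_nh4()] when `snr = 0`);
#' * `fused_corrected`: total above-background integrated projection intensity
#'   divided by the mean integrated intensity of the detected fusion events;
#' * `puncta_corrected`: the same total divided by the median integrated
#'   intensity of isolated single puncta (puncta within +/-50% of the modal
#'   punctum intensity).
#'
#' Integrated intensities are window sums (half-width `integration_radius_px`)
#' over the background-corrected projection (the mean of the pixels below the
#' Triangle threshold is subtracted, so punctum fluxes are captured with their
#' tails); event units are the matching background-corrected window sums of
#' the normalized movie at each event's peak frame, baseline subtracted -- the
#' same functional on both sides, so the ratio is an unbiased vesicle count
#' when event and punctum unit intensities match. The movie is normalized with
#' `params$normalization` before projection, mirroring the fusion-detection
#' branch. Saturated pixels (>= `saturation_level` during the NH4 window)
#' outside the soma are counted for QC; the soma mask is the dilated largest
#' connected component above the Triangle threshold of the baseline mean
#' image (the soma is the brightest structure before stimulation, whereas a
#' saturating artifact would dominate the NH4 projection and masquerade as
#' the soma).
#'
#' @param movie Raw [time_lapse()] movie.
#' @param paradigm An [acquisition_paradigm()].
#' @param events Optional Vesicle Parameters tibble from [measure_events()]
#'   (required for `fused_corrected`).
#' @param params A [detection_params()]; `pool_snr = 0` (the default) triggers
#'   automatic SNR estimation from the NH4Cl response.
#' @param integration_radius_px Half-width of the integration window
#'   (default 3, i.e. 7 x 7, covering a ~3 px punctum with its tails).
#' @param saturation_level Bit-depth maximum (default 65535 for 16-bit).
#' @param min_punctum_sd Detectability floor: a punctum must rise this many
#'   background SDs above the projection background (prominence alone is
#'   relative and cannot reject a noise-only projection whose global maximum
#'   is always maximally prominent).
#' @return A `pool_estimate` object.
#' @export
estimate_pool <- function(movie, paradigm, events = NULL,
                          params = detection_params(),
                          integration_radius_px = 3L,
                          saturation_level = 65535,
                          min_punctum_sd = 10) {
  stopifnot(inherits(movie, "time_lapse"),
            inherits(paradigm, "acquisition_paradigm"))
  norm <- normalize_movie(movie, params$normalization, paradigm)
  proj_raw <- nh4_max_projection(norm, paradigm$nh4_start_frame,
                                 paradigm$baseline_frames, rescale = FALSE)
  proj <- rescale_0_255(proj_raw)

  snr_used <- if (params$pool_snr <= 0) auto_snr_from_nh4(proj) else params$pool_snr
  puncta <- find_candidate_maxima(proj, snr_used)
  # detectability: prominence is relative (the global maximum of a rescaled
  # image always has prominence 255, even for pure noise), so puncta must also
  # rise min_punctum_sd background-SDs above the projection background
  thr0 <- triangle_threshold(proj_raw)
  bgpix <- proj_raw[proj_raw < thr0]
  if (nrow(puncta) > 0L && length(bgpix) >= 2L && sd(bgpix) > 0) {
    cut <- mean(bgpix) + min_punctum_sd * sd(bgpix)
    puncta <- puncta[proj_raw[cbind(puncta$row, puncta$col)] >= cut, ]
  }
  raw_pool <- nrow(puncta)

  # dequenching response: relative rise of the frame mean at NH4 onset.
  # A recording with no response has no detectable puncta regardless of what
  # the spot caller picks out of the noise (QC exclusion 2a).
  nh4_w <- paradigm$nh4_start_frame:n_frames(movie)
  pre_w <- max(1L, paradigm$nh4_start_frame - 11L):(paradigm$nh4_start_frame - 1L)
  nh4_rise <- mean(movie$frames[, , nh4_w]) / mean(movie$frames[, , pre_w]) - 1

  qc_flags <- character(0)
  if (raw_pool == 0L || nh4_rise < 0.01)
    qc_flags <- c(qc_flags, "no_nh4_puncta")

  # saturation outside the soma (QC exclusion)
  soma <- soma_mask_from_image(baseline_image(movie$frames,
                                              paradigm$baseline_frames))
  w <- paradigm$nh4_start_frame:n_frames(movie)
  d <- dim(movie$frames)
  sat_any <- matrix(
    rowSums(matrix(movie$frames[, , w] >= saturation_level,
                   ncol = length(w))) > 0, d[1], d[2])
  n_saturated <- sum(sat_any & !soma)
  if (n_saturated > 0L) qc_flags <- c(qc_flags, "nh4_saturation")

  # integrated intensities on the background-corrected projection
  shifted <- proj_raw - background_level(proj_raw)
  total <- NA_real_; unit_punctum <- NA_real_; puncta_corrected <- NA_real_
  if (raw_pool > 0L) {
    integrals <- vapply(seq_len(raw_pool), function(i)
      window_integral(shifted, puncta$row[i], puncta$col[i],
                      integration_radius_px), numeric(1))
    total <- sum(integrals)
    modal <- if (raw_pool >= 3L) {
      den <- density(integrals)
      den$x[which.max(den$y)]
    } else stats::median(integrals)
    isolated <- integrals >= 0.5 * modal & integrals <= 1.5 * modal
    if (any(isolated)) {
      unit_punctum <- stats::median(integrals[isolated])
      puncta_corrected <- total / unit_punctum
    }
  }

  # event unit intensity, measured the same way on the normalized movie
  unit_event <- NA_real_; fused_corrected <- NA_real_
  n_events <- if (is.null(events)) 0L else nrow(events)
  if (n_events > 0L && raw_pool > 0L) {
    base <- baseline_image(norm$frames, paradigm$baseline_frames)
    ev_int <- vapply(seq_len(n_events), function(i) {
      sf <- events$start_frame[i]
      ef <- min(sf + events$duration_frames[i] - 1L, paradigm$nh4_start_frame - 1L)
      # peak frame of the event on the normalized movie at the event center
      r <- events$center_row[i]; c <- events$center_col[i]
      pk <- sf + which.max(norm$frames[r, c, sf:ef]) - 1L
      dimg <- norm$frames[, , pk] - base
      window_integral(dimg - background_level(dimg), r, c,
                      integration_radius_px)
    }, numeric(1))
    unit_event <- mean(ev_int)
    if (unit_event > 0) fused_corrected <- total / unit_event
  }

  structure(
    list(raw_pool = raw_pool, fused_corrected = fused_corrected,
         puncta_corrected = puncta_corrected, n_events = n_events,
         snr_used = snr_used, nh4_rise = nh4_rise, total_intensity = total,
         unit_punctum = unit_punctum, unit_event = unit_event,
         n_saturated_px = n_saturated, soma_mask = soma,
         puncta = puncta, qc_flags = qc_flags),
    class = "pool_estimate"
  )
}

# Largest 8-connected component above the Triangle threshold, dilated (used
# only for the saturation QC).
soma_mask_from_image <- function(img, dilate_radius = 3L) {
  thr <- triangle_threshold(img)
  fg <- img > thr
  if (!any(fg)) return(fg)
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  dilate_mask(lab == which.max(sizes), dilate_radius)
}

#' @export
print.pool_estimate <- function(x, ...) {
  cat(sprintf("<pool_estimate> raw %d | fused-corrected %.1f | puncta-corrected %.1f (snr %.1f)\n",
              x$raw_pool, x$fused_corrected, x$puncta_corrected, x$snr_used))
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' DCV release fraction
#'
#' Number of detected fusion events divided by the selected pool estimate.
#'
#' @param n_events Number of fusion events.
#' @param pool A `pool_estimate` (or a bare number).
#' @param which `"raw"`, `"fused"` or `"puncta"`.
#' @return Fraction (0 when `n_events` is 0).
#' @export
release_fraction <- function(n_events, pool,
                             which = c("raw", "fused", "puncta")) {
  which <- match.arg(which)
  p <- if (inherits(pool, "pool_estimate")) {
    switch(which, raw = pool$raw_pool, fused = pool$fused_corrected,
           puncta = pool$puncta_corrected)
  } else pool
  if (n_events == 0L) return(0)
  if (is.na(p) || p <= 0) stopf("selected pool estimate is zero or undefined")
  n_events / p
}
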