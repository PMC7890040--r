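# Per-cell summaries, QC flags, batch collection across recordings.

#' Histogram of fusion-event start times
#'
#' Counts of event start times per half-open bin `[k*bin, (k+1)*bin)` from
#' t = 0 to the end of the recording. For 2 Hz data a bin of 0.5 s (per frame)
#' or 1.5 s (per stimulation train) is recommended.
#'
#' @param events Vesicle Parameters tibble (needs `start_time_s`).
#' @param bin_s Bin width in seconds (> 0).
#' @param t_end_s End of the recording in seconds (last bin edge is the first
#'   multiple of `bin_s` at or past it).
#' @return Tibble with `bin_start_s`, `bin_end_s`, `count`.
#' @export
event_histogram <- function(events, bin_s, t_end_s) {
  if (bin_s <= 0) stopf("bin_s must be > 0")
  n_bins <- ceiling(t_end_s / bin_s)
  edges <- seq(0, by = bin_s, length.out = n_bins + 1L)
  idx <- floor(events$start_time_s / bin_s) + 1L
  counts <- tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
  tibble(bin_start_s = edges[-(n_bins + 1L)], bin_end_s = edges[-1L],
         count = counts)
}

#' Cumulative event counts
#'
#' Prefix sums of a histogram; optionally normalized to the total number of
#' events (ends at 1 when the total is positive).
#'
#' @param histogram Tibble from [event_histogram()] or a bare counts vector.
#' @param normalize Divide by the total count.
#' @return Numeric vector of running counts.
#' @export
cumulative_counts <- function(histogram, normalize = FALSE) {
  counts <- if (is.data.frame(histogram)) histogram$count else histogram
  if (any(counts < 0)) stopf("counts must be non-negative")
  cc <- cumsum(counts)
  if (normalize && length(cc) && cc[length(cc)] > 0) cc <- cc / cc[length(cc)]
  cc
}

#' Quality-control flags for a recording
#'
#' Numeric proxies for the exclusion criteria; flags annotate, they never
#' delete data.
#' * `no_nh4_puncta`: no detectable puncta after NH4Cl superfusion -- the raw
#'   pool is empty, or the frame-mean intensity fails to rise by at least 1%
#'   at NH4 onset (no dequenching response, so any counted puncta are noise);
#' * `baseline_drift`: focus-drift proxy -- the frame-mean intensity over the
#'   pre-stimulation period drifts by more than `drift_tol` (relative);
#' * `nh4_saturation`: pixels outside the soma reach the bit-depth maximum
#'   during NH4Cl superfusion;
#' * `prestim_bright_puncta`: proxy for a large population of non-acidic,
#'   already-bright vesicles -- more than `prestim_frac` of the final pool is
#'   already visible as puncta in the baseline image.
#'
#' @param movie Raw [time_lapse()].
#' @param paradigm An [acquisition_paradigm()].
#' @param pool Optional `pool_estimate` (enables the pool-based flags).
#' @param drift_tol Relative drift tolerance (default 0.2).
#' @param prestim_frac Pre-stimulation punctum fraction threshold (default
#'   0.2).
#' @return Tibble with `flag`, `triggered`, `value`, `threshold`.
#' @export
qc_evaluate <- function(movie, paradigm, pool = NULL, drift_tol = 0.2,
                        prestim_frac = 0.2) {
  pre <- seq_len(min(paradigm$stim_start_frame) - 1L)
  fmeans <- vapply(pre, function(t) mean(movie$frames[, , t]), numeric(1))
  k <- max(3L, length(pre) %/% 10L)
  drift <- abs(mean(tail(fmeans, k)) - mean(head(fmeans, k))) /
    mean(head(fmeans, k))

  rows <- list(tibble(flag = "baseline_drift", triggered = drift > drift_tol,
                      value = drift, threshold = drift_tol))
  if (!is.null(pool)) {
    rows <- c(rows, list(
      tibble(flag = "no_nh4_puncta",
             triggered = pool$raw_pool == 0L || pool$nh4_rise < 0.01,
             value = pool$nh4_rise, threshold = 0.01),
      tibble(flag = "nh4_saturation", triggered = pool$n_saturated_px > 0L,
             value = as.numeric(pool$n_saturated_px), threshold = 0)
    ))
    if (pool$raw_pool > 0L) {
      base <- baseline_image(movie$frames, paradigm$baseline_frames)
      n_pre <- nrow(find_candidate_maxima(base, max(pool$snr_used, 1)))
      frac <- n_pre / pool$raw_pool
      rows <- c(rows, list(
        tibble(flag = "prestim_bright_puncta", triggered = frac > prestim_frac,
               value = frac, threshold = prestim_frac)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Analyze one cell end to end
#'
#' Detection, per-event measurement, optional synaptic classification, pool
#' estimation, release fractions and QC flags for one recording.
#'
#' @param movie Raw [time_lapse()].
#' @param paradigm An [acquisition_paradigm()].
#' @param params A [detection_params()].
#' @param synapse_image Optional marker image for the synapse mask.
#' @param cell_id Identifier for the output tables.
#' @param synapse_radius_px Mask filter radius (see [make_synapse_mask()]).
#' @param synaptic_tolerance_px Synaptic distance tolerance.
#' @param duration_sd Return-to-baseline criterion (see [event_duration()]).
#' @return A `dcv_cell` object: `events` (Vesicle Parameters tibble), `pool`
#'   (one-row Pool Values tibble), `qc`, plus the underlying `detection`,
#'   `pool_estimate` and `mask`.
#' @export
analyze_cell <- function(movie, paradigm, params = detection_params(),
                         synapse_image = NULL, cell_id = "cell",
                         synapse_radius_px = 3, synaptic_tolerance_px = 1,
                         duration_sd = 2) {
  detection <- detect_fusion_events(movie, paradigm, params)
  events <- measure_events(detection, cell_id = cell_id,
                           duration_sd = duration_sd)
  mask <- NULL
  if (!is.null(synapse_image)) {
    mask <- make_synapse_mask(synapse_image, synapse_radius_px)
    if (any(mask$mask))
      events <- classify_synaptic(events, mask, synaptic_tolerance_px)
  }
  pool_est <- estimate_pool(movie, paradigm, events, params)
  qc <- qc_evaluate(movie, paradigm, pool_est)
  flags <- unique(c(pool_est$qc_flags, qc$flag[qc$triggered]))
  rf <- function(which) {
    tryCatch(release_fraction(nrow(events), pool_est, which),
             error = function(e) NA_real_)
  }
  pool_tbl <- tibble(
    cell_id = cell_id, raw_pool = pool_est$raw_pool,
    fused_corrected = pool_est$fused_corrected,
    puncta_corrected = pool_est$puncta_corrected,
    n_events = nrow(events),
    release_fraction_raw = rf("raw"),
    release_fraction_fused = rf("fused"),
    release_fraction_puncta = rf("puncta"),
    qc_flags = paste(flags, collapse = ";")
  )
  structure(
    list(events = events, pool = pool_tbl, qc = qc, detection = detection,
         pool_estimate = pool_est, mask = mask, cell_id = cell_id,
         paradigm = paradigm),
    class = "dcv_cell"
  )
}

#' @export
print.dcv_cell <- function(x, ...) {
  cat(sprintf("<dcv_cell> %s: %d events, raw pool %d%s\n", x$cell_id,
              nrow(x$events), x$pool$raw_pool,
              if (nzchar(x$pool$qc_flags)) paste0(" [", x$pool$qc_flags, "]")
              else ""))
  invisible(x)
}

#' Re-measure a saved ROI set
#'
#' Collection path for recordings whose ROI sets were saved earlier: traces are
#' re-extracted from the movie for the stored ROIs and the per-event metrics
#' are recomputed, without re-running detection.
#'
#' @param movie Raw [time_lapse()].
#' @param rois ROI tibble (e.g. from [read_roi_set()]).
#' @param paradigm An [acquisition_paradigm()].
#' @inheritParams measure_events
#' @return Vesicle Parameters tibble.
#' @export
measure_roi_set <- function(movie, rois, paradigm, cell_id = "cell",
                            duration_sd = 2) {
  traces <- roi_traces(movie, rois)
  measure_events(rois, cell_id = cell_id, duration_sd = duration_sd,
                 traces = traces, paradigm = paradigm)
}

#' Collect all recordings in a folder
#'
#' Scans `folder` for time-lapse movies (`<stem>.tif`, excluding
#' `*_synapse.tif`) and analyzes each cell with `cell_id = stem`. When
#' `<stem>_rois.csv` exists the stored ROI set is re-measured instead of
#' re-running detection; `<stem>_synapse.tif`, when present, provides the
#' synapse mask. Cells with a missing required pair (no mask while
#' `synaptic = TRUE`) are skipped with a warning.
#'
#' @param folder Directory with the documented layout.
#' @param paradigm An [acquisition_paradigm()] shared by all recordings, or
#'   `NULL` to read `config.yaml` in the folder.
#' @param params A [detection_params()] (ignored when `config.yaml` is used).
#' @param synaptic Require and use synapse masks.
#' @param frame_rate_hz Frame rate passed to [read_stack()]; defaults to the
#'   paradigm's.
#' @inheritParams analyze_cell
#' @return List with `vesicles` and `pools` tibbles (sorted by `cell_id`) and
#'   `cells` (the per-cell `dcv_cell` objects).
#' @export
collect_folder <- function(folder, paradigm = NULL, params = detection_params(),
                           synaptic = FALSE, frame_rate_hz = NULL,
                           synapse_radius_px = 3, duration_sd = 2) {
  if (!dir.exists(folder)) stopf("folder not found: %s", folder)
  if (is.null(paradigm)) {
    cfg_path <- file.path(folder, "config.yaml")
    if (!file.exists(cfg_path)) stopf("no paradigm given and no config.yaml in %s", folder)
    cfg <- read_analysis_config(cfg_path)
    paradigm <- cfg$paradigm; params <- cfg$params
  }
  frame_rate_hz <- frame_rate_hz %||% paradigm$frame_rate_hz
  movies <- sort(list.files(folder, pattern = "\\.tif{1,2}$"))
  movies <- movies[!grepl("_synapse\\.tif{1,2}$", movies)]
  cells <- list()
  for (f in movies) {
    stem <- sub("\\.tif{1,2}$", "", f)
    mask_path <- file.path(folder, paste0(stem, "_synapse.tif"))
    if (synaptic && !file.exists(mask_path)) {
      warn(sprintf("cell '%s' skipped: synapse mask missing", stem))
      next
    }
    movie <- read_stack(file.path(folder, f), frame_rate_hz)
    synapse_image <- if (file.exists(mask_path)) read_image(mask_path) else NULL
    roi_path <- file.path(folder, paste0(stem, "_rois.csv"))
    if (file.exists(roi_path)) {
      rois <- read_roi_set(roi_path)
      events <- measure_roi_set(movie, rois, paradigm, cell_id = stem,
                                duration_sd = duration_sd)
      if (!is.null(synapse_image)) {
        msk <- make_synapse_mask(synapse_image, synapse_radius_px)
        if (any(msk$mask)) events <- classify_synaptic(events, msk)
      }
      pool_est <- estimate_pool(movie, paradigm, events, params)
      qc <- qc_evaluate(movie, paradigm, pool_est)
      flags <- unique(c(pool_est$qc_flags, qc$flag[qc$triggered]))
      rf <- function(which) tryCatch(release_fraction(nrow(events), pool_est, which),
                                     error = function(e) NA_real_)
      cell <- structure(
        list(events = events,
             pool = tibble(cell_id = stem, raw_pool = pool_est$raw_pool,
                           fused_corrected = pool_est$fused_corrected,
                           puncta_corrected = pool_est$puncta_corrected,
                           n_events = nrow(events),
                           release_fraction_raw = rf("raw"),
                           release_fraction_fused = rf("fused"),
                           release_fraction_puncta = rf("puncta"),
                           qc_flags = paste(flags, collapse = ";")),
             qc = qc, detection = NULL, pool_estimate = pool_est, mask = NULL,
             cell_id = stem, paradigm = paradigm),
        class = "dcv_cell")
    } else {
      cell <- analyze_cell(movie, paradigm, params,
                           synapse_image = synapse_image, cell_id = stem,
                           synapse_radius_px = synapse_radius_px,
                           duration_sd = duration_sd)
    }
    cells[[stem]] <- cell
  }
  if (!length(cells))
    return(list(vesicles = tibble(), pools = tibble(), cells = cells))
  vesicles <- dplyr::arrange(dplyr::bind_rows(purrr::map(cells, "events")),
                             .data$cell_id)
  pools <- dplyr::arrange(dplyr::bind_rows(purrr::map(cells, "pool")),
                          .data$cell_id)
  list(vesicles = vesicles, pools = pools, cells = cells)
}
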