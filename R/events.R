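# Per-event metrics: timing, amplitude, duration, inter-event distances.

#' Event start time in seconds
#'
#' `(start_frame - 1) / frame_rate_hz`: frame 1 is time 0.
#'
#' @param start_frame 1-based start frame (>= 1).
#' @param frame_rate_hz Imaging frequency.
#' @return Seconds.
#' @export
event_time <- function(start_frame, frame_rate_hz) {
  if (any(start_frame < 1)) stopf("start_frame must be >= 1")
  (start_frame - 1) / frame_rate_hz
}

# Baseline level and spread of a trace: mean and sample SD of frames
# 1..baseline_frames.
trace_baseline <- function(trace, baseline_frames) {
  b <- trace[seq_len(baseline_frames)]
  list(f0 = mean(b), sd0 = sd(b))
}

#' Event duration in frames
#'
#' Number of consecutive frames from the start during which the trace stays
#' above `F0 + duration_sd * SD0`, where `F0` and `SD0` are the mean and sample
#' SD of the baseline window. The start frame itself always counts, so the
#' duration is at least 1. Durations are capped at
#' `nh4_start_frame - start_frame`; events still
#' above threshold at the cap are flagged persistent (NH4 dequenching would
#' contaminate the decay).
#'
#' @param trace Mean ROI intensity per frame.
#' @param start_frame 1-based event start.
#' @param baseline_frames Baseline window length.
#' @param nh4_start_frame NH4Cl onset frame.
#' @param duration_sd Return-to-baseline criterion in baseline-SD units
#'   (default 2).
#' @return List with `duration_frames` and `persistent`.
#' @export
event_duration <- function(trace, start_frame, baseline_frames, nh4_start_frame,
                           duration_sd = 2) {
  bl <- trace_baseline(trace, baseline_frames)
  thr <- bl$f0 + duration_sd * bl$sd0
  cap <- nh4_start_frame - start_frame
  run <- 0L
  for (f in start_frame:(start_frame + cap - 1L)) {
    if (f > length(trace) || trace[f] <= thr) break
    run <- run + 1L
  }
  list(duration_frames = max(run, 1L), persistent = (run >= cap))
}

#' Event amplitude in dF/F0 units
#'
#' `F0` is the mean ROI trace over the baseline window; the amplitude is
#' `(max(trace) over the event - F0) / F0`, with the event spanning from the
#' start frame to the return to baseline (the [event_duration()] criterion) or
#' the NH4Cl onset, whichever comes first.
#'
#' @inheritParams event_duration
#' @return List with `peak_dff`, `f0`, `valid` (`FALSE` when `F0 <= 0`, in
#'   which case the ROI is excluded from dF/F0 statistics) and `dff_integral`
#'   (summed dF/F0 over the event frames).
#' @export
event_amplitude <- function(trace, start_frame, baseline_frames,
                            nh4_start_frame, duration_sd = 2) {
  bl <- trace_baseline(trace, baseline_frames)
  if (bl$f0 <= 0)
    return(list(peak_dff = NA_real_, f0 = bl$f0, valid = FALSE,
                dff_integral = NA_real_))
  dur <- event_duration(trace, start_frame, baseline_frames, nh4_start_frame,
                        duration_sd)
  idx <- start_frame:(start_frame + dur$duration_frames - 1L)
  list(peak_dff = (max(trace[idx]) - bl$f0) / bl$f0,
       f0 = bl$f0, valid = TRUE,
       dff_integral = sum((trace[idx] - bl$f0) / bl$f0))
}

#' Distance to the nearest other fusion event
#'
#' Euclidean distance between ROI centers; with a single event the distance is
#' undefined and reported as `NA` (not 0).
#'
#' @param events Tibble with `center_row` and `center_col`.
#' @return Numeric vector, one value per event.
#' @export
nearest_event_distance <- function(events) {
  n <- nrow(events)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(NA_real_)
  d <- as.matrix(stats::dist(cbind(events$center_row, events$center_col)))
  diag(d) <- Inf
  unname(apply(d, 1L, min))
}

#' Vesicle Parameters table for one cell
#'
#' Builds the per-event quantification table from a detection result: start
#' frame and time, duration (with persistence flag), peak dF/F0 amplitude and
#' its integral, and distance to the nearest other event. Synaptic annotation
#' columns are initialized to `NA` and filled by [classify_synaptic()] when a
#' synapse mask is available.
#'
#' @param detection A `dcv_detection` from [detect_fusion_events()], or an ROI
#'   tibble paired with `traces`.
#' @param cell_id Identifier copied into the table.
#' @param duration_sd Return-to-baseline criterion (see [event_duration()]).
#' @param traces,paradigm Override the detection's traces/paradigm (used when
#'   re-measuring saved ROI sets).
#' @return Tibble, one row per event.
#' @export
measure_events <- function(detection, cell_id = "cell", duration_sd = 2,
                           traces = NULL, paradigm = NULL) {
  if (inherits(detection, "dcv_detection")) {
    rois <- detection$rois
    traces <- traces %||% detection$traces
    paradigm <- paradigm %||% detection$paradigm
  } else {
    rois <- detection
    if (is.null(traces) || is.null(paradigm))
      stopf("traces and paradigm are required with a bare ROI tibble")
  }
  n <- nrow(rois)
  if (n == 0L) {
    return(tibble(cell_id = character(0), roi_id = character(0),
                  label = character(0), center_row = integer(0),
                  center_col = integer(0), start_frame = integer(0),
                  start_time_s = numeric(0), duration_frames = integer(0),
                  persistent = logical(0), f0 = numeric(0),
                  peak_dff = numeric(0), dff_integral = numeric(0),
                  valid_f0 = logical(0), synaptic = logical(0),
                  dist_to_synapse_px = numeric(0),
                  dist_to_nearest_event_px = numeric(0)))
  }
  bf <- paradigm$baseline_frames
  nh4 <- paradigm$nh4_start_frame
  per <- purrr::map(seq_len(n), function(i) {
    tr <- traces[, i]
    sf <- rois$event_start_frame[i]
    dur <- event_duration(tr, sf, bf, nh4, duration_sd)
    amp <- event_amplitude(tr, sf, bf, nh4, duration_sd)
    tibble(duration_frames = dur$duration_frames, persistent = dur$persistent,
           f0 = amp$f0, peak_dff = amp$peak_dff,
           dff_integral = amp$dff_integral, valid_f0 = amp$valid)
  })
  out <- dplyr::bind_cols(
    tibble(cell_id = cell_id, roi_id = rois$roi_id, label = rois$label,
           center_row = rois$center_row, center_col = rois$center_col,
           start_frame = rois$event_start_frame,
           start_time_s = event_time(rois$event_start_frame,
                                     paradigm$frame_rate_hz)),
    dplyr::bind_rows(per)
  )
  out$synaptic <- NA
  out$dist_to_synapse_px <- NA_real_
  out$dist_to_nearest_event_px <- nearest_event_distance(out)
  out
}
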