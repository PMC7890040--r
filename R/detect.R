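# Fusion-event detection: temporal SD projection of the stimulation window,
# prominence-based spot calling, greedy non-redundant ROI placement, and
# rolling-statistics event-start assignment on the raw traces.

#' Acquisition paradigm
#'
#' Frame bookkeeping for a recording: baseline window, stimulation block(s) and
#' NH4Cl onset. All frame indices are 1-based. With the reference paradigm
#' (2 Hz; 30 s baseline; 16 trains of 50 APs at 50 Hz, i.e. 24 s rounded up to
#' 50 frames; NH4Cl 50 s after stimulation onset) this is
#' `acquisition_paradigm(2, 30, 61, 50, 160)`.
#'
#' @param frame_rate_hz Acquisitions per second.
#' @param baseline_frames Rolling-window size (and baseline-average length) in
#'   frames.
#' @param stim_start_frame First frame of each stimulation block (vector for
#'   multiple blocks).
#' @param stim_len_frames Length of each stimulation block in frames.
#' @param nh4_start_frame First frame of NH4Cl superfusion.
#' @return An `acquisition_paradigm` list.
#' @export
acquisition_paradigm <- function(frame_rate_hz, baseline_frames,
                                 stim_start_frame, stim_len_frames,
                                 nh4_start_frame) {
  if (!is_scalar_number(frame_rate_hz) || frame_rate_hz <= 0)
    stopf("frame_rate_hz must be > 0")
  stim_start_frame <- sort(as.integer(stim_start_frame))
  if (length(stim_start_frame) < 1L) stopf("need at least one stimulation block")
  if (baseline_frames >= stim_start_frame[1])
    stopf("baseline_frames must be < stim_start_frame")
  if (max(stim_start_frame) + stim_len_frames - 1L >= nh4_start_frame)
    stopf("stimulation must end before nh4_start_frame")
  structure(
    list(frame_rate_hz = frame_rate_hz,
         baseline_frames = as.integer(baseline_frames),
         stim_start_frame = stim_start_frame,
         stim_len_frames = as.integer(stim_len_frames),
         nh4_start_frame = as.integer(nh4_start_frame),
         n_stimulations = length(stim_start_frame)),
    class = "acquisition_paradigm"
  )
}

# Frame ranges of the stimulation blocks.
stim_windows <- function(paradigm) {
  lapply(paradigm$stim_start_frame, function(s)
    seq.int(s, s + paradigm$stim_len_frames - 1L))
}

#' Detection parameters
#'
#' @param snr Prominence threshold for spot calling, on the 0-255 scale of the
#'   min-max rescaled SD projection.
#' @param pool_snr Prominence threshold for punctum counting on the NH4
#'   projection; 0 (the default) estimates it automatically from the NH4Cl
#'   response ([auto_snr_from_nh4()]).
#' @param detection_threshold_sd In baseline-subtraction mode only: candidate
#'   pixels must additionally exceed mean + this many SDs of the normalized
#'   movie's stimulation-window intensity.
#' @param cleaning_threshold_sd Event-start threshold, in multiples of the
#'   rolling SD (trailing window of `baseline_frames`).
#' @param roi_size_px Odd side length of the square ROIs (default 3).
#' @param max_overlap_px Maximum pixels two retained ROIs may share; defaults to
#'   [max_overlap_for_roi()], i.e. a third of the ROI area, and may not exceed
#'   it.
#' @param normalization A [normalization_params()] object.
#' @return A `detection_params` list.
#' @export
detection_params <- function(snr = 15, pool_snr = 0,
                             detection_threshold_sd = 2,
                             cleaning_threshold_sd = 5,
                             roi_size_px = 3L, max_overlap_px = NULL,
                             normalization = normalization_params()) {
  if (!is_scalar_number(snr) || snr < 0 || snr > 255)
    stopf("snr must be in [0, 255]")
  if (!is_scalar_number(pool_snr) || pool_snr < 0 || pool_snr > 255)
    stopf("pool_snr must be in [0, 255]")
  if (roi_size_px %% 2L != 1L || roi_size_px < 1L)
    stopf("roi_size_px must be odd and >= 1")
  cap <- max_overlap_for_roi(roi_size_px)
  max_overlap_px <- max_overlap_px %||% cap
  if (max_overlap_px > cap)
    stopf("max_overlap_px must be at most a third of the ROI area (%d px)", cap)
  stopifnot(inherits(normalization, "normalization_params"))
  structure(
    list(snr = snr, pool_snr = pool_snr,
         detection_threshold_sd = detection_threshold_sd,
         cleaning_threshold_sd = cleaning_threshold_sd,
         roi_size_px = as.integer(roi_size_px),
         max_overlap_px = as.integer(max_overlap_px),
         normalization = normalization),
    class = "detection_params"
  )
}

#' Paradigm arithmetic
#'
#' `frames_for_duration()` converts a duration in seconds to frames
#' (`round(seconds * frame_rate_hz)`); `round_stim_window()` rounds a
#' stimulation duration in frames up to the closest multiple of 10 (48 frames
#' of 16 x 50 AP trains at 2 Hz become a 50-frame stimulation window);
#' `max_overlap_for_roi()` gives the largest allowed ROI overlap,
#' `floor(roi_size_px^2 / 3)` (3 px for the default 3 x 3 ROI).
#'
#' @param seconds Duration (>= 0).
#' @param frame_rate_hz Acquisitions per second.
#' @return Frame count (integer).
#' @export
frames_for_duration <- function(seconds, frame_rate_hz) {
  if (any(seconds < 0)) stopf("duration must be >= 0")
  as.integer(round(seconds * frame_rate_hz))
}

#' @rdname frames_for_duration
#' @param frames Stimulation duration in frames (>= 1).
#' @export
round_stim_window <- function(frames) {
  stopifnot(all(frames >= 1))
  as.integer(10 * ceiling(frames / 10))
}

#' @rdname frames_for_duration
#' @param roi_size_px Side length of the square ROI (>= 1).
#' @export
max_overlap_for_roi <- function(roi_size_px) {
  stopifnot(all(roi_size_px >= 1))
  as.integer(roi_size_px^2 %/% 3)
}

#' Temporal standard-deviation projection
#'
#' Per-pixel sample standard deviation (n - 1 denominator) over a frame window.
#' With multiple stimulation blocks, one projection per block combined by
#' pixel-wise maximum.
#'
#' @param movie A [time_lapse()] object (usually normalized).
#' @param windows Integer vector of frames, or a list of such vectors (one per
#'   stimulation block). Each window needs >= 2 frames. An
#'   [acquisition_paradigm()] may be given instead, meaning its stimulation
#'   block(s).
#' @return 2-D numeric matrix.
#' @export
sd_projection <- function(movie, windows) {
  stopifnot(inherits(movie, "time_lapse"))
  if (inherits(windows, "acquisition_paradigm")) windows <- stim_windows(windows)
  if (!is.list(windows)) windows <- list(windows)
  nt <- n_frames(movie)
  d <- dim(movie$frames)
  proj <- NULL
  for (w in windows) {
    w <- as.integer(w)
    if (length(w) < 2L) stopf("window length must be >= 2")
    if (min(w) < 1L || max(w) > nt) stopf("window outside movie (1..%d)", nt)
    m <- matrix(movie$frames[, , w], ncol = length(w))
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (length(w) - 1L))
    p <- matrix(s, d[1], d[2])
    proj <- if (is.null(proj)) p else pmax(proj, p)
  }
  proj
}

#' Find candidate maxima by prominence
#'
#' Rescales the image to 0-255 (min-max) and returns the local maxima whose
#' topographic prominence -- height above the highest saddle connecting them to
#' a higher maximum -- is at least `prominence` (the "SNR" knob). Plateau maxima
#' collapse to their rounded centroid; ties in score break by (row, col).
#'
#' @param image 2-D numeric matrix (e.g. an SD projection).
#' @param prominence Prominence threshold on the 0-255 scale (> 0).
#' @return Tibble with `row`, `col`, `score` (rescaled peak height) and
#'   `prominence`, sorted by descending score.
#' @export
find_candidate_maxima <- function(image, prominence) {
  stopifnot(is.matrix(image))
  if (!is_scalar_number(prominence) || prominence <= 0)
    stopf("prominence must be > 0")
  as_tibble(cpp_prominence_maxima(rescale_0_255(image), prominence))
}

#' Place non-redundant ROIs
#'
#' Greedy acceptance in descending score order: a candidate is rejected when its
#' square ROI (clipped at the image border) would share more than
#' `max_overlap_px` pixels with any already accepted ROI. Accepted ROIs are
#' numbered "0000", "0001", ... in acceptance order.
#'
#' @param maxima Tibble from [find_candidate_maxima()] (sorted by descending
#'   score).
#' @param roi_size_px Odd ROI side length.
#' @param max_overlap_px Maximum shared pixels between retained ROIs.
#' @param image_shape `c(rows, cols)` of the image.
#' @return Tibble of ROI records (`roi_id`, `center_row`, `center_col`,
#'   `size_px`, `score`).
#' @export
place_rois <- function(maxima, roi_size_px, max_overlap_px, image_shape) {
  if (roi_size_px > min(image_shape)) stopf("ROI larger than image")
  n <- nrow(maxima)
  acc_r <- integer(0); acc_c <- integer(0); keep <- logical(n)
  for (k in seq_len(n)) {
    r <- maxima$row[k]; c <- maxima$col[k]
    ok <- TRUE
    for (a in seq_along(acc_r)) {
      if (roi_overlap_px(r, c, acc_r[a], acc_c[a], roi_size_px, image_shape) >
          max_overlap_px) { ok <- FALSE; break }
    }
    if (ok) { acc_r <- c(acc_r, r); acc_c <- c(acc_c, c); keep[k] <- TRUE }
  }
  tibble(
    roi_id = sprintf("%04d", seq_len(sum(keep)) - 1L),
    center_row = as.integer(maxima$row[keep]),
    center_col = as.integer(maxima$col[keep]),
    size_px = as.integer(roi_size_px),
    score = maxima$score[keep]
  )
}

#' Mean ROI intensity traces
#'
#' @param movie A [time_lapse()] object (traces are measured on the raw movie).
#' @param rois ROI tibble with `center_row`, `center_col`, `size_px` and either
#'   `label` or `roi_id` columns for naming.
#' @return Numeric matrix (frames x ROIs), columns named by ROI label/id.
#' @export
roi_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "time_lapse"))
  d <- dim(movie$frames)
  nt <- d[3]
  out <- matrix(numeric(0), nrow = nt, ncol = 0)
  if (nrow(rois) == 0L) return(out)
  cols <- lapply(seq_len(nrow(rois)), function(i) {
    sr <- roi_span(rois$center_row[i], rois$size_px[i], d[1])
    sc <- roi_span(rois$center_col[i], rois$size_px[i], d[2])
    sub <- movie$frames[sr[1]:sr[2], sc[1]:sc[2], , drop = FALSE]
    colMeans(matrix(sub, ncol = nt))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- if ("label" %in% names(rois)) rois$label else rois$roi_id
  out
}

# Trailing rolling mean and sample SD over windows of length w ending at each
# frame; positions with an incomplete window are NA.
rolling_stats <- function(trace, w) {
  n <- length(trace)
  mu <- rep(NA_real_, n); s <- rep(NA_real_, n)
  if (n >= w) {
    cs <- cumsum(trace); cs2 <- cumsum(trace^2)
    idx <- w:n
    sum_w <- cs[idx] - c(0, cs)[idx - w + 1L]
    sum2_w <- cs2[idx] - c(0, cs2)[idx - w + 1L]
    mu[idx] <- sum_w / w
    var_w <- pmax((sum2_w - sum_w^2 / w) / (w - 1L), 0)
    s[idx] <- sqrt(var_w)
  }
  list(mean = mu, sd = s)
}

#' Assign the event start frame of a trace
#'
#' Rolling mean and rolling sample SD are computed over a trailing (causal)
#' window of `baseline_frames`, so an event cannot inflate its own threshold.
#' The event start is the first frame `f` in `[stim_start, nh4_start)` with
#' `trace[f] > mean[f-1] + cleaning_threshold_sd * sd[f-1]`; `NA` if the
#' threshold is never exceeded (such ROIs are discarded downstream).
#'
#' @param trace Numeric vector of mean ROI intensity per frame.
#' @param paradigm An [acquisition_paradigm()].
#' @param cleaning_threshold_sd Threshold in rolling-SD units.
#' @param baseline_frames Rolling-window length; defaults to the paradigm's.
#' @return Integer frame or `NA`.
#' @export
assign_event_start <- function(trace, paradigm, cleaning_threshold_sd,
                               baseline_frames = paradigm$baseline_frames) {
  w <- as.integer(baseline_frames)
  f0 <- min(paradigm$stim_start_frame)
  f1 <- paradigm$nh4_start_frame - 1L
  if (f0 - 1L < w) stopf("rolling window longer than pre-stimulation trace")
  if (length(trace) < f1) stopf("trace shorter than the search window")
  rs <- rolling_stats(trace, w)
  for (f in f0:f1) {
    thr <- rs$mean[f - 1L] + cleaning_threshold_sd * rs$sd[f - 1L]
    if (trace[f] > thr) return(f)
  }
  NA_integer_
}

#' Detect DCV fusion events
#'
#' Full detection pipeline: normalize, SD-project the stimulation window(s),
#' call candidate maxima by prominence, place non-redundant ROIs, measure each
#' ROI's mean trace on the raw movie, and assign event start frames with the
#' rolling-statistics rule. In baseline-subtraction mode, candidates must
#' additionally exceed `mean + detection_threshold_sd * SD` of the normalized
#' movie's stimulation-window intensity. ROIs whose trace never crosses the
#' cleaning threshold are dropped; the survivors are renumbered from "0000".
#' Deterministic for fixed input.
#'
#' @param movie Raw [time_lapse()] movie.
#' @param paradigm An [acquisition_paradigm()].
#' @param params A [detection_params()].
#' @return A `dcv_detection` object: list with `rois` (tibble incl.
#'   `event_start_frame` and `label`), `traces` (frames x ROIs matrix on the
#'   raw movie), `sd_image`, `n_candidates`, `paradigm`, `params`.
#' @export
detect_fusion_events <- function(movie, paradigm, params = detection_params()) {
  stopifnot(inherits(movie, "time_lapse"),
            inherits(paradigm, "acquisition_paradigm"),
            inherits(params, "detection_params"))
  if (paradigm$nh4_start_frame > n_frames(movie))
    stopf("paradigm nh4_start_frame beyond movie length")
  norm <- normalize_movie(movie, params$normalization, paradigm)
  sdimg <- sd_projection(norm, paradigm)
  maxima <- find_candidate_maxima(sdimg, params$snr)

  if (params$normalization$method == "baseline_subtraction" && nrow(maxima)) {
    wins <- unlist(stim_windows(paradigm))
    stim_frames <- norm$frames[, , wins, drop = FALSE]
    peak_img <- apply(stim_frames, c(1, 2), max)
    cut <- mean(stim_frames) + params$detection_threshold_sd * sd(stim_frames)
    maxima <- maxima[peak_img[cbind(maxima$row, maxima$col)] > cut, ]
  }

  rois <- place_rois(maxima, params$roi_size_px, params$max_overlap_px,
                     dim(movie$frames)[1:2])
  traces <- roi_traces(movie, rois)
  starts <- vapply(seq_len(nrow(rois)), function(i)
    assign_event_start(traces[, i], paradigm, params$cleaning_threshold_sd),
    integer(1))
  keep <- !is.na(starts)
  rois <- rois[keep, ]
  traces <- traces[, keep, drop = FALSE]
  rois$roi_id <- sprintf("%04d", seq_len(nrow(rois)) - 1L)
  rois$event_start_frame <- starts[keep]
  rois$label <- if (nrow(rois)) roi_label(rois$roi_id, rois$event_start_frame) else character(0)
  if (ncol(traces)) colnames(traces) <- rois$label

  structure(
    list(rois = rois, traces = traces, sd_image = sdimg,
         n_candidates = nrow(maxima), paradigm = paradigm, params = params),
    class = "dcv_detection"
  )
}

#' @export
print.dcv_detection <- function(x, ...) {
  cat(sprintf("<dcv_detection> %d fusion events (%d candidate maxima, snr = %g, %s)\n",
              nrow(x$rois), x$n_candidates, x$params$snr,
              x$params$normalization$method))
  invisible(x)
}
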