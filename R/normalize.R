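# Movie normalization applied before detection.
#
# Two methods mirror the reference workflow: "B&W opening" (a maximum filter,
# then a minimum filter, then a Gaussian blur, per frame -- the verbatim filter
# order, which is a grayscale closing followed by a blur) and baseline
# subtraction (subtract the per-pixel temporal mean of the first X frames).

#' Normalization parameters
#'
#' @param method `"bw_opening"` (default; local, robust to uneven illumination)
#'   or `"baseline_subtraction"` (recommended for noisy images).
#' @param smoothing_radius_px Neighborhood radius of the rank filters; the
#'   Gaussian blur uses sigma equal to the same radius. Must be >= 1.
#' @param baseline_frames Number of initial frames averaged for baseline
#'   subtraction; `NULL` means "use the paradigm's value". Must be >= 2 when
#'   given.
#' @return A `normalization_params` list.
#' @export
normalization_params <- function(method = c("bw_opening", "baseline_subtraction"),
                                 smoothing_radius_px = 1L,
                                 baseline_frames = NULL) {
  method <- match.arg(method)
  if (!is_scalar_number(smoothing_radius_px) || smoothing_radius_px < 1)
    stopf("smoothing_radius_px must be >= 1")
  if (!is.null(baseline_frames) &&
      (!is_scalar_number(baseline_frames) || baseline_frames < 2))
    stopf("baseline_frames must be >= 2")
  structure(
    list(method = method,
         smoothing_radius_px = as.integer(smoothing_radius_px),
         baseline_frames = if (is.null(baseline_frames)) NULL else as.integer(baseline_frames)),
    class = "normalization_params"
  )
}

#' Baseline subtraction
#'
#' Subtracts the per-pixel temporal mean of the first `baseline_frames` frames
#' from every frame. Negative output values are kept, not clipped.
#'
#' @param movie A [time_lapse()] object.
#' @param baseline_frames Number of initial frames to average (>= 2, < movie
#'   length).
#' @return A [time_lapse()] with the baseline image subtracted.
#' @export
baseline_subtract <- function(movie, baseline_frames) {
  stopifnot(inherits(movie, "time_lapse"))
  nt <- n_frames(movie)
  if (!is_scalar_number(baseline_frames) || baseline_frames < 2)
    stopf("baseline_frames must be >= 2")
  if (baseline_frames > nt)
    stopf("baseline_frames (%d) exceeds movie length (%d)", baseline_frames, nt)
  base <- baseline_image(movie$frames, baseline_frames)
  out <- movie
  out$frames <- movie$frames - as.vector(base)  # recycles over time
  out
}

# Per-pixel mean of frames 1..n_base.
baseline_image <- function(frames, n_base) {
  d <- dim(frames)
  m <- matrix(frames[, , seq_len(n_base)], ncol = n_base)
  matrix(rowMeans(m), d[1], d[2])
}

#' "B&W opening" frame filter
#'
#' Maximum filter, then minimum filter (square neighborhood of side
#' `2 * radius + 1`), then Gaussian blur with `sigma = radius` (kernel truncated
#' at `ceil(3 * sigma)`, normalized to unit sum), in that order, with reflect
#' padding at the borders.
#'
#' @param frame 2-D numeric matrix.
#' @param radius Neighborhood radius in pixels (>= 1, at most half the image).
#' @return Filtered matrix of the same shape.
#' @export
bw_open_frame <- function(frame, radius) {
  stopifnot(is.matrix(frame))
  if (!is_scalar_number(radius) || radius < 1) stopf("radius must be >= 1")
  if (radius > min(dim(frame)) / 2)
    stopf("radius (%g) larger than half the image", radius)
  radius <- as.integer(radius)
  cpp_gaussian_blur(
    cpp_rank_filter(cpp_rank_filter(frame, radius, TRUE), radius, FALSE),
    as.numeric(radius)
  )
}

#' Normalize a movie
#'
#' Dispatches to [baseline_subtract()] or applies [bw_open_frame()] to each
#' frame independently. The chosen method is recorded in the
#' `"normalization"` attribute of the result (provenance).
#'
#' @param movie A [time_lapse()] object.
#' @param params A [normalization_params()] object.
#' @param paradigm Optional [acquisition_paradigm()]; supplies `baseline_frames`
#'   when the params leave it `NULL`.
#' @return Normalized [time_lapse()].
#' @export
normalize_movie <- function(movie, params = normalization_params(),
                            paradigm = NULL) {
  stopifnot(inherits(movie, "time_lapse"), inherits(params, "normalization_params"))
  out <- switch(
    params$method,
    baseline_subtraction = {
      bf <- params$baseline_frames %||% paradigm$baseline_frames
      if (is.null(bf)) stopf("baseline_frames not set (params or paradigm)")
      baseline_subtract(movie, bf)
    },
    bw_opening = {
      fr <- movie$frames
      for (t in seq_len(n_frames(movie)))
        fr[, , t] <- bw_open_frame(movie$frames[, , t],
                                   params$smoothing_radius_px)
      out <- movie
      out$frames <- fr
      out
    },
    stopf("unknown normalization method: %s", params$method)
  )
  attr(out, "normalization") <- params
  out
}
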