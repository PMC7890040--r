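# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a detection result
#'
#' @param x A `dcv_detection` from [detect_fusion_events()].
#' @param ... Unused.
#' @return Tibble of ROI records with start times.
#' @export
tidy.dcv_detection <- function(x, ...) {
  out <- x$rois
  if (nrow(out))
    out$start_time_s <- event_time(out$event_start_frame,
                                   x$paradigm$frame_rate_hz)
  out
}

#' @rdname tidy.dcv_detection
#' @export
glance.dcv_detection <- function(x, ...) {
  tibble(n_events = nrow(x$rois), n_candidates = x$n_candidates,
         snr = x$params$snr,
         normalization = x$params$normalization$method,
         cleaning_threshold_sd = x$params$cleaning_threshold_sd,
         roi_size_px = x$params$roi_size_px)
}

#' Tidy a pool estimate
#' @param x A `pool_estimate` from [estimate_pool()].
#' @param ... Unused.
#' @export
tidy.pool_estimate <- function(x, ...) {
  tibble(raw_pool = x$raw_pool, fused_corrected = x$fused_corrected,
         puncta_corrected = x$puncta_corrected, n_events = x$n_events,
         snr_used = x$snr_used, n_saturated_px = x$n_saturated_px,
         qc_flags = paste(x$qc_flags, collapse = ";"))
}

#' Tidy / glance a per-cell analysis
#' @param x A `dcv_cell` from [analyze_cell()].
#' @param ... Unused.
#' @return `tidy()`: the Vesicle Parameters tibble; `glance()`: the one-row
#'   Pool Values tibble.
#' @export
tidy.dcv_cell <- function(x, ...) x$events

#' @rdname tidy.dcv_cell
#' @export
glance.dcv_cell <- function(x, ...) x$pool

#' Plot a detection result
#'
#' SD projection of the stimulation window with the retained ROIs outlined.
#'
#' @param object A `dcv_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcv_detection <- function(object, ...) {
  img <- as_tibble(expand.grid(row = seq_len(nrow(object$sd_image)),
                               col = seq_len(ncol(object$sd_image))))
  img$sd <- as.vector(object$sd_image)
  rois <- object$rois
  h <- rois$size_px %/% 2L
  p <- ggplot2::ggplot(img, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$sd)) +
    ggplot2::scale_fill_viridis_c(name = "SD") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)",
                  title = sprintf("%d fusion events", nrow(rois)))
  if (nrow(rois)) {
    p <- p + ggplot2::geom_rect(
      data = rois,
      ggplot2::aes(xmin = .data$center_col - h - 0.5,
                   xmax = .data$center_col + h + 0.5,
                   ymin = .data$center_row - h - 0.5,
                   ymax = .data$center_row + h + 0.5),
      inherit.aes = FALSE, fill = NA, color = "red", linewidth = 0.3)
  }
  p
}

#' Plot per-cell event timing
#'
#' Event-time histogram with the cumulative count overlaid.
#'
#' @param object A `dcv_cell`.
#' @param bin_s Histogram bin in seconds (default 1.5, one stimulation train).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcv_cell <- function(object, bin_s = 1.5, ...) {
  t_end <- n_frames_of_cell(object) / object$paradigm$frame_rate_hz
  hist <- event_histogram(object$events, bin_s, t_end)
  hist$cumulative <- cumulative_counts(hist)
  sc <- max(hist$count, 1) / max(hist$cumulative, 1)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_start_s)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey40") +
    ggplot2::geom_step(ggplot2::aes(y = .data$cumulative * sc), color = "red") +
    ggplot2::scale_y_continuous(
      name = "events / bin",
      sec.axis = ggplot2::sec_axis(~ . / sc, name = "cumulative")) +
    ggplot2::labs(x = "time (s)", title = object$cell_id)
}

n_frames_of_cell <- function(cell) {
  if (!is.null(cell$detection)) nrow(cell$detection$traces)
  else cell$paradigm$nh4_start_frame + 40L
}

#' Plot ROI intensity traces
#'
#' @param traces Frames x ROIs matrix (e.g. `detection$traces`).
#' @param frame_rate_hz Frame rate for the time axis.
#' @param rois Optional subset of ROI labels to show.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, frame_rate_hz, rois = NULL) {
  df <- as_tibble(traces, .name_repair = "minimal")
  df$time_s <- (seq_len(nrow(df)) - 1) / frame_rate_hz
  long <- tidyr::pivot_longer(df, -"time_s", names_to = "roi",
                              values_to = "intensity")
  if (!is.null(rois)) long <- dplyr::filter(long, .data$roi %in% rois)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "mean ROI intensity")
}
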