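# Image-stack and tabular artifact I/O.
#
# Movies are grayscale multi-page TIFFs; ROI sets, traces and result tables are
# CSV. Frame indices are 1-based everywhere (files, labels and R arrays alike);
# pixel coordinates are (row, col), 1-based, origin top-left. The frame rate and
# acquisition paradigm always come from a config file or function arguments,
# never from TIFF metadata.

#' Time-lapse fluorescence movie
#'
#' Light container for an ordered stack of 2-D intensity frames. Frames are
#' stored as a 3-D array with dimensions (row, col, time) so a single frame is a
#' contiguous matrix slice.
#'
#' @param frames 3-D numeric array (row, col, time) or list of equally sized
#'   matrices; at least 2 frames.
#' @param frame_rate_hz Acquisitions per second (> 0).
#' @param pixel_size_um Optional microns per pixel.
#' @return A `time_lapse` object.
#' @export
time_lapse <- function(frames, frame_rate_hz, pixel_size_um = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stopf("inconsistent frame shapes")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("frames must be a 3-D array (row, col, time)")
  if (dim(frames)[3] < 2L)
    stopf("not a time series: need at least 2 frames, got %d", dim(frames)[3])
  if (!is_scalar_number(frame_rate_hz) || frame_rate_hz <= 0)
    stopf("frame_rate_hz must be a positive number")
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um),
    class = "time_lapse"
  )
}

#' @export
print.time_lapse <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<time_lapse> %d x %d px, %d frames @ %g Hz\n",
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.time_lapse <- function(x) dim(x$frames)

#' Number of frames in a movie
#' @param movie A [time_lapse()] object.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Read a multi-page TIFF stack
#'
#' Pages are returned in stored order with raw integer (or float) values
#' preserved. The frame rate is a required argument: it is deliberately never
#' guessed from TIFF metadata.
#'
#' @param path Path to a grayscale multi-page TIFF with at least 2 pages.
#' @inheritParams time_lapse
#' @return A [time_lapse()] object.
#' @export
read_stack <- function(path, frame_rate_hz, pixel_size_um = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stopf("not a time series: %s has %d page(s)", path, length(pages))
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stopf("grayscale frames expected (multi-channel page found)")
  time_lapse(pages, frame_rate_hz, pixel_size_um)
}

#' Write a movie as a multi-page TIFF
#'
#' Values are rounded and stored as unsigned integers; reading the file back
#' with [read_stack()] reproduces the rounded array exactly.
#'
#' @param movie A [time_lapse()] object or 3-D array.
#' @param path Output path.
#' @param bits_per_sample 8 or 16.
#' @export
write_stack <- function(movie, path, bits_per_sample = 16L) {
  frames <- if (inherits(movie, "time_lapse")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3L)
  if (!bits_per_sample %in% c(8L, 16L)) stopf("bits_per_sample must be 8 or 16")
  top <- 2^bits_per_sample - 1
  frames <- round(frames)
  if (min(frames) < 0 || max(frames) > top)
    stopf("values outside 0..%d; rescale before writing", top)
  pages <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}

#' Read / write a single grayscale image (e.g. a synapse-marker frame)
#' @param path TIFF path.
#' @return Numeric matrix of raw values.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.list(img)) img <- img[[1]]
  if (length(dim(img)) != 2L) stopf("grayscale image expected")
  img
}

#' @rdname read_image
#' @param image Numeric matrix.
#' @inheritParams write_stack
#' @export
write_image <- function(image, path, bits_per_sample = 16L) {
  top <- 2^bits_per_sample - 1
  image <- round(image)
  if (min(image) < 0 || max(image) > top)
    stopf("values outside 0..%d; rescale before writing", top)
  tiff::writeTIFF(image / top, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}

# ---- ROI records ------------------------------------------------------------

#' ROI labels
#'
#' ROIs are named `ROIID-EventStart`: a 4-digit zero-padded identifier starting
#' at "0000", a dash, and the 1-based frame at which the event trace first rose
#' above the detection threshold. The same EventStart may repeat across ROIs.
#'
#' @param roi_id 4-digit identifier string (or integer, zero-padded on the fly).
#' @param event_start_frame 1-based start frame (>= 1).
#' @return Label string, e.g. `"0000-35"`.
#' @export
roi_label <- function(roi_id, event_start_frame) {
  if (is.numeric(roi_id)) roi_id <- sprintf("%04d", roi_id)
  if (!all(grepl("^[0-9]{4}$", roi_id))) stopf("roi_id must be exactly 4 digits")
  if (any(event_start_frame < 1L)) stopf("event_start_frame must be >= 1")
  paste0(roi_id, "-", as.integer(event_start_frame))
}

#' @rdname roi_label
#' @param label Label string to parse.
#' @export
parse_roi_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]{4})-([0-9]+)$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stopf("malformed ROI label (expected ROIID-EventStart): %s",
          paste(label[bad], collapse = ", "))
  tibble(
    roi_id = vapply(m, `[`, character(1), 2L),
    event_start_frame = as.integer(vapply(m, `[`, character(1), 3L))
  )
}

#' Read / write ROI sets
#'
#' ROI sets are stored as CSV with columns `roi_id` (4-digit string),
#' `center_row`, `center_col` (1-based pixels), `size_px` (odd side length) and
#' `event_start_frame` (1-based). A `label` column is written for
#' interoperability and must regenerate exactly from the other fields.
#'
#' @param rois Tibble with the columns above.
#' @param path CSV path.
#' @return `read_roi_set()` returns the tibble (with `label` regenerated);
#'   `write_roi_set()` returns `path` invisibly.
#' @export
write_roi_set <- function(rois, path) {
  rois <- validate_roi_set(rois)
  readr::write_csv(rois, path)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  rois <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      roi_id = readr::col_character(),
      center_row = readr::col_integer(),
      center_col = readr::col_integer(),
      size_px = readr::col_integer(),
      event_start_frame = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
  if ("label" %in% names(rois)) {
    parsed <- parse_roi_label(rois$label)
    if (!"roi_id" %in% names(rois)) rois$roi_id <- parsed$roi_id
    if (!"event_start_frame" %in% names(rois))
      rois$event_start_frame <- parsed$event_start_frame
  }
  validate_roi_set(rois)
}

validate_roi_set <- function(rois) {
  rois <- as_tibble(rois)
  need <- c("roi_id", "center_row", "center_col", "size_px", "event_start_frame")
  miss <- setdiff(need, names(rois))
  if (length(miss)) stopf("ROI set missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(rois)) {
    if (!all(grepl("^[0-9]{4}$", rois$roi_id)))
      stopf("roi_id must be exactly 4 digits (\"0000\", \"0001\", ...)")
    if (any(rois$size_px %% 2L != 1L) || any(rois$size_px < 1L))
      stopf("size_px must be odd and >= 1")
    if (any(rois$event_start_frame < 1L)) stopf("event_start_frame must be >= 1")
  }
  rois$label <- if (nrow(rois)) roi_label(rois$roi_id, rois$event_start_frame) else character(0)
  rois[, c("roi_id", "center_row", "center_col", "size_px",
           "event_start_frame", "label",
           setdiff(names(rois), c(need, "label")))]
}

# ---- trace tables -----------------------------------------------------------

#' Read / write ROI intensity trace tables
#'
#' One column per ROI (header = ROI label), one row per time-lapse frame,
#' values = mean ROI intensity, matching the reference "Measure ROIs" CSV
#' layout. All traces must have the same length.
#'
#' @param traces Numeric matrix (frames x ROIs) with column names, or a named
#'   list of equal-length numeric vectors.
#' @param path CSV path.
#' @export
write_trace_table <- function(traces, path) {
  if (is.list(traces) && !is.data.frame(traces)) {
    if (length(traces)) {
      len <- lengths(traces)
      if (length(unique(len)) != 1L) stopf("unequal trace lengths")
      traces <- do.call(cbind, traces)
    } else {
      traces <- matrix(numeric(0), nrow = 0, ncol = 0)
    }
  }
  traces <- as.matrix(traces)
  if (ncol(traces) == 0L) {
    writeLines("", path)
    return(invisible(path))
  }
  readr::write_csv(as_tibble(traces, .name_repair = "minimal"), path)
  invisible(path)
}

#' @rdname write_trace_table
#' @return `read_trace_table()` returns a numeric matrix (frames x ROIs).
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!nzchar(first)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  as.matrix(df)
}

# ---- analysis config --------------------------------------------------------

#' Read an analysis configuration file
#'
#' YAML file with a `paradigm` block (passed to [acquisition_paradigm()]) and an
#' optional `detection` block (passed to [detection_params()], with
#' `normalization`, `smoothing_radius_px` and `baseline_frames` routed to
#' [normalization_params()]).
#'
#' @param path YAML path.
#' @return List with elements `paradigm` and `params`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$paradigm)) stopf("config is missing the 'paradigm' block")
  paradigm <- do.call(acquisition_paradigm, cfg$paradigm)
  det <- cfg$detection %||% list()
  norm_names <- intersect(names(det), c("normalization", "smoothing_radius_px",
                                        "baseline_frames"))
  norm_args <- det[norm_names]
  names(norm_args)[names(norm_args) == "normalization"] <- "method"
  det <- det[setdiff(names(det), norm_names)]
  det$normalization <- do.call(normalization_params, norm_args)
  params <- do.call(detection_params, det)
  list(paradigm = paradigm, params = params)
}
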