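# Shared internal helpers.

# Linear rescale to [0, 255]; a constant image maps to all zeros.
rescale_0_255 <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1]) * 255
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

# Clipped square ROI span: size s centred at c covers c - s %/% 2 .. c + s %/% 2,
# clipped to 1..n.
roi_span <- function(center, size_px, n) {
  h <- size_px %/% 2L
  c(max(1L, center - h), min(n, center + h))
}

# Number of pixels shared by two clipped square ROIs.
roi_overlap_px <- function(r1, c1, r2, c2, size_px, dim_hw) {
  s1r <- roi_span(r1, size_px, dim_hw[1]); s1c <- roi_span(c1, size_px, dim_hw[2])
  s2r <- roi_span(r2, size_px, dim_hw[1]); s2c <- roi_span(c2, size_px, dim_hw[2])
  dr <- min(s1r[2], s2r[2]) - max(s1r[1], s2r[1]) + 1L
  dc <- min(s1c[2], s2c[2]) - max(s1c[1], s2c[1]) + 1L
  if (dr <= 0L || dc <= 0L) 0L else dr * dc
}

#' Triangle automatic threshold
#'
#' Geometric automatic threshold for unimodal histograms with a tail: the
#' intensities are binned into 256 equal-width bins over their range, a line is
#' drawn from the histogram peak to the far end of the longer tail, and the
#' threshold is placed at the bin whose histogram point lies farthest from that
#' line (perpendicular distance).
#'
#' @param x Numeric vector or matrix of intensities.
#' @param n_bins Number of histogram bins (default 256, 8-bit convention).
#' @return Threshold on the scale of `x` (midpoint of the selected bin).
#'   Pixels strictly above the threshold are foreground.
#' @export
triangle_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stopf("no finite values to threshold")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  bin <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  peak <- which.max(counts)
  nz <- which(counts > 0L)
  lo <- nz[1]; hi <- nz[length(nz)]
  # longer tail side; tie goes right
  right <- (hi - peak) >= (peak - lo)
  end <- if (right) hi else lo
  idx <- if (right) peak:end else end:peak
  # perpendicular distance from (b, counts[b]) to the line peak -> (end, 0)
  x1 <- peak; y1 <- counts[peak]; x2 <- end; y2 <- 0
  num <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - y2 * x1)
  b_thr <- idx[which.max(num)]
  rng[1] + (b_thr - 0.5) / n_bins * (rng[2] - rng[1])
}

# Label 8-connected components of a logical matrix (0 = background).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_label_components(mask)
}

# Binary dilation with a square structuring element of the given radius.
dilate_mask <- function(mask, radius) {
  cpp_rank_filter(mask * 1.0, as.integer(radius), TRUE) > 0
}
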