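# Synapse mask from a synapsin-marker image; synaptic/extra-synaptic
# annotation of fusion events.

#' Build a binary synapse mask
#'
#' Morphological top-hat chain. The working image must carry *bright* objects:
#' with `objects = "dark"` (puncta darker than their surroundings, the
#' black-object-on-white convention) the input is first inverted; with
#' `objects = "bright"` (a fluorescence marker) it is used directly. The
#' working image is then opened -- minimum filter, then maximum filter (square
#' neighborhood of side `2 * radius + 1`), then Gaussian blur with sigma equal
#' to the same radius -- which erases puncta no larger than the radius while
#' following the smooth background, and the opened image is subtracted from
#' the working image (clamped at 0). The difference is thresholded with the
#' Triangle method. Connected components outside `[min_area, max_area]` are
#' removed, replacing the reference workflow's manual deletion of extra
#' objects.
#'
#' @param image Marker image; synapses appear as puncta of roughly
#'   `radius_px` size.
#' @param radius_px Filter radius, ideally about the synapse size in pixels.
#' @param objects `"bright"` (fluorescent puncta, default) or `"dark"`
#'   (inverted-contrast input, which is inverted before the top-hat).
#' @param min_area,max_area Component area bounds (pixels) of the size filter.
#' @return A `synapse_mask` object (logical `mask` plus parameters).
#' @export
make_synapse_mask <- function(image, radius_px, objects = c("bright", "dark"),
                              min_area = 2L, max_area = Inf) {
  stopifnot(is.matrix(image))
  objects <- match.arg(objects)
  if (radius_px >= min(dim(image)) / 2)
    stopf("radius_px (%g) must be below half the image size", radius_px)
  r <- as.integer(radius_px)
  work <- if (objects == "dark") max(image) + min(image) - image else image
  opened <- cpp_gaussian_blur(
    cpp_rank_filter(cpp_rank_filter(work, r, FALSE), r, TRUE),
    as.numeric(r)
  )
  diff <- pmax(work - opened, 0)
  mask <- if (max(diff) == min(diff)) {
    matrix(FALSE, nrow(image), ncol(image))
  } else {
    diff > triangle_threshold(diff)
  }
  if (any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area & sizes <= max_area)
    mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  }
  structure(
    list(mask = mask, radius_px = r, min_area = min_area, max_area = max_area),
    class = "synapse_mask"
  )
}

#' @export
print.synapse_mask <- function(x, ...) {
  cat(sprintf("<synapse_mask> %d x %d px, %d foreground px (radius %d)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$radius_px))
  invisible(x)
}

#' Distance from points to the nearest mask pixel
#'
#' Euclidean distance from each point to the nearest foreground pixel center;
#' 0 for points inside the mask.
#'
#' @param points Two-column matrix/tibble of (row, col), or a length-2 vector.
#' @param mask A `synapse_mask` or logical matrix with at least one foreground
#'   pixel.
#' @return Numeric vector of distances in pixels.
#' @export
distance_to_mask <- function(points, mask) {
  if (inherits(mask, "synapse_mask")) mask <- mask$mask
  if (!any(mask)) stopf("empty mask: no foreground pixels")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  fg <- which(mask, arr.ind = TRUE)
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((fg[, 1] - pts[i, 1])^2 + (fg[, 2] - pts[i, 2])^2))
  }, numeric(1))
}

#' Annotate events as synaptic or extra-synaptic
#'
#' An event is synaptic when its ROI center lies within `tolerance_px` of the
#' synapse mask (default 1 px: inside or adjacent).
#'
#' @param events Vesicle Parameters tibble (needs `center_row`, `center_col`).
#' @param mask A `synapse_mask` or logical matrix.
#' @param tolerance_px Distance tolerance in pixels.
#' @return The events tibble with `dist_to_synapse_px` and `synaptic` filled.
#' @export
classify_synaptic <- function(events, mask, tolerance_px = 1) {
  if (nrow(events) == 0L) return(events)
  d <- distance_to_mask(cbind(events$center_row, events$center_col), mask)
  events$dist_to_synapse_px <- d
  events$synaptic <- d <= tolerance_px
  events
}
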