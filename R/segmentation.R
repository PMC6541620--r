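#' Segment the cell outline from an actin average projection
#'
#' Adaptive (local-mean) thresholding, hole filling, and selection of the
#' single largest connected component. Local thresholding makes the outline
#' robust to slow illumination gradients; the window should comfortably
#' exceed the cell diameter so the cell itself does not bias the local mean.
#'
#' @param actin_avg A `Projection` (average projection of the actin channel)
#'   or a plain numeric matrix with values in `[0, 1]`.
#' @param params List of parameters: `window_px` (full width of the local
#'   mean window; default half the smaller image dimension, clamped to the
#'   image), `offset` (threshold offset above the local mean, default 0.05),
#'   and `fill_holes` (default TRUE).
#' @return Logical cell mask.
#' @export
segment_cell <- function(actin_avg, params = list()) {
  img <- proj_matrix(actin_avg, "actin_avg")
  w <- adaptive_halfwidth(dim(img), params$window_px)
  offset <- params$offset %||% 0.05
  fg <- EBImage::thresh(img, w = w, h = w, offset = offset)
  if (isTRUE(params$fill_holes %||% TRUE)) fg <- EBImage::fillHull(fg)
  mask <- largest_component(as_binary_matrix(fg))
  if (is.null(mask)) stop("no cell detected")
  mask
}

# thresh() takes the half-width of the moving window and requires
# 2 * w + 1 <= min(dim); default to ~half the image.
adaptive_halfwidth <- function(dim_yx, window_px = NULL) {
  full <- window_px %||% floor(min(dim_yx) / 2)
  w <- floor((full - 1) / 2)
  max(min(w, floor((min(dim_yx) - 2) / 2)), 2L)
}

#' Segment the nucleus from a DAPI average projection
#'
#' Same adaptive-threshold procedure as [segment_cell()], followed by
#' intersection with the cell mask and selection of the largest component.
#'
#' @param dapi_avg A `Projection` or numeric matrix.
#' @param cell_mask Logical cell mask on the same grid.
#' @param params See [segment_cell()].
#' @return Logical nucleus mask, a subset of `cell_mask`.
#' @export
segment_nucleus <- function(dapi_avg, cell_mask, params = list()) {
  img <- proj_matrix(dapi_avg, "dapi_avg")
  cell_mask <- as_binary_matrix(cell_mask, "cell_mask")
  w <- adaptive_halfwidth(dim(img), params$window_px)
  offset <- params$offset %||% 0.05
  fg <- EBImage::thresh(img, w = w, h = w, offset = offset)
  if (isTRUE(params$fill_holes %||% TRUE)) fg <- EBImage::fillHull(fg)
  mask <- largest_component(as_binary_matrix(fg) & cell_mask)
  if (is.null(mask)) stop("no nucleus detected")
  mask
}

#' Cortical ring mask
#'
#' Isolates the cortical band by walking inward from the cell outline: the
#' ring is the cell mask minus its erosion by a rasterized disc of radius
#' `round(thickness_um / pixel_size_um)` pixels (the [disc_brush()]
#' element). An alternative formulation thresholds the Euclidean distance
#' transform at the same radius; both agree except for grid-rasterization
#' detail at the inner boundary.
#'
#' @param cell_mask Logical cell mask.
#' @param thickness_um Ring thickness in micrometres (default 2, the
#'   conventional cortex width).
#' @param pixel_size_um Pixel size in micrometres.
#' @param method `"erode"` (default) or `"edt"`.
#' @return Logical ring mask; attributes `thickness_px` records the radius
#'   used.
#' @export
cortical_ring <- function(cell_mask, thickness_um = 2, pixel_size_um,
                          method = c("erode", "edt")) {
  method <- match.arg(method)
  cell_mask <- as_binary_matrix(cell_mask, "cell_mask")
  if (!any(cell_mask)) stop("cortical_ring: empty cell mask")
  r_px <- round(thickness_um / pixel_size_um)
  if (r_px < 1)
    stop("cortical_ring: ring thickness below one pixel (", thickness_um,
         " um at ", pixel_size_um, " um/px)")
  interior <- if (method == "erode") {
    as_binary_matrix(EBImage::erode(cell_mask * 1, disc_brush(r_px)))
  } else {
    dm <- EBImage::distmap(cell_mask * 1)
    as_binary_matrix(EBImage::imageData(dm) > r_px)
  }
  if (!any(interior))
    stop("cortical_ring: cell smaller than the erosion radius (", r_px, " px)")
  ring <- cell_mask & !interior
  attr(ring, "thickness_px") <- r_px
  ring
}

#' Centrosome mask from a PCNT maximum projection
#'
#' Global threshold above background followed by small-object removal.
#' Multiple foci are retained (centrosome-amplified cells); an empty mask is
#' a legitimate result (cells without centrosomes), not an error.
#'
#' @param pcnt_max A `Projection` or numeric matrix.
#' @param params List: `threshold` (absolute; default halfway between the
#'   median and the maximum of the image) and `min_area_px` (default 4).
#' @return Logical mask, possibly empty.
#' @export
centrosome_mask <- function(pcnt_max, params = list()) {
  img <- proj_matrix(pcnt_max, "pcnt_max")
  min_area <- params$min_area_px %||% 4L
  if (diff(range(img)) < 1e-9) return(matrix(FALSE, nrow(img), ncol(img)))
  thr <- params$threshold %||% (stats::median(img) + 0.5 * (max(img) - stats::median(img)))
  lab <- EBImage::imageData(EBImage::bwlabel((img > thr) * 1))
  if (max(lab) < 1) return(matrix(FALSE, nrow(img), ncol(img)))
  keep <- which(tabulate(lab[lab > 0], nbins = max(lab)) >= min_area)
  matrix(lab %in% keep, nrow(img), ncol(img))
}

#' Restrict the cortical ring to protrusion boxes
#'
#' Protrusions are delineated manually (as ROI boxes, using the actin channel
#' as the reference); this returns the union of every box intersected with
#' the ring. A box that misses the ring entirely raises a warning; an empty
#' overall region is an error.
#'
#' @param ring_mask Logical cortical-ring mask.
#' @param boxes List of [roi_box()] objects.
#' @return Logical region mask.
#' @export
apply_protrusion_boxes <- function(ring_mask, boxes) {
  ring_mask <- as_binary_matrix(ring_mask, "ring_mask")
  region <- matrix(FALSE, nrow(ring_mask), ncol(ring_mask))
  for (i in seq_along(boxes)) {
    bm <- boxes_to_mask(boxes[i], dim(ring_mask)) & ring_mask
    if (!any(bm))
      warning("apply_protrusion_boxes: box ", i, " does not intersect the ring")
    region <- region | bm
  }
  if (!any(region)) stop("apply_protrusion_boxes: no box intersects the ring")
  region
}

#' Seeded random cortical boxes for cells without protrusions
#'
#' For rounded cells the cortical sample is drawn automatically: the nucleus
#' is first dilated (so the sampled cortex keeps the same clearance from the
#' nucleus as protrusion samples do), the dilated region is removed from the
#' ring, and `n` pairwise non-overlapping boxes whose centres lie on the
#' remaining eligible ring pixels are drawn by seeded rejection sampling.
#'
#' @param ring_mask Logical cortical-ring mask.
#' @param nucleus_mask Logical nucleus mask.
#' @param box_size_px Box side in pixels (boxes are square, the same size as
#'   the protrusion boxes in use).
#' @param n Number of boxes (default 2).
#' @param dilation_um Nucleus dilation radius (default 2 um, matching the
#'   ring thickness).
#' @param pixel_size_um Pixel size in micrometres.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param max_attempts Rejection-sampling budget (default 10000).
#' @return List of `n` [roi_box()] objects labelled `"random"`.
#' @export
select_random_boxes <- function(ring_mask, nucleus_mask, box_size_px, n = 2,
                                dilation_um = 2, pixel_size_um, seed = 1L,
                                max_attempts = 10000L) {
  ring_mask <- as_binary_matrix(ring_mask, "ring_mask")
  nucleus_mask <- as_binary_matrix(nucleus_mask, "nucleus_mask")
  r_px <- round(dilation_um / pixel_size_um)
  excl <- if (r_px >= 1 && any(nucleus_mask))
    as_binary_matrix(EBImage::dilate(nucleus_mask * 1, disc_brush(r_px)))
  else nucleus_mask
  eligible <- ring_mask & !excl
  if (!any(eligible))
    stop("select_random_boxes: no eligible ring pixels after nucleus dilation")
  idx <- which(eligible)
  ny <- nrow(ring_mask); nx <- ncol(ring_mask)
  half_lo <- floor(box_size_px / 2)
  boxes <- list()
  with_seed(seed, {
    attempts <- 0L
    while (length(boxes) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      k <- idx[sample.int(length(idx), 1L)]
      cy <- (k - 1L) %% ny + 1L
      cx <- (k - 1L) %/% ny + 1L
      x0 <- cx - 1L - half_lo; y0 <- cy - 1L - half_lo
      x1 <- x0 + box_size_px; y1 <- y0 + box_size_px
      if (x0 < 0 || y0 < 0 || x1 > nx || y1 > ny) next
      cand <- roi_box(x0, y0, x1, y1, "random")
      clash <- any(vapply(boxes, function(b)
        b$x0 < cand$x1 && cand$x0 < b$x1 && b$y0 < cand$y1 && cand$y0 < b$y1,
        logical(1)))
      if (!clash) boxes[[length(boxes) + 1L]] <- cand
    }
  })
  if (length(boxes) < n)
    stop("select_random_boxes: placed only ", length(boxes), " of ", n,
         " non-overlapping boxes within ", max_attempts, " attempts")
  boxes
}
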