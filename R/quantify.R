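#' Mean intensity under a region
#'
#' The elementary regional measurement: arithmetic mean of the
#' protein-of-interest pixels (conventionally from a maximum projection)
#' under a mask or under a union of ROI boxes.
#'
#' @param region Logical mask, or a list of [roi_box()] objects (their union
#'   is used).
#' @param poi_max A `Projection` or numeric matrix.
#' @return Mean intensity (a.u.).
#' @export
mean_intensity <- function(region, poi_max) {
  img <- proj_matrix(poi_max, "poi_max")
  mask <- region_mask(region, dim(img))
  if (!any(mask)) stop("mean_intensity: empty region")
  mean(img[mask])
}

region_mask <- function(region, dim_yx) {
  if (is.list(region) && all(vapply(region, inherits, logical(1), "roi_box")))
    return(boxes_to_mask(region, dim_yx))
  if (inherits(region, "roi_box")) return(boxes_to_mask(list(region), dim_yx))
  m <- as_binary_matrix(region, "region")
  if (!all(dim(m) == dim_yx))
    stop("region mask dimensions do not match the image")
  m
}

#' Total intensity under the centrosome mask
#'
#' @param centrosome_mask Logical mask (may be empty: cells lacking
#'   centrosomes yield 0, not an error).
#' @param poi_max A `Projection` or numeric matrix.
#' @return Summed intensity (a.u.).
#' @export
centrosome_total_intensity <- function(centrosome_mask, poi_max) {
  img <- proj_matrix(poi_max, "poi_max")
  mask <- as_binary_matrix(centrosome_mask, "centrosome_mask")
  if (!any(mask)) return(0)
  sum(img[mask])
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Cytoplasm is the whole cell excluding the nucleus. The ratio is
#' `mean(nucleus) / mean(cytoplasm)` of the protein-of-interest projection.
#'
#' @param nucleus_mask,cell_mask Logical masks; the nucleus is intersected
#'   with the cell before use.
#' @param poi_max A `Projection` or numeric matrix.
#' @return N/C ratio (dimensionless).
#' @export
nc_ratio <- function(nucleus_mask, cell_mask, poi_max) {
  img <- proj_matrix(poi_max, "poi_max")
  nuc <- as_binary_matrix(nucleus_mask, "nucleus_mask") &
    as_binary_matrix(cell_mask, "cell_mask")
  cyto <- as_binary_matrix(cell_mask, "cell_mask") & !nuc
  if (!any(nuc)) stop("nc_ratio: empty nucleus region")
  if (!any(cyto)) stop("nc_ratio: empty cytoplasm (nucleus fills the cell)")
  m_cyto <- mean(img[cyto])
  if (m_cyto <= 0) stop("nc_ratio: zero cytoplasmic mean intensity")
  mean(img[nuc]) / m_cyto
}

#' Aspect ratio of a cell mask
#'
#' Ratio of the major to minor axis of the intensity-equivalent ellipse,
#' computed from the second central moments of the pixel coordinates. Each
#' pixel contributes its unit extent (variance 1/12 per axis), so a perfect
#' `a x b` pixel rectangle returns exactly `a / b` and one-dimensional masks
#' stay finite.
#'
#' @param cell_mask Logical mask with at least 2 pixels.
#' @return Aspect ratio `>= 1`.
#' @export
aspect_ratio <- function(cell_mask) {
  mask <- as_binary_matrix(cell_mask, "cell_mask")
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 2) stop("aspect_ratio: degenerate mask (< 2 pixels)")
  cv <- stats::cov(pix) * (nrow(pix) - 1) / nrow(pix) + diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[1] / ev[2])
}

#' Normalise measurements to the control condition
#'
#' Converts raw intensities to fold changes relative to the control cells of
#' the same experiment batch: `fold = raw / mean(raw over control cells of
#' that batch)`. Per batch, the control folds average to exactly 1. Imaging
#' sessions differ in illumination and exposure, so normalisation never
#' crosses batches.
#'
#' @param records Data frame with at least a condition column and a value
#'   column; an optional batch column separates experiments (absent = one
#'   batch).
#' @param control_condition Condition label of the control group.
#' @param value_col,condition_col,batch_col Column names (defaults `value`,
#'   `condition`, `batch`).
#' @return `records` with an added `fold` column.
#' @export
normalize_to_control <- function(records, control_condition,
                                 value_col = "value",
                                 condition_col = "condition",
                                 batch_col = "batch") {
  stopifnot(is.data.frame(records))
  for (cl in c(value_col, condition_col))
    if (!cl %in% names(records)) stop("normalize_to_control: missing column ", cl)
  batch <- if (batch_col %in% names(records)) records[[batch_col]]
           else rep("batch1", nrow(records))
  vals <- records[[value_col]]
  cond <- records[[condition_col]]
  folds <- rep(NA_real_, nrow(records))
  for (b in unique(batch)) {
    in_b <- batch == b
    ctrl <- in_b & cond == control_condition
    if (!any(ctrl))
      stop("normalize_to_control: batch '", b, "' has no '",
           control_condition, "' cells")
    m <- mean(vals[ctrl])
    if (m <= 0) stop("normalize_to_control: non-positive control mean in batch '",
                     b, "'")
    folds[in_b] <- vals[in_b] / m
  }
  records$fold <- folds
  records
}
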