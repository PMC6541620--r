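#' Wound area of a scratch-assay frame
#'
#' Segments the cell-free region by texture: a confluent monolayer is locally
#' heterogeneous while the scratch is smooth, so the wound is the largest
#' connected component of low local variance. Variance is computed in a
#' sliding `window_px` box; the thresholded core is dilated by half the
#' window to undo the variance spill-over at the wound edge, and components
#' smaller than `min_area_frac` of the frame are discarded.
#'
#' @param frame Numeric matrix (phase-contrast-like image).
#' @param params List: `window_px` (odd, default 3), `var_threshold`
#'   (default 1e-6), `min_area_frac` (default 0.005), `pixel_size_um`
#'   (default 1).
#' @return List with `area_px2`, `area_um2` and the wound `mask` (all zero /
#'   FALSE when no wound region is found).
#' @export
wound_area <- function(frame, params = list()) {
  img <- proj_matrix(frame, "frame")
  w <- params$window_px %||% 3L
  if (w %% 2 != 1) stop("wound_area: window_px must be odd")
  thr <- params$var_threshold %||% 1e-6
  min_frac <- params$min_area_frac %||% 0.005
  px <- params$pixel_size_um %||% 1

  k <- matrix(1 / w^2, w, w)
  ex <- EBImage::imageData(EBImage::filter2(img, k))
  ex2 <- EBImage::imageData(EBImage::filter2(img^2, k))
  v <- pmax(ex2 - ex^2, 0)
  core <- v <= thr
  if (!any(core))
    return(list(area_px2 = 0, area_um2 = 0,
                mask = matrix(FALSE, nrow(img), ncol(img))))
  half <- (w - 1L) / 2L
  grown <- if (half >= 1)
    as_binary_matrix(EBImage::dilate(core * 1,
                                     matrix(1, 2 * half + 1, 2 * half + 1)))
  else core
  lab <- EBImage::imageData(EBImage::bwlabel(grown * 1))
  if (max(lab) < 1)
    return(list(area_px2 = 0, area_um2 = 0, mask = core & FALSE))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  best <- which.max(sizes)
  if (sizes[best] < min_frac * length(img))
    return(list(area_px2 = 0, area_um2 = 0, mask = core & FALSE))
  mask <- lab == best
  list(area_px2 = sum(mask), area_um2 = sum(mask) * px^2, mask = mask)
}

#' Residual and recovered wound area over time
#'
#' Expresses each wound area as a percentage of the area at `t = 0`
#' (residual) and its complement (recovered).
#'
#' @param areas Numeric vector of wound areas (any consistent unit).
#' @param timepoints_h Matching acquisition times; must contain 0 with a
#'   positive area.
#' @return Data frame of class `wound_series` with `t_h`, `area`,
#'   `residual_pct` and `recovered_pct`.
#' @export
residual_series <- function(areas, timepoints_h) {
  if (length(areas) != length(timepoints_h))
    stop("residual_series: areas and timepoints differ in length")
  i0 <- which(timepoints_h == 0)
  if (!length(i0)) stop("residual_series: no t = 0 timepoint")
  a0 <- areas[i0[1]]
  if (!is.finite(a0) || a0 <= 0)
    stop("residual_series: no wound detected at t = 0 (zero initial area)")
  o <- order(timepoints_h)
  res <- 100 * areas[o] / a0
  out <- data.frame(t_h = timepoints_h[o], area = areas[o],
                    residual_pct = res, recovered_pct = 100 - res)
  class(out) <- c("wound_series", "data.frame")
  out
}
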