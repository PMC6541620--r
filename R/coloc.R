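#' Mask-based colocalization coefficient of two channels
#'
#' For a cropped region (typically a manually cropped protrusion), a
#' foreground mask is generated per channel, the masks are combined, and the
#' Pearson correlation of the two channels is computed over the combined
#' pixels. The coefficient weighs signal intensity, not merely overlap area.
#' The default combination is the union of the per-channel masks, so signal
#' present in only one channel still contributes (an intersection variant is
#' available). The default per-channel mask is an Otsu threshold within the
#' crop.
#'
#' @param crop_ch1,crop_ch2 Numeric matrices of identical shape (channel 1 is
#'   conventionally the reference protein, channel 2 the candidate partner).
#' @param mask_method `"otsu"` (default) or `"quantile"` (upper quartile).
#' @param combine `"union"` (default) or `"intersection"`.
#' @return An object of class `coloc_result`: list with `r_obs`, `n_px`,
#'   `mask_method`, `combine`.
#' @export
coloc_coefficient <- function(crop_ch1, crop_ch2,
                              mask_method = c("otsu", "quantile"),
                              combine = c("union", "intersection")) {
  mask_method <- match.arg(mask_method)
  combine <- match.arg(combine)
  a <- proj_matrix(crop_ch1, "crop_ch1")
  b <- proj_matrix(crop_ch2, "crop_ch2")
  if (!all(dim(a) == dim(b))) stop("coloc_coefficient: crops differ in shape")
  m1 <- channel_mask(a, mask_method)
  m2 <- channel_mask(b, mask_method)
  mask <- if (combine == "union") m1 | m2 else m1 & m2
  if (!any(mask)) stop("coloc_coefficient: combined mask is empty")
  v1 <- a[mask]; v2 <- b[mask]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("coloc_coefficient: constant channel under the combined mask; ",
         "correlation undefined")
  structure(list(r_obs = stats::cor(v1, v2), n_px = sum(mask),
                 mask_method = mask_method, combine = combine),
            class = "coloc_result")
}

channel_mask <- function(img, method) {
  rng <- range(img)
  if (diff(rng) < 1e-12)
    stop("coloc_coefficient: constant channel; cannot build a mask")
  if (method == "otsu") {
    norm <- (img - rng[1]) / diff(rng)
    thr <- EBImage::otsu(norm, range = c(0, 1))
    norm > thr
  } else {
    img > stats::quantile(img, 0.75)
  }
}

#' Normalise a colocalization coefficient to a self-reference
#'
#' The reference is the correlation of one signal detected through two
#' independently labelled secondary antibodies — the practical ceiling of
#' measurable colocalization. The normalised coefficient is
#' `r_norm = r_obs / r_ref`.
#'
#' @param result A [coloc_coefficient()] result (or a bare correlation).
#' @param reference A [coloc_coefficient()] result from the self-reference
#'   experiment (or a bare positive correlation).
#' @return `result` with `r_ref` and `r_norm` fields added (a `coloc_result`).
#' @export
coloc_normalized <- function(result, reference) {
  r_obs <- if (inherits(result, "coloc_result")) result$r_obs else as.numeric(result)
  r_ref <- if (inherits(reference, "coloc_result")) reference$r_obs else as.numeric(reference)
  if (!is.finite(r_ref) || r_ref <= 0)
    stop("coloc_normalized: reference coefficient must be positive")
  out <- if (inherits(result, "coloc_result")) result
         else structure(list(r_obs = r_obs), class = "coloc_result")
  out$r_ref <- r_ref
  out$r_norm <- r_obs / r_ref
  out
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: r_obs = %.4f (n = %s px)", x$r_obs,
              x$n_px %||% "?"))
  if (!is.null(x$r_norm)) cat(sprintf(", r_ref = %.4f, r_norm = %.4f",
                                      x$r_ref, x$r_norm))
  cat("\n")
  invisible(x)
}
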