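#' Generate a synthetic scratch-wound image series
#'
#' Renders phase-contrast-like frames in which a confluent monolayer
#' (high-variance random texture) surrounds a straight, vertical cell-free
#' band whose width shrinks linearly at `closure_rate_um_per_h`. Ground-truth
#' areas are returned both as the analytic band area
#' `max(0, w0 - rate * t) * H` and as the rasterized pixel count actually
#' rendered.
#'
#' @param width_um Initial wound width (> 0).
#' @param closure_rate_um_per_h Closure rate (>= 0), micrometres of width
#'   lost per hour.
#' @param timepoints_h Acquisition times in hours (must include 0 for
#'   downstream residual-area analysis).
#' @param image_size_px Frame size `c(ny, nx)`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param wound_level Constant intensity inside the wound band.
#' @param noise_sd Gaussian noise sd added to the wound band (0 = noiseless).
#' @param seed Seed for the monolayer texture and noise.
#' @return List with `frames` (list of y-by-x matrices, one per timepoint),
#'   `timepoints_h`, `true_area_um2` (analytic), `rasterized_area_um2` and
#'   `pixel_size_um`.
#' @export
make_wound_series <- function(width_um, closure_rate_um_per_h, timepoints_h,
                              image_size_px = c(200, 300), pixel_size_um = 1,
                              wound_level = 0.1, noise_sd = 0, seed = 1L) {
  if (width_um <= 0) stop("make_wound_series: width_um must be > 0")
  if (closure_rate_um_per_h < 0) stop("make_wound_series: rate must be >= 0")
  ny <- image_size_px[1]; nx <- image_size_px[2]
  if (width_um / pixel_size_um > nx)
    stop("make_wound_series: wound wider than the frame")
  widths_um <- pmax(0, width_um - closure_rate_um_per_h * timepoints_h)
  out <- with_seed(seed, {
    texture <- matrix(stats::runif(ny * nx, 0.3, 1), ny, nx)
    lapply(widths_um, function(w) {
      frame <- texture
      ncols <- round(w / pixel_size_um)
      if (ncols > 0) {
        j0 <- floor((nx - ncols) / 2) + 1
        band <- j0:(j0 + ncols - 1)
        frame[, band] <- wound_level
        if (noise_sd > 0)
          frame[, band] <- pmax(frame[, band] +
            stats::rnorm(ny * ncols, sd = noise_sd), 0)
      }
      frame
    })
  })
  list(frames = out, timepoints_h = timepoints_h,
       true_area_um2 = widths_um * ny * pixel_size_um,
       rasterized_area_um2 = round(widths_um / pixel_size_um) * ny *
         pixel_size_um^2,
       pixel_size_um = pixel_size_um)
}
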