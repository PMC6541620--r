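#' Multi-channel image stack
#'
#' Container for a multi-channel, multi-plane fluorescence acquisition. The
#' intensity array is indexed `(channel, z, y, x)`; physical calibration is an
#' isotropic x/y pixel size in micrometres; `channel_map` assigns biological
#' roles to channel indices. Recognised roles are `actin` (segmentation of the
#' cell outline), `dapi` (nucleus), `pcnt` (centrosome marker), and `poi` /
#' `poi2` (the protein(s) of interest being quantified).
#'
#' @param data Numeric array, either 4D `(channel, z, y, x)`, 3D
#'   `(channel, y, x)` (a single plane), or a plain 2D matrix (one channel,
#'   one plane). Values must be finite and non-negative.
#' @param pixel_size_um Pixel size in micrometres (> 0), isotropic in x/y.
#' @param channel_map Named integer vector mapping roles to channel indices,
#'   e.g. `c(actin = 1, dapi = 2, pcnt = 3, poi = 4)`.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, pixel_size_um, channel_map) {
  if (is.matrix(data)) dim(data) <- c(1L, 1L, dim(data))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1L], 1L, dim(data)[2:3])
  if (length(dim(data)) != 4L)
    stop("image_stack: data must have dimensions (channel, z, y, x)")
  if (!all(is.finite(data))) stop("image_stack: data must be finite")
  if (min(data) < 0) stop("image_stack: data must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("image_stack: pixel_size_um must be a single positive number")
  roles <- c("actin", "dapi", "pcnt", "poi", "poi2")
  if (is.null(names(channel_map)) || !all(names(channel_map) %in% roles))
    stop("image_stack: channel_map roles must be among: ",
         paste(roles, collapse = ", "))
  idx <- as.integer(channel_map)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > dim(data)[1L]))
    stop("image_stack: channel_map index out of range for ", dim(data)[1L],
         " channel(s)")
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         channel_map = stats::setNames(idx, names(channel_map))),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d channel(s), %d z-plane(s), %d x %d px @ %.4g um/px\n",
              d[1], d[2], d[3], d[4], x$pixel_size_um))
  cat("channels:", paste(sprintf("%s=%d", names(x$channel_map), x$channel_map),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Read a multi-page TIFF into an ImageStack
#'
#' Pages are interpreted plane-major with the channel index varying fastest
#' (page `k` holds channel `(k - 1) %% n_channels + 1` of z-plane
#' `(k - 1) %/% n_channels + 1`), the interleaving used by
#' [write_image_stack()]. If the file carries an x-resolution tag in
#' pixels-per-cm or pixels-per-inch it is used for the pixel size; otherwise
#' the supplied `pixel_size_um` is used with a warning, since acquisition
#' metadata frequently omits calibration.
#'
#' @param path Path to a TIFF/OME-TIFF file.
#' @param channel_map Named integer vector of channel roles (see
#'   [image_stack()]).
#' @param pixel_size_um Fallback pixel size in micrometres used when the file
#'   has no resolution metadata.
#' @return An `ImageStack`.
#' @export
read_image_stack <- function(path, channel_map, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("read_image_stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  nc <- max(as.integer(channel_map))
  if (length(pages) %% nc != 0)
    stop("read_image_stack: ", length(pages),
         " page(s) are not divisible by ", nc, " channel(s)")
  nz <- length(pages) %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nc, nz, ny, nx))
  for (z in seq_len(nz)) for (ch in seq_len(nc))
    arr[ch, z, , ] <- pages[[(z - 1L) * nc + ch]]
  px <- tiff_pixel_size_um(pages[[1]])
  if (is.null(px)) {
    if (is.null(pixel_size_um))
      stop("read_image_stack: no resolution metadata and no pixel_size_um given")
    warning("read_image_stack: no resolution metadata in ", basename(path),
            "; falling back to configured pixel size ", pixel_size_um, " um")
    px <- pixel_size_um
  }
  image_stack(arr, px, channel_map)
}

tiff_pixel_size_um <- function(page) {
  xres <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  if (is.null(unit)) return(NULL)
  per_um <- switch(as.character(unit),
                   cm = xres / 1e4, inch = xres / 25400, `2` = xres / 25400,
                   `3` = xres / 1e4, NULL)
  if (is.null(per_um) || per_um <= 0) return(NULL)
  1 / per_um
}

#' Write an ImageStack as a multi-page TIFF
#'
#' Pages are written channel-fastest (see [read_image_stack()]). Intensities
#' are assumed to lie in `[0, 1]` and are quantised to the requested bit
#' depth; 16 bits round-trips 16-bit data exactly.
#'
#' @param stack An `ImageStack`.
#' @param path Output path.
#' @param bits_per_sample 8, 16 or 32.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  if (max(stack$data) > 1)
    stop("write_image_stack: intensities must lie in [0, 1] for TIFF output")
  pages <- vector("list", d[1] * d[2])
  for (z in seq_len(d[2])) for (ch in seq_len(d[1]))
    pages[[(z - 1L) * d[1] + ch]] <- stack$data[ch, z, , ]
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                  reduce = FALSE)
  invisible(path)
}

#' Project a channel of a stack along z
#'
#' Maximum projection is the convention for quantified protein-of-interest
#' signal; average projection is the convention for segmentation markers
#' (actin, DAPI).
#'
#' @param stack An `ImageStack`.
#' @param role Channel role present in the stack's `channel_map`.
#' @param method `"max"` or `"average"`.
#' @return A `Projection`: list with `image` (y-by-x matrix), `method`,
#'   `source_role` and `pixel_size_um`.
#' @export
project <- function(stack, role, method = c("max", "average")) {
  stopifnot(inherits(stack, "ImageStack"))
  method <- match.arg(method)
  if (!role %in% names(stack$channel_map))
    stop("project: role '", role, "' not in channel_map")
  ch <- stack$channel_map[[role]]
  planes <- stack$data[ch, , , , drop = FALSE]
  dim(planes) <- dim(stack$data)[2:4]
  img <- if (method == "max") apply(planes, c(2, 3), max)
         else apply(planes, c(2, 3), mean)
  structure(list(image = img, method = method, source_role = role,
                 pixel_size_um = stack$pixel_size_um),
            class = "Projection")
}

#' @export
print.Projection <- function(x, ...) {
  cat(sprintf("Projection (%s of '%s'): %d x %d px\n", x$method,
              x$source_role, nrow(x$image), ncol(x$image)))
  invisible(x)
}
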