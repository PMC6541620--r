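`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, then restores the caller's RNG state, so
#' seeded operations never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Rasterized disc structuring element
#'
#' Square matrix of side `2 * r_px + 1` marking integer offsets `d` with
#' `|d| <= r_px` (Euclidean). This is the brush used for cortical-ring
#' erosion and nucleus dilation, declared explicitly so that brute-force
#' enumerations can reproduce it exactly.
#'
#' @param r_px Integer radius in pixels, `>= 1`.
#' @return 0/1 matrix usable with [EBImage::erode()] / [EBImage::dilate()].
#' @export
disc_brush <- function(r_px) {
  r_px <- as.integer(r_px)
  if (r_px < 1) stop("disc_brush: radius must be >= 1 pixel")
  d <- -r_px:r_px
  outer(d, d, function(a, b) as.numeric(a^2 + b^2 <= r_px^2))
}

#' Rasterized disk mask
#'
#' Logical mask of pixels whose centres lie within `radius_px` of
#' `centre` (Euclidean, `<=`), on a `dim_yx[1] x dim_yx[2]` grid.
#'
#' @param dim_yx Integer vector `c(ny, nx)`.
#' @param centre Numeric `c(y, x)` in 1-based pixel coordinates.
#' @param radius_px Radius in pixels.
#' @return Logical matrix.
#' @export
disk_mask <- function(dim_yx, centre, radius_px) {
  y <- seq_len(dim_yx[1]) - centre[1]
  x <- seq_len(dim_yx[2]) - centre[2]
  outer(y^2, x^2, `+`) <= radius_px^2
}

as_binary_matrix <- function(m, what = "mask") {
  if (inherits(m, "Image")) m <- EBImage::imageData(m)
  if (!is.matrix(m)) stop(sprintf("%s must be a 2D matrix", what))
  if (is.logical(m)) return(m)
  m != 0
}

# Extract the plain intensity matrix from a Projection or matrix input.
proj_matrix <- function(x, what = "projection") {
  if (inherits(x, "Projection")) return(x$image)
  if (inherits(x, "Image")) return(EBImage::imageData(x))
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop(sprintf("%s must be a Projection or a numeric matrix", what))
}

# Largest connected foreground component of a binary matrix (8-connectivity);
# NULL when the mask is empty.
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n < 1) return(NULL)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  lab == which.max(sizes)
}
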