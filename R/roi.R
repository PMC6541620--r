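#' Rectangular region of interest
#'
#' An axis-aligned box on the pixel grid, 0-based and half-open:
#' `[x0, x1) x [y0, y1)`. Boxes mark manually sliced protrusions or
#' algorithmically placed random cortical samples.
#'
#' @param x0,y0 Inclusive lower corners (0-based pixel indices).
#' @param x1,y1 Exclusive upper corners; `x1 > x0`, `y1 > y0`.
#' @param label `"protrusion"` or `"random"`.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(x0, y0, x1, y1, label = c("protrusion", "random")) {
  label <- match.arg(label)
  v <- vapply(list(x0, y0, x1, y1), function(z) as.integer(z[1]), integer(1))
  if (any(is.na(v)) || any(v < 0)) stop("roi_box: corners must be non-negative integers")
  if (v[3] <= v[1] || v[4] <= v[2]) stop("roi_box: need x1 > x0 and y1 > y0")
  structure(list(x0 = v[1], y0 = v[2], x1 = v[3], y1 = v[4], label = label),
            class = "roi_box")
}

boxes_df <- function(boxes) {
  do.call(rbind, lapply(boxes, function(b)
    data.frame(x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1, label = b$label,
               stringsAsFactors = FALSE)))
}

df_boxes <- function(df) {
  need <- c("x0", "y0", "x1", "y1", "label")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    roi_box(df$x0[i], df$y0[i], df$x1[i], df$y1[i], df$label[i]))
}

#' Read ROI boxes from CSV or JSON
#'
#' @param path File with columns/fields `x0, y0, x1, y1, label` (0-based,
#'   half-open). Format is chosen by extension (`.json` vs anything else
#'   treated as CSV).
#' @return List of [roi_box()] objects.
#' @export
read_roi_boxes <- function(path) {
  if (!file.exists(path)) stop("read_roi_boxes: file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else utils::read.csv(path, stringsAsFactors = FALSE)
  df_boxes(df)
}

#' Write ROI boxes to CSV or JSON
#'
#' @param boxes List of [roi_box()] objects.
#' @param path Output path; `.json` writes a JSON array, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_roi_boxes <- function(boxes, path) {
  df <- boxes_df(boxes)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = FALSE)
  else utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Rasterize ROI boxes onto a pixel grid
#'
#' @param boxes List of [roi_box()] objects.
#' @param dim_yx Grid dimensions `c(ny, nx)`.
#' @return Logical matrix marking the union of the boxes.
#' @export
boxes_to_mask <- function(boxes, dim_yx) {
  m <- matrix(FALSE, dim_yx[1], dim_yx[2])
  for (b in boxes) {
    if (b$x1 > dim_yx[2] || b$y1 > dim_yx[1])
      stop("boxes_to_mask: box [", b$x0, ",", b$x1, ")x[", b$y0, ",", b$y1,
           ") exceeds image bounds ", dim_yx[1], "x", dim_yx[2])
    m[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1] <- TRUE
  }
  m
}
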