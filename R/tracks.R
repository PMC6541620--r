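#' Single-cell trajectory
#'
#' Time-ordered 2D positions of one cell centre sampled at a fixed frame
#' interval. Times are stored in hours; positions in micrometres.
#'
#' @param track_id Identifier (coerced to character).
#' @param times_h Strictly increasing, uniformly spaced times in hours
#'   (at least two points).
#' @param x_um,y_um Coordinates in micrometres.
#' @param dt_tol Relative tolerance on spacing uniformity.
#' @return An object of class `Track` with elements `track_id`, `times_h`,
#'   `x_um`, `y_um` and `dt_h`.
#' @export
track <- function(track_id, times_h, x_um, y_um, dt_tol = 1e-6) {
  n <- length(times_h)
  if (n < 2) stop("track: need at least 2 points (track ", track_id, ")")
  if (length(x_um) != n || length(y_um) != n)
    stop("track: coordinate lengths differ from times (track ", track_id, ")")
  if (!all(is.finite(times_h)) || !all(is.finite(x_um)) || !all(is.finite(y_um)))
    stop("track: non-finite values (track ", track_id, ")")
  dts <- diff(times_h)
  if (any(dts <= 0)) stop("track: times must be strictly increasing (track ",
                          track_id, ")")
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > dt_tol * dt)
    stop("track: non-uniform time spacing beyond tolerance (track ",
         track_id, ")")
  structure(list(track_id = as.character(track_id), times_h = as.numeric(times_h),
                 x_um = as.numeric(x_um), y_um = as.numeric(y_um), dt_h = dt),
            class = "Track")
}

#' @export
print.Track <- function(x, ...) {
  cat(sprintf("Track '%s': %d points, dt = %.4g h, span %.4g h\n", x$track_id,
              length(x$times_h), x$dt_h, diff(range(x$times_h))))
  invisible(x)
}

#' Read cell trajectories from CSV
#'
#' Expects long-format columns `track_id`, `t`, `x`, `y` (aliases `frame`,
#' `time_h`, `x_um`, `y_um` are accepted). With `time_unit = "frames"` the
#' time column holds frame indices converted to hours via
#' `frame_interval_min` (default 10 min, the standard sampling interval for
#' overnight motility movies).
#'
#' @param path CSV file.
#' @param time_unit `"frames"` or `"hours"`.
#' @param frame_interval_min Frame interval in minutes, used for
#'   `time_unit = "frames"`.
#' @return List of [track()] objects, points sorted by time.
#' @export
read_tracks <- function(path, time_unit = c("frames", "hours"),
                        frame_interval_min = 10) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (!length(hit)) stop("read_tracks: missing column; expected one of: ",
                           paste(cands, collapse = ", "))
    df[[hit[1]]]
  }
  id <- as.character(pick(c("track_id", "id", "track")))
  tt <- as.numeric(pick(c("t", "frame", "time_h", "time")))
  xx <- as.numeric(pick(c("x", "x_um")))
  yy <- as.numeric(pick(c("y", "y_um")))
  if (time_unit == "frames") tt <- tt * frame_interval_min / 60
  lapply(split(seq_along(id), id), function(ix) {
    o <- ix[order(tt[ix])]
    if (anyDuplicated(tt[o]))
      stop("read_tracks: duplicated time point in track ", id[ix[1]])
    track(id[ix[1]], tt[o], xx[o], yy[o])
  })
}

#' Write trajectories to CSV
#'
#' @param tracks List of [track()] objects.
#' @param path Output CSV (columns `track_id, t, x, y`; `t` in hours).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id, t = tr$times_h, x = tr$x_um,
               y = tr$y_um, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a measurement table to CSV
#'
#' Long-format writer for quantification records and per-cell speeds; one row
#' per measurement, UTF-8, stable column order. An empty data frame writes a
#' header-only file.
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a measurement table written by [write_records()]
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
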