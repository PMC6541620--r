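# Shared fixture builders; everything is generated in code at test time.

# Track from step displacements (rows of dx, dy in um), 10-min frames.
mk_track <- function(steps, dt_h = 1 / 6, id = "t1") {
  xy <- rbind(c(0, 0), apply(steps, 2, cumsum))
  track(id, seq(0, by = dt_h, length.out = nrow(xy)), xy[, 1], xy[, 2])
}

# Independent O(n^2) time-averaged MSD oracle: explicit loop over all
# ordered same-track pairs, grouped by lag.
msd_oracle <- function(tr, k_max) {
  n <- length(tr$times_h)
  vapply(seq_len(k_max), function(k) {
    d2 <- numeric(n - k)
    for (i in seq_len(n - k))
      d2[i] <- (tr$x_um[i + k] - tr$x_um[i])^2 +
        (tr$y_um[i + k] - tr$y_um[i])^2
    mean(d2)
  }, numeric(1))
}

# Rasterized Euclidean disk pixel count (brute force).
disk_count <- function(n, centre, r) {
  sum(outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, `+`) <= r^2)
}

# Brute-force erosion of a binary mask by the rasterized disc brush of
# radius r_px: a pixel survives iff every in-brush neighbour is foreground
# (out-of-bounds neighbours count as background).
erode_oracle <- function(mask, r_px) {
  ny <- nrow(mask); nx <- ncol(mask)
  offs <- which(disc_brush(r_px) == 1, arr.ind = TRUE) - (r_px + 1L)
  out <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!mask[i, j]) next
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
      if (ii < 1 || ii > ny || jj < 1 || jj > nx || !mask[ii, jj]) {
        ok <- FALSE
        break
      }
    }
    out[i, j] <- ok
  }
  out
}

# Small noiseless phantom used across tests.
quiet_phantom <- function(...) make_cell_image(cell_phantom_spec(noise = NULL, ...))
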