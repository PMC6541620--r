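test_that("noise-free phantom segmentation recovers the true cell and nucleus", {
  ph <- quiet_phantom(seed = 2)
  cell <- segment_cell(project(ph$stack, "actin", "average"))
  iou <- sum(cell & ph$truth$cell) / sum(cell | ph$truth$cell)
  expect_gte(iou, 0.95)
  nuc <- segment_nucleus(project(ph$stack, "dapi", "average"), cell)
  iou_n <- sum(nuc & ph$truth$nucleus) / sum(nuc | ph$truth$nucleus)
  expect_gte(iou_n, 0.95)
  expect_true(all(cell[nuc]))  # nucleus within cell, always
})

test_that("blank projections raise the no-cell / no-nucleus errors", {
  blank <- matrix(0.05, 64, 64)
  expect_error(segment_cell(blank), "no cell detected")
  cellm <- matrix(TRUE, 64, 64)
  expect_error(segment_nucleus(blank, cellm), "no nucleus detected")
})

test_that("only the largest of two objects is retained", {
  img <- matrix(0.05, 80, 80)
  big <- disk_mask(c(80, 80), c(25, 25), 15)
  small <- disk_mask(c(80, 80), c(60, 60), 6)
  img[big] <- 0.8; img[small] <- 0.8
  mask <- segment_cell(img, list(window_px = 40))
  expect_true(all(mask[big]))
  expect_false(any(mask & small))
})

test_that("cell-mask IoU stays above 0.9 across noise levels", {
  for (sd_frac in c(0, 0.05, 0.10)) {
    noise <- if (sd_frac > 0) list(type = "gaussian", sd_frac = sd_frac)
    for (seed in 1:3) {
      ph <- make_cell_image(cell_phantom_spec(noise = noise, seed = seed))
      cell <- segment_cell(project(ph$stack, "actin", "average"))
      iou <- sum(cell & ph$truth$cell) / sum(cell | ph$truth$cell)
      expect_gte(iou, 0.9)
    }
  }
})

test_that("cortical ring equals its brute-force erosion oracle on a disk", {
  n <- 61
  cell <- disk_mask(c(n, n), c(31, 31), 20)
  ring <- cortical_ring(cell, thickness_um = 4, pixel_size_um = 1)
  oracle_interior <- erode_oracle(cell, 4)
  expect_identical(which(ring), which(cell & !oracle_interior))
  expect_true(all(cell[ring]))                      # ring within cell
  expect_false(any(ring & oracle_interior))         # disjoint from interior
})

test_that("erosion-based and distance-transform rings agree", {
  ph <- quiet_phantom(n_protrusions = 2, seed = 8)
  a <- cortical_ring(ph$truth$cell, 2, 0.25, method = "erode")
  b <- cortical_ring(ph$truth$cell, 2, 0.25, method = "edt")
  expect_identical(as.vector(a), as.vector(b))
})

test_that("degenerate ring requests are rejected", {
  cell <- disk_mask(c(41, 41), c(21, 21), 10)
  expect_error(cortical_ring(cell, 0, 1), "below one pixel")
  expect_error(cortical_ring(cell, 15, 1), "smaller than the erosion radius")
  expect_error(cortical_ring(matrix(FALSE, 5, 5), 2, 1), "empty")
})

test_that("ring area grows monotonically with thickness", {
  cell <- disk_mask(c(81, 81), c(41, 41), 30)
  areas <- vapply(1:6, function(t)
    sum(cortical_ring(cell, t, 1)), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("centrosome mask finds foci and tolerates their absence", {
  img <- matrix(0.03, 64, 64)
  g <- function(cy, cx, s = 1.5) {
    d2 <- outer((1:64 - cy)^2, (1:64 - cx)^2, `+`)
    0.8 * exp(-d2 / (2 * s^2))
  }
  one <- centrosome_mask(img + g(20, 20))
  lab <- EBImage::bwlabel(one * 1)
  expect_equal(max(lab), 1)
  expect_true(one[20, 20])
  two <- centrosome_mask(img + g(20, 20) + g(45, 50))
  expect_equal(max(EBImage::bwlabel(two * 1)), 2)
  blank <- centrosome_mask(matrix(0.03, 64, 64))
  expect_false(any(blank))   # centrinone-treated cells: empty, not an error
})

test_that("protrusion boxes intersect the ring as a strict union", {
  cell <- disk_mask(c(61, 61), c(31, 31), 20)
  ring <- cortical_ring(cell, 3, 1)
  whole <- apply_protrusion_boxes(ring, list(roi_box(0, 0, 61, 61)))
  expect_identical(which(whole), which(ring))
  expect_error(
    suppressWarnings(apply_protrusion_boxes(ring, list(roi_box(28, 28, 32, 32)))),
    "no box intersects")
  b1 <- roi_box(25, 5, 40, 20); b2 <- roi_box(30, 10, 45, 25)
  both <- apply_protrusion_boxes(ring, list(b1, b2))
  manual <- (boxes_to_mask(list(b1), dim(ring)) |
               boxes_to_mask(list(b2), dim(ring))) & ring
  expect_identical(both, manual)
})

test_that("random cortical boxes are seeded, eligible and non-overlapping", {
  ph <- quiet_phantom(seed = 6)
  tr <- ph$truth
  args <- list(tr$ring, tr$nucleus, box_size_px = 10, n = 2,
               pixel_size_um = 0.25, seed = 11)
  a <- do.call(select_random_boxes, args)
  b <- do.call(select_random_boxes, args)
  expect_identical(a, b)
  excl <- EBImage::dilate(tr$nucleus * 1, disc_brush(8)) > 0
  eligible <- tr$ring & !excl
  for (bx in a) {
    cx <- bx$x0 + 1 + floor(10 / 2); cy <- bx$y0 + 1 + floor(10 / 2)
    expect_true(eligible[cy, cx])
    expect_equal(bx$label, "random")
  }
  expect_false(a[[1]]$x0 < a[[2]]$x1 && a[[2]]$x0 < a[[1]]$x1 &&
                 a[[1]]$y0 < a[[2]]$y1 && a[[2]]$y0 < a[[1]]$y1)
  args$seed <- 12
  expect_false(identical(do.call(select_random_boxes, args), a))
})

test_that("impossible box placement reports the shortfall", {
  ring <- matrix(FALSE, 40, 40); ring[20, 20] <- TRUE
  nuc <- matrix(FALSE, 40, 40)
  expect_error(select_random_boxes(ring, nuc, box_size_px = 8, n = 2,
                                   pixel_size_um = 1, seed = 1,
                                   max_attempts = 200),
               "placed only 1 of 2")
})
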