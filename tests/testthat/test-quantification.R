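test_that("regional mean intensity matches hand-computed values", {
  uniform <- matrix(7, 10, 10)
  any_region <- disk_mask(c(10, 10), c(5, 5), 3)
  expect_equal(mean_intensity(any_region, uniform), 7)
  img <- matrix(0, 4, 4)
  img[1:2, 1:2] <- c(1, 3, 2, 4)  # column-major: [1,2;3,4]
  expect_equal(mean_intensity(list(roi_box(0, 0, 2, 2)), img), 2.5)
  expect_error(mean_intensity(matrix(FALSE, 4, 4), img), "empty region")
})

test_that("centrosome totals sum under the mask, empty mask giving zero", {
  img <- matrix(1, 6, 6); img[2, 2:4] <- 5
  mask <- matrix(FALSE, 6, 6); mask[2, 2:4] <- TRUE
  expect_equal(centrosome_total_intensity(mask, img), 15)
  expect_equal(centrosome_total_intensity(matrix(FALSE, 6, 6), img), 0)
  off <- matrix(FALSE, 6, 6); off[5, 5] <- TRUE
  expect_equal(centrosome_total_intensity(off, img), 1)  # background only
})

test_that("N/C ratio recovers the phantom ratio and rejects degeneracies", {
  img <- matrix(3, 20, 20)
  cell <- disk_mask(c(20, 20), c(10, 10), 8)
  nuc <- disk_mask(c(20, 20), c(10, 10), 4)
  expect_equal(nc_ratio(nuc, cell, img), 1)
  ph <- quiet_phantom(nc_ratio = 0.65)
  poi <- project(ph$stack, "poi", "max")
  expect_equal(nc_ratio(ph$truth$nucleus, ph$truth$cell, poi), 0.65)
  expect_error(nc_ratio(cell, cell, img), "cytoplasm")
  expect_error(nc_ratio(matrix(FALSE, 20, 20), cell, img), "nucleus")
})

test_that("aspect ratio follows the second-moment ellipse", {
  circ <- disk_mask(c(61, 61), c(31, 31), 20)
  expect_equal(aspect_ratio(circ), 1, tolerance = 0.05)
  rect <- matrix(FALSE, 60, 60); rect[11:50, 21:30] <- TRUE  # 40 x 10 px
  expect_equal(aspect_ratio(rect), 4)
  line <- matrix(FALSE, 30, 30); line[5, 3:22] <- TRUE       # 20 x 1 px
  ar <- aspect_ratio(line)
  expect_true(is.finite(ar))
  expect_equal(ar, 20)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_error(aspect_ratio(single), "degenerate")
})

test_that("control normalisation gives unit control mean per batch", {
  all_ctrl <- data.frame(condition = "ctrl", value = c(2, 4, 6))
  out <- normalize_to_control(all_ctrl, "ctrl")
  expect_equal(mean(out$fold), 1)
  two <- data.frame(condition = c("ctrl", "drug", "ctrl", "drug"),
                    value = c(2, 4, 10, 10),
                    batch = c("e1", "e1", "e2", "e2"))
  out2 <- normalize_to_control(two, "ctrl")
  expect_equal(out2$fold, c(1, 2, 1, 1))  # hand: 4/2, 10/10
  expect_error(normalize_to_control(
    data.frame(condition = "drug", value = 1), "ctrl"), "no 'ctrl' cells")
})

test_that("segmented-mask pipeline recovers enrichment and N/C within 10%", {
  # spot check at two folds; the full four-level sweep runs in the
  # acceptance suite
  for (E in c(1.5, 3)) {
    est <- vapply(1:5, function(seed) {
      ph <- make_cell_image(cell_phantom_spec(
        enrichment_fold = E, nc_ratio = 0.65,
        noise = list(type = "gaussian", sd_frac = 0.05), seed = seed))
      cell <- segment_cell(project(ph$stack, "actin", "average"))
      nuc <- segment_nucleus(project(ph$stack, "dapi", "average"), cell)
      ring <- cortical_ring(cell, 2, 0.25)
      poi <- project(ph$stack, "poi", "max")
      c(mean_intensity(ring, poi) /
          mean_intensity(cell & !ring & !nuc, poi),
        nc_ratio(nuc, cell, poi))
    }, numeric(2))
    expect_lt(abs(mean(est[1, ]) / E - 1), 0.10)
    expect_lt(abs(mean(est[2, ]) / 0.65 - 1), 0.10)
  }
})

test_that("colocalization matches the Pearson formula over the union mask", {
  set.seed(3)
  base <- matrix(runif(144, 0, 1), 12, 12)
  self <- coloc_coefficient(base, base)
  expect_equal(self$r_obs, 1)
  neg <- coloc_coefficient(base, 0.9 - 0.8 * base)
  expect_equal(neg$r_obs, -1)
  # 3x3 hand case: union of the per-channel bright sets is pixels 1..6
  # (column-major); Pearson computed directly on the hand-listed values
  ch1 <- matrix(c(0.8, 0.8, 0.8, 0.8, 0, 0, 0, 0, 0), 3, 3)
  ch2 <- matrix(c(0, 0, 0.9, 0.9, 0.9, 0.9, 0, 0, 0), 3, 3)
  got <- coloc_coefficient(ch1, ch2)
  v1 <- c(0.8, 0.8, 0.8, 0.8, 0, 0)
  v2 <- c(0, 0, 0.9, 0.9, 0.9, 0.9)
  expect_equal(got$r_obs,
               sum((v1 - mean(v1)) * (v2 - mean(v2))) /
                 sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2)),
               tolerance = 1e-12)
  expect_equal(got$n_px, 6)
})

test_that("colocalization is invariant to affine intensity rescaling", {
  set.seed(4)
  a <- matrix(runif(100), 10, 10)
  b <- matrix(runif(100), 10, 10)
  r0 <- coloc_coefficient(a, b)$r_obs
  expect_equal(coloc_coefficient(2.5 * a + 0.3, b)$r_obs, r0)
  expect_equal(coloc_coefficient(a, 0.1 * b + 1)$r_obs, r0)
})

test_that("degenerate colocalization inputs are errors", {
  flat <- matrix(1, 5, 5)
  var5 <- matrix(runif(25), 5, 5)
  expect_error(coloc_coefficient(flat, var5), "constant channel")
  expect_error(coloc_coefficient(var5, matrix(runif(16), 4, 4)), "shape")
})

test_that("self-reference normalisation is a plain ratio with guards", {
  set.seed(5)
  a <- matrix(runif(64), 8, 8)
  obs <- coloc_coefficient(a, a)
  out <- coloc_normalized(obs, obs)
  expect_equal(out$r_norm, 1)
  expect_equal(coloc_normalized(0.4, 0.8)$r_norm, 0.5)
  expect_error(coloc_normalized(0.4, 0), "positive")
  expect_error(coloc_normalized(0.4, -0.2), "positive")
})
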