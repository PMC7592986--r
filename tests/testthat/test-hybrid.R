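test_that("body segmentation recovers the phantom body and rejects
           degenerate input", {
  spec <- mid_spec(seed = 11)
  f <- generate_frame(spec, 10)
  body <- segment_body(f$image)
  expect_gt(dice_coefficient(body, f$body_mask), 0.98)
  expect_error(segment_body(image3d(array(0, c(8, 8, 8)))), "constant")
  # union ROI is the voxelwise OR of the two body masks
  f2 <- generate_frame(spec, 20)
  body2 <- segment_body(f2$image)
  expect_identical(body | body2, (body | body2) | body)
})

test_that("lung segmentation matches the ground truth and respects the
           volume floor", {
  spec <- mid_spec(seed = 12)
  f <- generate_frame(spec, 12)
  body <- segment_body(f$image)
  lung <- segment_lungs(f$image, body)
  expect_gt(dice_coefficient(lung, f$lung_mask), 0.95)
  ratio <- sum(lung) / sum(f$lung_mask)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 1.5)
  expect_true(all(body[lung]))
  expect_error(segment_lungs(f$image, array(FALSE, dim(f$image$data))),
               "empty body")
})

test_that("air bubbles are detected component-wise and filled with the
           bodyshell mean", {
  spec <- mid_spec(seed = 13)
  f <- generate_frame(spec, 8)
  body <- segment_body(f$image)
  lung <- segment_lungs(f$image, body)
  shell <- body & !lung
  th <- tr4dmri:::otsu_threshold(f$image$data[body])
  res <- fill_bubbles(f$image, shell, threshold = th)
  # all seeded bubbles found (component-wise recall)
  lab <- array(tr4dmri:::cpp_label6(f$bubble_mask, dim(f$bubble_mask)),
               dim(f$bubble_mask))
  hits <- vapply(seq_len(max(lab)), function(i)
    any(res$bubble_mask[lab == i]), logical(1))
  expect_true(all(hits))
  # filled with the mean of the remaining bodyshell
  fill_val <- mean(f$image$data[shell & !res$bubble_mask])
  expect_lt(max(abs(res$image$data[res$bubble_mask] - fill_val)), 1e-6)
  # re-detection after filling finds nothing
  again <- fill_bubbles(res$image, shell, threshold = th)
  expect_equal(sum(again$bubble_mask), 0)
  expect_identical(again$image$data, res$image$data)
})

test_that("sub-ROI renormalization stretches to full range, preserves
           ranking, and increases contrast", {
  spec <- mid_spec(seed = 14)
  f <- generate_frame(spec, 0)
  lung_roi <- f$lung_mask
  ren <- renormalize_subroi(f$image, lung_roi)
  v_in <- ren$data[lung_roi]
  expect_gte(min(v_in), 0)
  expect_lte(max(v_in), 1)
  expect_gt(max(v_in), 0.999)           # window endpoints reach the range
  expect_equal(unique(ren$data[!lung_roi]), 0)
  # monotone: ranking preserved for unclipped voxels
  raw <- f$image$data[lung_roi]
  w <- attr(ren, "window")
  unclipped <- raw > w$lo & raw < w$hi
  expect_equal(order(raw[unclipped]), order(v_in[unclipped]))
  # contrast strictly increases for a narrow-band sub-ROI
  expect_gt(stats::sd(v_in), stats::sd(raw))
  expect_error(renormalize_subroi(f$image, lung_roi & FALSE), "empty")
})

test_that("histogram matching aligns ROI quantiles monotonically", {
  set.seed(31)
  n <- c(10, 10, 10)
  a <- image3d(array(runif(prod(n)), n))
  b <- image3d(array(0.2 + 0.5 * runif(prod(n))^2, n))
  m <- histogram_match(b, a)
  expect_lt(abs(stats::median(m$data) - stats::median(a$data)), 0.02)
  # monotone in the source intensities
  o <- order(b$data)
  expect_true(all(diff(m$data[o]) >= -1e-12))
})

test_that("combining sub-ROI fields stitches supports and blends the
           interface", {
  n <- c(20, 20, 20)
  lung <- array(FALSE, n); lung[, , 1:10] <- TRUE
  shell <- !lung
  z <- array(0, n)
  d_lung <- dvf3d(z + ifelse(lung, 1, 0), z, z, c(2, 2, 2))
  d_body <- dvf3d(z, z + ifelse(shell, 1, 0), z, c(2, 2, 2))
  comb <- combine_dvfs(d_lung, d_body, lung, shell)
  # away from the interface each region keeps its own field
  expect_equal(comb$ux[, , 1:6], array(1, c(20, 20, 6)), tolerance = 1e-9)
  expect_equal(comb$uy[, , 15:20], array(1, c(20, 20, 6)), tolerance = 1e-9)
  expect_equal(comb$uy[, , 1:6], array(0, c(20, 20, 6)), tolerance = 1e-9)
  # inside the band the field is a smooth blend
  expect_true(all(comb$ux[, , 10] > 0 & comb$ux[, , 10] < 1))
  # linearity of the stitch away from the seam: vector sums add up
  away <- abs(slice.index(z, 3) - 10.5) > 3
  expect_equal(sum(comb$ux[away]), sum(d_lung$ux[away]) + 0,
               tolerance = 1e-9)
  # one field empty: the other passes through outside the band
  comb2 <- combine_dvfs(d_lung, dvf3d(z, z, z, c(2, 2, 2)), lung, shell)
  expect_equal(comb2$ux[, , 1:6], array(1, c(20, 20, 6)), tolerance = 1e-9)
  # overlapping nonzero supports beyond the band raise a warning
  bad <- dvf3d(z + 1, z, z, c(2, 2, 2))
  expect_warning(combine_dvfs(bad, d_body, lung, shell), "overlap")
})

test_that("field composition reduces to addition for uniform fields", {
  n <- c(12, 12, 12)
  z <- array(0, n)
  u1 <- dvf3d(z + 3, z, z + 1, c(2, 2, 2))
  u2 <- dvf3d(z, z + 2, z, c(2, 2, 2))
  comp <- compose_dvf(u1, u2)
  interior <- 3:10
  expect_equal(comp$ux[interior, interior, interior],
               array(3, c(8, 8, 8)), tolerance = 1e-9)
  expect_equal(comp$uy[interior, interior, interior],
               array(2, c(8, 8, 8)), tolerance = 1e-9)
  expect_equal(comp$uz[interior, interior, interior],
               array(1, c(8, 8, 8)), tolerance = 1e-9)
})

test_that("zero-motion pairs give near-identity total fields", {
  spec <- mid_spec(seed = 15)
  f <- generate_frame(spec, 0)
  low <- degrade_frame(f, seed = 15)
  res <- run_two_step(f$image, low,
                      params = demons_params(max_iters = c(60, 30, 15)),
                      finetune_iters = 10)
  mag <- tr4dmri:::dvf_magnitude(res$dvf)
  expect_lt(mean(mag[res$roi]), 0.5 * min(spec$spacing))
  # partition invariants: disjoint and exhaustive within the body ROI
  p <- res$partition
  expect_false(any(p$lung_mask & p$bodyshell_mask))
  expect_identical(p$lung_mask | p$bodyshell_mask, res$roi)
})
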