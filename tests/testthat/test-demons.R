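test_that("VID is the mean absolute intensity difference over the ROI", {
  a <- image3d(array(0.5, c(4, 4, 4)))
  expect_equal(compute_vid(a, a), 0)
  b <- image3d(a$data + 0.1)
  expect_equal(compute_vid(a, b), 0.1, tolerance = 1e-12)
  # 4-voxel ROI with differences {0.1, -0.3, 0.0, 0.2} -> 0.15
  d <- array(0, c(4, 4, 4))
  d[1:4] <- c(0.1, -0.3, 0.0, 0.2)
  roi <- array(FALSE, c(4, 4, 4)); roi[1:4] <- TRUE
  expect_equal(compute_vid(a, image3d(a$data + d), roi), 0.15,
               tolerance = 1e-12)
  expect_error(compute_vid(a, b, array(FALSE, c(4, 4, 4))), "empty ROI")
})

test_that("the Demons force is zero without mismatch or gradient and
           points toward alignment on a ramp", {
  ramp <- ramp_image(c(12, 12, 12), c(2, 2, 2), slope = c(0.02, 0, 0))
  # identical images: no force
  z <- demons_update(ramp, ramp)
  expect_equal(max(abs(z$ux)), 0)
  # flat static, different moving: degenerate denominator, no force
  flat <- image3d(array(0.5, c(12, 12, 12)), c(2, 2, 2))
  mov <- image3d(array(0.7, c(12, 12, 12)), c(2, 2, 2))
  z2 <- demons_update(flat, mov)
  expect_equal(max(abs(z2$ux)), 0)

  # static ramp, moving = ramp shifted by +delta in x. Direct evaluation of
  # the force formula at an interior voxel (independent arithmetic):
  # grad_s = 0.04/voxel, diff = I_s - I_m = slope * delta
  delta <- 3  # mm; content moved toward +x, so the backward sample is -x
  movr <- warp_image(ramp, uniform_dvf(ramp, c(-delta, 0, 0)))
  f <- demons_update(ramp, movr)
  gs <- 0.02 * 2                       # per-voxel gradient
  d0 <- 0.02 * delta
  expected <- d0 * gs / (gs^2 + d0^2 + 1e-6) * 2   # mm
  expect_equal(f$ux[6, 6, 6], expected, tolerance = 1e-6)
  # the increment must pull the sampling point toward the moving content
  expect_gt(f$ux[6, 6, 6], 0)
})

test_that("pseudo-force spreading conserves force and has the printed
           physical reach", {
  n <- c(11, 11, 11)
  z <- array(0, n)
  imp <- z; imp[6, 6, 6] <- 1
  inc <- dvf3d(imp, z, z, c(2, 2, 2))
  sp <- pseudo_force_spread(inc)
  # a unit impulse spreads over exactly 5^3 = 125 voxels, weights sum to 1,
  # centre weight maximal
  expect_equal(sum(sp$ux != 0), 125)
  expect_equal(sum(sp$ux), 1, tolerance = 1e-12)
  expect_equal(which.max(sp$ux), which.max(imp))
  # uniform field is unchanged by the normalized kernel
  uni <- dvf3d(z + 2, z, z, c(2, 2, 2))
  spu <- pseudo_force_spread(uni)
  expect_equal(spu$ux[4:8, 4:8, 4:8], array(2, c(5, 5, 5)),
               tolerance = 1e-12)
  # vector-sum conservation for interior-supported fields
  set.seed(9)
  fld <- z; fld[4:8, 4:8, 4:8] <- rnorm(125)
  spf <- pseudo_force_spread(dvf3d(fld, z, z, c(2, 2, 2)))
  expect_equal(sum(spf$ux), sum(fld), tolerance = 1e-9 * abs(sum(fld)) + 1e-12)

  # physical reach at the coarse level: 2 mm x (5/2) x 6 = 30 mm
  expect_equal(pseudo_force_reach(demons_params(), 2), 30)
})

test_that("registering an image to itself yields a near-zero field", {
  spec <- mid_spec(seed = 7)
  img <- generate_frame(spec, 10)$image
  roi <- segment_body(img)
  reg <- register_demons(img, img, roi,
                         demons_params(max_iters = c(30, 20, 10)))
  mag <- tr4dmri:::dvf_magnitude(reg$dvf)
  expect_lt(mean(mag), 0.1 * min(spec$spacing))
  expect_lt(reg$final_vid, 1e-6)
})

test_that("a 10 mm translation is recovered within one voxel", {
  n <- c(40, 40, 40)
  co <- tr4dmri:::voxel_coords(image3d(array(0, n), c(2, 2, 2)))
  blob <- function(cx) {
    image3d(array(
      0.8 * exp(-((co$x - cx)^2 + (co$y - 40)^2 + (co$z - 40)^2) / 288),
      n), c(2, 2, 2))
  }
  stat <- blob(46)
  mov <- blob(36)          # content shifted +10 mm in x
  reg <- register_demons(stat, mov,
                         params = demons_params(pyramid_factors = c(2, 1),
                                                max_iters = c(150, 60),
                                                diff_threshold = 0))
  supp <- stat$data > 0.15
  # backward convention: field points from target position to source
  expect_lt(abs(mean(reg$dvf$ux[supp]) - (-10)), 2)
  expect_lt(abs(mean(reg$dvf$uy[supp])), 1)
  # deformed moving matches the static
  expect_lt(compute_vid(stat, reg$deformed, supp), 0.02)
})

test_that("the convergence trace honours the stopping rules", {
  spec <- mid_spec(seed = 8)
  f0 <- generate_frame(spec, 0)
  f1 <- generate_frame(spec, 8)
  roi <- segment_body(f0$image)
  p <- demons_params(max_iters = c(60, 40, 25), stop_dvid = 1e-3)
  reg <- register_demons(f1$image, f0$image, roi, p)
  for (tr in reg$trace) {
    # VID never increases by more than 5% between accepted iterations
    if (length(tr) > 1)
      expect_true(all(diff(tr) <= 0.05 * tr[-length(tr)] + 1e-12))
  }
  # stopping: last accepted relative change below threshold or cap reached
  lv <- reg$trace[[3]]
  if (length(lv) > 1 && reg$iterations[3] < 25) {
    rel <- abs(diff(lv)) / lv[-length(lv)]
    expect_lt(rel[length(rel)], p$stop_dvid)
  }
  expect_equal(length(reg$trace), 3)
})

test_that("parameter validation rejects malformed pyramids", {
  expect_error(demons_params(pyramid_factors = c(2, 6, 1)), "decreasing")
  expect_error(demons_params(pyramid_factors = c(6, 2)), "end at 1")
  expect_error(demons_params(stop_dvid = 0), "stop_dvid")
  expect_error(demons_params(pseudo_kernel_size = 4), "odd")
})
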