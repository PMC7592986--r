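make_img <- function(v, n = c(4, 4, 4), spacing = c(1, 1, 1)) {
  image3d(array(v, n), spacing)
}

test_that("voxel intensity correlation matches a hand Pearson computation", {
  # pairs {(0,0),(1,2),(2,4),(3,5)}; r computed independently from the
  # definition: sum((x-mx)(y-my)) / sqrt(sum((x-mx)^2) sum((y-my)^2))
  a <- make_img(rep(c(0, 1, 2, 3), 16))
  b <- make_img(rep(c(0, 2, 4, 5), 16))
  # r = 8.5 / sqrt(5 * 14.75) = 0.9897783
  expect_equal(vic(a, b), 8.5 / sqrt(5 * 14.75), tolerance = 1e-12)
  expect_equal(vic(a, b), vic(b, a))
  # perfect correlation / anticorrelation; affine invariance
  expect_equal(vic(a, a), 1.0)
  neg <- make_img(3 - 2 * rep(c(0, 1, 2, 3), 16))
  expect_equal(vic(a, neg), -1.0)
  aff <- make_img(0.25 + 0.5 * rep(c(0, 2, 4, 5), 16))
  expect_equal(vic(a, aff), vic(a, b), tolerance = 1e-12)
  expect_error(vic(a, make_img(1)), "variance")
})

test_that("CCC follows its defining ratio and flags outliers", {
  expect_equal(ccc_index(1, 1, 1), 1.0)
  expect_equal(ccc_index(1, 0.9, 0.9), 1 / 0.9, tolerance = 1e-12)
  expect_equal(ccc_index(0.95, 0.91, 0.89), 2 * 0.95 / 1.80,
               tolerance = 1e-12)
  expect_error(ccc_index(1, 0.5, -0.5), "denominator")
  vals <- c(1.02, 1.03, 1.04, 1.02, 1.15)
  expect_equal(flag_ccc_outliers(vals),
               abs(vals - mean(vals)) > sd(vals))
})

test_that("SSIM is 1 on identity and negative on inverted texture", {
  set.seed(3)
  a <- make_img(runif(12^3), c(12, 12, 12))
  expect_equal(ssim3d(a, a), 1.0, tolerance = 1e-9)
  # checkerboard block against its inversion: structure anticorrelates
  g <- expand.grid(1:12, 1:12, 1:12)
  chk <- make_img(as.numeric((g[, 1] + g[, 2] + g[, 3]) %% 2),
                  c(12, 12, 12))
  inv <- make_img(1 - chk$data, c(12, 12, 12))
  expect_lt(ssim3d(chk, inv), 0)
  expect_error(ssim3d(a, a, window = 15), "window")
})

test_that("mask metrics count, locate and scale correctly", {
  m <- array(FALSE, c(6, 6, 6))
  m1 <- m; m1[1:10] <- TRUE
  m2 <- m; m2[6:15] <- TRUE            # 10 voxels each, 5 shared
  expect_equal(dice_coefficient(m1, m2), 0.5)
  expect_equal(dice_coefficient(m1, m1), 1.0)
  expect_equal(dice_coefficient(m1, m2), dice_coefficient(m2, m1))
  expect_equal(com_delta(m1, m1, c(2, 2, 2)), 0)
  expect_equal(volume_ratio(m1, m2), 1.0)
  expect_error(dice_coefficient(m1, m), "empty")

  # sphere shifted 4 mm on a 2 mm grid
  n <- c(20, 20, 20)
  co <- tr4dmri:::voxel_coords(image3d(array(0, n), c(2, 2, 2)))
  s1 <- (co$x - 18)^2 + (co$y - 18)^2 + (co$z - 18)^2 <= 64
  s2 <- (co$x - 22)^2 + (co$y - 18)^2 + (co$z - 18)^2 <= 64
  expect_equal(com_delta(s1, s2, c(2, 2, 2)), 4.0, tolerance = 0.1)
})

test_that("landmark TRE reports per-point error statistics", {
  p <- matrix(c(0, 0, 0, 10, 10, 10, -5, 2, 7), 3, byrow = TRUE)
  expect_equal(landmark_tre(p, p)$mean, 0)
  off <- sweep(p, 2, c(3, 0, 0), "+")
  tre <- landmark_tre(off, p)
  expect_equal(tre$mean, 3.0)
  expect_equal(tre$sd, 0.0)
  # errors {2, 4, 6} mm: mean 4, population sd sqrt(8/3) = 1.632993
  pred <- p + cbind(c(2, 4, 6), 0, 0)
  tre2 <- landmark_tre(pred, p)
  expect_equal(tre2$mean, 4.0)
  expect_equal(tre2$sd, 1.632993, tolerance = 1e-6)
  expect_error(landmark_tre(p[1:2, ], p), "length")
})

# Independent brute-force stencil oracle for the field derivatives: plain R
# loops over voxels, one-sided at boundaries.
oracle_grad <- function(comp, axis, h) {
  n <- dim(comp)
  out <- array(0, n)
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
    idx <- c(i, j, k)
    hi <- idx; hi[axis] <- min(idx[axis] + 1, n[axis])
    lo <- idx; lo[axis] <- max(idx[axis] - 1, 1)
    out[i, j, k] <- (comp[hi[1], hi[2], hi[3]] - comp[lo[1], lo[2], lo[3]]) /
      ((hi[axis] - lo[axis]) * h)
  }
  out
}

oracle_jacobian <- function(dvf) {
  s <- dvf$spacing
  gs <- list(ux = lapply(1:3, function(a) oracle_grad(dvf$ux, a, s[a])),
             uy = lapply(1:3, function(a) oracle_grad(dvf$uy, a, s[a])),
             uz = lapply(1:3, function(a) oracle_grad(dvf$uz, a, s[a])))
  n <- dim(dvf$ux)
  out <- array(0, n)
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
    m <- rbind(c(gs$ux[[1]][i, j, k] + 1, gs$ux[[2]][i, j, k],
                 gs$ux[[3]][i, j, k]),
               c(gs$uy[[1]][i, j, k], gs$uy[[2]][i, j, k] + 1,
                 gs$uy[[3]][i, j, k]),
               c(gs$uz[[1]][i, j, k], gs$uz[[2]][i, j, k],
                 gs$uz[[3]][i, j, k] + 1))
    out[i, j, k] <- det(m)
  }
  out
}

oracle_curl <- function(dvf) {
  s <- dvf$spacing
  list(cx = oracle_grad(dvf$uz, 2, s[2]) - oracle_grad(dvf$uy, 3, s[3]),
       cy = oracle_grad(dvf$ux, 3, s[3]) - oracle_grad(dvf$uz, 1, s[1]),
       cz = oracle_grad(dvf$uy, 1, s[1]) - oracle_grad(dvf$ux, 2, s[2]))
}

test_that("Jacobian and curl maps agree with the brute-force oracle", {
  set.seed(11)
  n <- c(8, 8, 8)
  rnd <- function() array(rnorm(prod(n), sd = 2), n)
  dvf <- dvf3d(rnd(), rnd(), rnd(), c(2, 2, 2))
  jac <- jacobian_map(dvf)
  expect_equal(jac$map, oracle_jacobian(dvf), tolerance = 1e-12)
  cl <- curl_map(dvf)
  orc <- oracle_curl(dvf)
  expect_equal(cl$cx, orc$cx, tolerance = 1e-12)
  expect_equal(cl$cy, orc$cy, tolerance = 1e-12)
  expect_equal(cl$cz, orc$cz, tolerance = 1e-12)
})

test_that("Jacobian determinant has the closed-form value for stretches", {
  n <- c(10, 10, 10)
  co <- tr4dmri:::voxel_coords(image3d(array(0, n), c(2, 2, 2)))
  # U = (0.1 x, 0, 0): uniform 10% stretch, det(I + grad U) = 1.1
  z <- array(0, n)
  dvf <- dvf3d(0.1 * co$x, z, z, c(2, 2, 2))
  jac <- jacobian_map(dvf)
  expect_equal(jac$map[3:8, 3:8, 3:8], array(1.1, c(6, 6, 6)),
               tolerance = 1e-12)
  # zero field: identity everywhere
  jac0 <- jacobian_map(dvf3d(z, z, z, c(2, 2, 2)))
  expect_equal(jac0$map, array(1, n))
  expect_equal(jac0$min, 1)
  expect_equal(jac0$pct_negative, 0)
})

test_that("curl vanishes for constants/gradients and is 2w for rotations", {
  n <- c(12, 12, 12)
  z <- array(0, n)
  # constant field
  cl0 <- curl_map(dvf3d(z + 3, z - 1, z + 2, c(2, 2, 2)))
  expect_equal(cl0$max, 0)
  co <- tr4dmri:::voxel_coords(image3d(array(0, n), c(2, 2, 2)))
  # rigid in-plane rotation u = -w y, v = w x: curl = (0, 0, 2w)
  w <- 0.05
  cl <- curl_map(dvf3d(-w * co$y, w * co$x, z, c(2, 2, 2)))
  expect_equal(cl$cz[3:10, 3:10, 3:10], array(2 * w, c(8, 8, 8)),
               tolerance = 1e-12)
  # gradient field U = grad(phi), phi smooth: curl -> 0 at h^2 rate
  curl_err <- function(h) {
    nn <- round(24 / h * c(1, 1, 1))
    cg <- tr4dmri:::voxel_coords(image3d(array(0, nn), rep(h, 3)))
    phi_dx <- function(x, y, z) 2 * x * 0.01 * sin(y / 5)
    phi_dy <- function(x, y, z) 0.01 * x^2 / 5 * cos(y / 5)
    phi_dz <- function(x, y, z) 0 * z
    d <- dvf3d(phi_dx(cg$x, cg$y, cg$z), phi_dy(cg$x, cg$y, cg$z),
               phi_dz(cg$x, cg$y, cg$z), rep(h, 3))
    m <- curl_map(d)$magnitude
    int <- 3:(dim(m)[1] - 2)
    max(m[int, int, int])
  }
  e2 <- curl_err(2)
  e1 <- curl_err(1)
  expect_lt(e1, e2 / 2.5)          # ~h^2 convergence
})

test_that("qa_report bundles the available metrics", {
  set.seed(5)
  a <- make_img(runif(8^3), c(8, 8, 8))
  rep <- qa_report(a, a, dvf = dvf3d(array(0, c(8, 8, 8)),
                                     array(0, c(8, 8, 8)),
                                     array(0, c(8, 8, 8)), c(1, 1, 1)))
  expect_s3_class(rep, "qa_report")
  expect_equal(rep$vic, 1.0)
  expect_equal(rep$vid, 0.0)
  expect_equal(rep$jac_min, 1.0)
  expect_true(is.na(rep$dice))
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 1)
})
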