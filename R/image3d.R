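#' 3-D scalar image with physical geometry
#'
#' The basic container of the package: a 3-D array of intensities together
#' with isotropic-or-not voxel spacing and a physical origin, both in mm.
#' Axis order is fixed as (x = right-left, y = anterior-posterior,
#' z = superior-inferior); the centre of voxel `(i, j, k)` (0-based) sits at
#' `origin + c(i, j, k) * spacing`.
#'
#' @param data numeric 3-D array of finite intensities, at least 2 voxels per
#'   axis.
#' @param spacing numeric 3-vector, mm per voxel, all positive.
#' @param origin numeric 3-vector, mm position of the first voxel centre.
#' @return An object of class `image3d`.
#' @export
image3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 2L))
    stop("image must have at least 2 voxels per axis")
  if (!all(is.finite(data)))
    stop("image intensities must be finite (no NA/NaN/Inf)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image3d")
}

#' @export
dim.image3d <- function(x) dim(x$data)

#' @export
as.array.image3d <- function(x, ...) x$data

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image3d> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

is_image3d <- function(x) inherits(x, "image3d")

# Grids match when dims agree and spacing/origin agree to 1e-6 mm.
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# Physical coordinates (mm) of all voxel centres, as three arrays.
voxel_coords <- function(img) {
  d <- dim(img$data)
  list(
    x = array(rep(img$origin[1] + (seq_len(d[1]) - 1) * img$spacing[1],
                  times = d[2] * d[3]), d),
    y = array(rep(rep(img$origin[2] + (seq_len(d[2]) - 1) * img$spacing[2],
                      each = d[1]), times = d[3]), d),
    z = array(rep(img$origin[3] + (seq_len(d[3]) - 1) * img$spacing[3],
                  each = d[1] * d[2]), d)
  )
}

#' Normalize image intensity to the unit range with trimmed extremes
#'
#' Computes an intensity window from a region of interest by averaging the
#' lowest and highest `trim_fraction` of ROI intensities (guards against
#' single-voxel spikes in 12-bit MR data) and linearly rescales the whole
#' image so the window maps to \[0, 1\], clipping outside it.
#'
#' @param img an [image3d].
#' @param roi logical array on the image grid; window statistics are computed
#'   from these voxels only. Default: whole image.
#' @param trim_fraction fraction (in `[0, 0.5)`) of extreme intensities to
#'   average for the window endpoints; `0` uses the plain min/max.
#' @return list with `image` (rescaled [image3d]) and `window` (list with
#'   `lo`, `hi`, `trim_fraction`).
#' @export
normalize_intensity <- function(img, roi = NULL, trim_fraction = 0.01) {
  stopifnot(is_image3d(img))
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("`trim_fraction` must be in [0, 0.5)")
  if (is.null(roi)) roi <- array(TRUE, dim(img$data))
  if (!any(roi)) stop("empty ROI: no voxels to normalize over")
  v <- sort(img$data[roi])
  n <- length(v)
  if (v[1] == v[n]) stop("constant image within ROI: degenerate window")
  k <- if (trim_fraction == 0) 1L else max(1L, floor(trim_fraction * n))
  lo <- if (trim_fraction == 0) v[1] else mean(v[seq_len(k)])
  hi <- if (trim_fraction == 0) v[n] else mean(v[n - seq_len(k) + 1])
  if (hi == lo) stop("constant image within ROI: degenerate window")
  out <- pmin(pmax((img$data - lo) / (hi - lo), 0), 1)
  list(image = image3d(out, img$spacing, img$origin),
       window = list(lo = lo, hi = hi, trim_fraction = trim_fraction))
}

#' Add Rayleigh-distributed background noise
#'
#' Adds an independent Rayleigh sample (scale `level`) to every voxel,
#' mimicking magnitude-MR background noise on a normalized \[0, 1\] image.
#'
#' @param img an [image3d], expected to be normalized to \[0, 1\].
#' @param level Rayleigh scale as a fraction of the normalized range
#'   (default 0.02, i.e. "2% noise"); `0` returns the input untouched.
#' @param seed integer seed for reproducibility (the caller's RNG state is
#'   preserved).
#' @return noisy [image3d].
#' @export
add_noise <- function(img, level = 0.02, seed = NULL) {
  stopifnot(is_image3d(img))
  if (level < 0) stop("noise `level` must be >= 0")
  if (level == 0) return(img)
  d <- dim(img$data)
  noise <- with_seed(seed, {
    u <- runif(prod(d))
    array(level * sqrt(-2 * log(u)), d)
  })
  image3d(img$data + noise, img$spacing, img$origin)
}

# Target grid covering the same physical extent: cell edges aligned at the
# inferior/left/anterior face, n = ceil(extent / target_spacing).
resample_grid <- function(img, target_spacing) {
  d <- dim(img$data)
  extent <- d * img$spacing
  n <- as.integer(ceiling(extent / target_spacing - 1e-9))
  if (any(n < 2L))
    stop("target grid would have fewer than 2 voxels on some axis")
  origin <- img$origin - img$spacing / 2 + target_spacing / 2
  list(dim = n, spacing = as.numeric(target_spacing), origin = origin)
}

# 1-D overlap matrix between target cells (rows) and source cells (cols).
overlap_matrix <- function(nt, st, ot, ns, ss, os) {
  # cell i spans [o - s/2 + i*s, o + s/2 + i*s], 0-based
  tl <- ot - st / 2 + (seq_len(nt) - 1) * st
  sl <- os - ss / 2 + (seq_len(ns) - 1) * ss
  w <- matrix(0, nt, ns)
  for (i in seq_len(nt)) {
    lo <- pmax(tl[i], sl)
    hi <- pmin(tl[i] + st, sl + ss)
    ov <- pmax(hi - lo, 0)
    w[i, ] <- ov
  }
  w
}

#' Resample an image to a new voxel spacing
#'
#' `block_mean` models a coarse acquisition: each target voxel is the
#' overlap-weighted average of the source voxels it covers (correct for
#' non-integer factors such as 2 mm to 5 mm). `trilinear` interpolates at
#' the target voxel centres. The output grid covers the same physical extent
#' (within one target voxel), with cell edges aligned at the first face.
#'
#' @param img an [image3d].
#' @param target_spacing numeric scalar or 3-vector, mm.
#' @param method `"trilinear"` or `"block_mean"`.
#' @return resampled [image3d].
#' @export
resample <- function(img, target_spacing,
                     method = c("trilinear", "block_mean")) {
  stopifnot(is_image3d(img))
  method <- match.arg(method)
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(target_spacing <= 0)) stop("`target_spacing` must be positive")
  g <- resample_grid(img, target_spacing)
  if (method == "trilinear")
    return(resample_to(img, g))
  d <- dim(img$data)
  w1 <- overlap_matrix(g$dim[1], g$spacing[1], g$origin[1],
                       d[1], img$spacing[1], img$origin[1])
  w2 <- overlap_matrix(g$dim[2], g$spacing[2], g$origin[2],
                       d[2], img$spacing[2], img$origin[2])
  w3 <- overlap_matrix(g$dim[3], g$spacing[3], g$origin[3],
                       d[3], img$spacing[3], img$origin[3])
  # successive mode products; normalise by total overlap weight per cell
  a <- apply_mode(img$data, w1, 1)
  a <- apply_mode(a, w2, 2)
  a <- apply_mode(a, w3, 3)
  ones <- array(1, d)
  nrm <- apply_mode(ones, w1, 1)
  nrm <- apply_mode(nrm, w2, 2)
  nrm <- apply_mode(nrm, w3, 3)
  image3d(a / pmax(nrm, .Machine$double.eps), g$spacing, g$origin)
}

# Multiply array `a` along mode `mode` by matrix `w` (rows = new size).
apply_mode <- function(a, w, mode) {
  d <- dim(a)
  perm <- c(mode, setdiff(1:3, mode))
  ap <- aperm(a, perm)
  m <- w %*% matrix(ap, nrow = d[mode])
  out <- array(m, c(nrow(w), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Resample an image onto a reference grid
#'
#' Trilinear interpolation of `img` at the voxel centres of `grid` (either an
#' [image3d] or a list with `dim`, `spacing`, `origin`); samples outside the
#' source take the nearest-edge value.
#'
#' @param img an [image3d].
#' @param grid reference grid.
#' @return [image3d] on the reference grid.
#' @export
resample_to <- function(img, grid) {
  if (is_image3d(grid))
    grid <- list(dim = dim(grid$data), spacing = grid$spacing,
                 origin = grid$origin)
  n <- grid$dim
  cx <- (grid$origin[1] + (seq_len(n[1]) - 1) * grid$spacing[1] -
           img$origin[1]) / img$spacing[1]
  cy <- (grid$origin[2] + (seq_len(n[2]) - 1) * grid$spacing[2] -
           img$origin[2]) / img$spacing[2]
  cz <- (grid$origin[3] + (seq_len(n[3]) - 1) * grid$spacing[3] -
           img$origin[3]) / img$spacing[3]
  xs <- array(rep(cx, times = n[2] * n[3]), n)
  ys <- array(rep(rep(cy, each = n[1]), times = n[3]), n)
  zs <- array(rep(cz, each = n[1] * n[2]), n)
  v <- cpp_sample(as.numeric(img$data), dim(img$data),
                  as.numeric(xs), as.numeric(ys), as.numeric(zs))
  image3d(array(v, n), grid$spacing, grid$origin)
}

#' Warp an image by a displacement field
#'
#' Backward mapping with trilinear interpolation:
#' `out(x) = img(x + U(x))`, all in physical mm coordinates. Samples falling
#' outside the image take the nearest-edge value; a zero field is the
#' identity.
#'
#' @param img an [image3d].
#' @param dvf a [dvf3d] on the same grid.
#' @return warped [image3d].
#' @export
warp_image <- function(img, dvf) {
  stopifnot(is_image3d(img), is_dvf3d(dvf))
  if (!same_grid(img, list(data = dvf$ux, spacing = dvf$spacing,
                           origin = dvf$origin)))
    stop("image and displacement field are on different grids")
  v <- cpp_warp(as.numeric(img$data), dim(img$data),
                as.numeric(dvf$ux), as.numeric(dvf$uy), as.numeric(dvf$uz),
                img$spacing)
  image3d(array(v, dim(img$data)), img$spacing, img$origin)
}

# Separable Gaussian smoothing, sigma in voxels (scalar); radius 3*sigma.
gaussian_kernel1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_gaussian <- function(arr, sigma, renorm = TRUE) {
  if (sigma <= 0) return(arr)
  k <- gaussian_kernel1d(sigma)
  array(cpp_convolve_sep(as.numeric(arr), dim(arr), k, renorm), dim(arr))
}

# Separable box mean with an odd window (voxels), edge-renormalised.
box_mean <- function(arr, width) {
  k <- rep(1 / width, width)
  array(cpp_convolve_sep(as.numeric(arr), dim(arr), k, TRUE), dim(arr))
}
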