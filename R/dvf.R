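#' Displacement vector field
#'
#' Per-voxel 3-component displacement in mm, stored as three arrays on an
#' [image3d]-style grid. The field follows the backward-warp convention used
#' by [warp_image()]: `out(x) = img(x + U(x))`.
#'
#' @param ux,uy,uz numeric 3-D arrays of displacement (mm) along x, y, z.
#' @param spacing,origin grid geometry in mm (see [image3d]).
#' @return An object of class `dvf3d`.
#' @export
dvf3d <- function(ux, uy, uz, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(ux)
  if (!identical(d, dim(uy)) || !identical(d, dim(uz)))
    stop("components must share one grid")
  if (!all(is.finite(ux)) || !all(is.finite(uy)) || !all(is.finite(uz)))
    stop("displacement field must be finite everywhere")
  structure(list(ux = ux, uy = uy, uz = uz,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "dvf3d")
}

is_dvf3d <- function(x) inherits(x, "dvf3d")

#' @export
dim.dvf3d <- function(x) dim(x$ux)

#' @export
print.dvf3d <- function(x, ...) {
  d <- dim(x$ux)
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf(
    "<dvf3d> %d x %d x %d voxels, spacing %s mm; |U| mean %.3f max %.3f mm\n",
    d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
    mean(mag), max(mag)))
  invisible(x)
}

zero_dvf <- function(like) {
  d <- if (is_image3d(like)) dim(like$data) else like$dim
  sp <- if (is_image3d(like)) like$spacing else like$spacing
  or <- if (is_image3d(like)) like$origin else like$origin
  z <- array(0, d)
  dvf3d(z, z, z, sp, or)
}

dvf_magnitude <- function(dvf) sqrt(dvf$ux^2 + dvf$uy^2 + dvf$uz^2)

# Component-wise map over the three displacement arrays.
dvf_map <- function(dvf, f) {
  dvf3d(f(dvf$ux), f(dvf$uy), f(dvf$uz), dvf$spacing, dvf$origin)
}

dvf_add <- function(a, b) {
  dvf3d(a$ux + b$ux, a$uy + b$uy, a$uz + b$uz, a$spacing, a$origin)
}

dvf_sub <- function(a, b) {
  dvf3d(a$ux - b$ux, a$uy - b$uy, a$uz - b$uz, a$spacing, a$origin)
}

# Trilinear resampling of a field onto another grid (values stay in mm).
resample_dvf <- function(dvf, grid) {
  as_img <- function(a) image3d(a, dvf$spacing, dvf$origin)
  dvf3d(resample_to(as_img(dvf$ux), grid)$data,
        resample_to(as_img(dvf$uy), grid)$data,
        resample_to(as_img(dvf$uz), grid)$data,
        if (is_image3d(grid)) grid$spacing else grid$spacing,
        if (is_image3d(grid)) grid$origin else grid$origin)
}

#' Compose two displacement fields
#'
#' Returns the field of the warp "first apply `inner`, then look up `outer`
#' at the displaced position": `U(x) = inner(x) + outer(x + inner(x))`.
#' Used to stack the stage-1 field under the sub-ROI refinements.
#'
#' @param outer,inner [dvf3d] objects on the same grid.
#' @return composed [dvf3d].
#' @export
compose_dvf <- function(outer, inner) {
  stopifnot(is_dvf3d(outer), is_dvf3d(inner))
  as_img <- function(a) image3d(a, outer$spacing, outer$origin)
  wx <- warp_image(as_img(outer$ux), inner)$data
  wy <- warp_image(as_img(outer$uy), inner)$data
  wz <- warp_image(as_img(outer$uz), inner)$data
  dvf3d(inner$ux + wx, inner$uy + wy, inner$uz + wz,
        outer$spacing, outer$origin)
}

smooth_dvf <- function(dvf, sigma) {
  if (sigma <= 0) return(dvf)
  dvf_map(dvf, function(a) smooth_gaussian(a, sigma))
}

#' Remove local folding from a displacement field
#'
#' Iteratively replaces the field around voxels with a negative Jacobian
#' determinant by its Gaussian-smoothed version until the folds are gone or
#' the pass budget is exhausted. Local smoothing trades a little alignment
#' in the affected neighbourhood (typically regions without reliable image
#' correspondence) for invertibility.
#'
#' @param dvf a [dvf3d].
#' @param roi logical array restricting where folds are repaired (default
#'   whole grid).
#' @param sigma Gaussian sigma in voxels per pass (default 1).
#' @param margin dilation radius (voxels) of the repair neighbourhood
#'   (default 2).
#' @param max_passes pass budget (default 15).
#' @return repaired [dvf3d].
#' @export
unfold_dvf <- function(dvf, roi = NULL, sigma = 1, margin = 2L,
                       max_passes = 15) {
  stopifnot(is_dvf3d(dvf))
  d <- dim(dvf$ux)
  if (is.null(roi)) roi <- array(TRUE, d)
  neg <- jacobian_map(dvf)$map < 0 & roi
  for (pass in seq_len(max_passes)) {
    if (!any(neg)) break
    # work inside a bounding box around the folds only
    idx <- which(neg, arr.ind = TRUE)
    pad <- margin + ceiling(3 * sigma) + 2L
    lo <- pmax(apply(idx, 2, min) - pad, 1L)
    hi <- pmin(apply(idx, 2, max) + pad, d)
    sl <- lapply(1:3, function(a) lo[a]:hi[a])
    crop <- function(a) a[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    sub <- dvf3d(crop(dvf$ux), crop(dvf$uy), crop(dvf$uz),
                 dvf$spacing, dvf$origin + (lo - 1) * dvf$spacing)
    patch <- dilate_mask(crop(neg), margin)
    sm <- smooth_dvf(sub, sigma)
    fix <- function(comp, s) {
      block <- crop(dvf[[comp]])
      block[patch] <- s[patch]
      out <- dvf[[comp]]
      out[sl[[1]], sl[[2]], sl[[3]]] <- block
      out
    }
    dvf <- dvf3d(fix("ux", sm$ux), fix("uy", sm$uy), fix("uz", sm$uz),
                 dvf$spacing, dvf$origin)
    negsub <- jacobian_map(dvf3d(crop(dvf$ux), crop(dvf$uy), crop(dvf$uz),
                                 dvf$spacing, sub$origin))$map < 0 &
      crop(roi)
    neg <- array(FALSE, d)
    neg[sl[[1]], sl[[2]], sl[[3]]] <- negsub
  }
  dvf
}

#' Transfer landmark points through a registration field
#'
#' A backward field maps target positions to source positions
#' (`source = x + U(x)`), so the target-frame position of a source landmark
#' `p` solves the fixed-point equation `x = p - U(x)`, iterated with
#' trilinear sampling of the field.
#'
#' @param points n-by-3 matrix of source-frame landmark coordinates (mm).
#' @param dvf a [dvf3d].
#' @param iters fixed-point iterations (default 10).
#' @return n-by-3 matrix of predicted target-frame coordinates (mm).
#' @export
transfer_landmarks <- function(points, dvf, iters = 10) {
  stopifnot(is_dvf3d(dvf))
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dim(dvf$ux)
  sample_u <- function(p) {
    vx <- (p[, 1] - dvf$origin[1]) / dvf$spacing[1]
    vy <- (p[, 2] - dvf$origin[2]) / dvf$spacing[2]
    vz <- (p[, 3] - dvf$origin[3]) / dvf$spacing[3]
    cbind(cpp_sample(as.numeric(dvf$ux), d, vx, vy, vz),
          cpp_sample(as.numeric(dvf$uy), d, vx, vy, vz),
          cpp_sample(as.numeric(dvf$uz), d, vx, vy, vz))
  }
  x <- points
  for (i in seq_len(iters)) x <- points - sample_u(x)
  x
}
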