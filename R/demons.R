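#' Demons registration hyperparameters
#'
#' @param pyramid_factors multi-resolution downsampling factors, strictly
#'   decreasing and ending at 1 (default `c(6, 2, 1)`, i.e. registration at
#'   6x, 2x and 1x the native voxel size).
#' @param pseudo_kernel_size edge length (voxels) of the box over which each
#'   voxel's force is spread at coarse levels (default 5, i.e. the 124
#'   nearest neighbours).
#' @param pseudo_sigma Gaussian sigma (voxels) of the spreading weights
#'   (default 1).
#' @param pseudo_level pyramid factors `>=` this value apply the pseudo-force
#'   spreading (default 6: coarsest level only).
#' @param regularization_sigma Gaussian sigma (voxels) applied to the
#'   accumulated field after every iteration (default 1).
#' @param max_iters iteration cap per level, coarse to fine (recycled;
#'   default `c(300, 100, 50)`).
#' @param stop_dvid stop a level once the relative change of the voxel
#'   intensity difference between consecutive iterations falls below this
#'   (default `1e-4` for a conventional full registration; the hybrid
#'   pipeline relaxes its first stage to `1e-3`). Non-native pyramid levels
#'   apply a 10x stricter version of the same criterion.
#' @param force_epsilon stabiliser added to the Demons force denominator
#'   (default `1e-6`).
#' @param force force model passed to [demons_update()] (default
#'   `"symmetric"`).
#' @param increment_sigma Gaussian sigma (voxels) applied to each force
#'   increment before accumulation (fluid-like viscosity; default 0: off).
#' @param diff_threshold intensity residuals smaller than this generate no
#'   force (default 0.05, about twice the noise level of a 2% Rayleigh
#'   background on normalized images); stops noise from random-walking the
#'   field. Set 0 to disable.
#' @param psf_sigma Gaussian sigma (native voxels) applied to the warped
#'   moving image before each force evaluation, matching a sharp moving
#'   image to the point-spread of a blurred static; the output warp stays
#'   sharp. Default 0 (off); the hybrid refinements use it to register the
#'   2 mm image against the 5 mm-derived frame.
#' @return object of class `demons_params`.
#' @export
demons_params <- function(pyramid_factors = c(6, 2, 1),
                          pseudo_kernel_size = 5,
                          pseudo_sigma = 1,
                          pseudo_level = 6,
                          regularization_sigma = 1,
                          max_iters = c(300, 100, 50),
                          stop_dvid = 1e-4,
                          force_epsilon = 1e-6,
                          force = c("symmetric", "passive"),
                          increment_sigma = 0,
                          diff_threshold = 0.05,
                          psf_sigma = 0) {
  force <- match.arg(force)
  pyramid_factors <- as.numeric(pyramid_factors)
  if (any(diff(pyramid_factors) >= 0) && length(pyramid_factors) > 1)
    stop("`pyramid_factors` must be strictly decreasing")
  if (pyramid_factors[length(pyramid_factors)] != 1)
    stop("`pyramid_factors` must end at 1 (native resolution)")
  if (stop_dvid <= 0) stop("`stop_dvid` must be > 0")
  if (pseudo_kernel_size %% 2 != 1) stop("pseudo kernel size must be odd")
  structure(list(pyramid_factors = pyramid_factors,
                 pseudo_kernel_size = as.integer(pseudo_kernel_size),
                 pseudo_sigma = pseudo_sigma,
                 pseudo_level = pseudo_level,
                 regularization_sigma = regularization_sigma,
                 max_iters = rep(as.integer(max_iters),
                                 length.out = length(pyramid_factors)),
                 stop_dvid = stop_dvid,
                 force_epsilon = force_epsilon,
                 force = force,
                 increment_sigma = increment_sigma,
                 diff_threshold = diff_threshold,
                 psf_sigma = psf_sigma),
            class = "demons_params")
}

#' Physical reach of the pseudo-force at a pyramid level
#'
#' Half-width of the spreading box in mm:
#' `spacing * (kernel_size / 2) * factor` — e.g. 2 mm x (5/2) x 6 = 30 mm at
#' the coarsest level of a 2 mm image.
#'
#' @param params a [demons_params].
#' @param spacing native voxel size (mm, scalar).
#' @param factor pyramid factor (default: the coarsest).
#' @return reach in mm.
#' @export
pseudo_force_reach <- function(params, spacing,
                               factor = max(params$pyramid_factors)) {
  spacing * (params$pseudo_kernel_size / 2) * factor
}

#' Mean absolute voxel intensity difference (VID)
#'
#' `(1/N) * sum(|I_m - I_s|)` over the N ROI voxels; the registration
#' cost whose relative change drives the stopping criterion.
#'
#' @param a,b [image3d] objects on the same grid.
#' @param roi logical array; default whole grid.
#' @return scalar VID.
#' @export
compute_vid <- function(a, b, roi = NULL) {
  stopifnot(is_image3d(a), is_image3d(b))
  if (!same_grid(a, b)) stop("images are on different grids")
  if (is.null(roi)) roi <- array(TRUE, dim(a$data))
  if (!any(roi)) stop("empty ROI")
  mean(abs(a$data[roi] - b$data[roi]))
}

#' Single Demons force increment
#'
#' Passive (Thirion) force driven by the static image gradient:
#' `u = (I_s - I_m) * grad(I_s) / (|grad(I_s)|^2 + (I_s - I_m)^2 + eps)`,
#' evaluated per voxel with the gradient in voxel units and the returned
#' displacement converted to mm. Zero where the denominator is degenerate
#' and outside the ROI.
#'
#' @param static static (target-frame) [image3d], normalized.
#' @param moving_warped the moving image already warped by the current
#'   field, on the static grid.
#' @param roi logical array.
#' @param eps denominator stabiliser.
#' @param force `"passive"` drives the update with the static gradient
#'   only (classic Thirion); `"symmetric"` averages the static and
#'   warped-moving gradients, which keeps a force alive where one image is
#'   locally flat — important when a sharp 2 mm image is registered to a
#'   blurred 5 mm one.
#' @return a [dvf3d] increment (mm).
#' @export
demons_update <- function(static, moving_warped, roi = NULL, eps = 1e-6,
                          force = c("symmetric", "passive")) {
  stopifnot(is_image3d(static), is_image3d(moving_warped))
  force <- match.arg(force)
  if (!same_grid(static, moving_warped))
    stop("images are on different grids")
  if (is.null(roi)) roi <- array(TRUE, dim(static$data))
  f <- cpp_demons_force(as.numeric(static$data),
                        as.numeric(moving_warped$data),
                        dim(static$data), as.logical(roi),
                        static$spacing, eps, force == "symmetric")
  n <- dim(static$data)
  dvf3d(array(f$ux, n), array(f$uy, n), array(f$uz, n),
        static$spacing, static$origin)
}

# Normalized 5x5x5 (by default) Gaussian spreading kernel, one axis.
pseudo_kernel1d <- function(size = 5, sigma = 1) {
  r <- (size - 1) / 2
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Spread a force field over its 5x5x5 neighbourhood (pseudo-force)
#'
#' Distributes each voxel's force to its `size^3 - 1` nearest neighbours
#' with normalized Gaussian weights — equivalently, convolution of each
#' component with the normalized separable kernel (zero padding, so the
#' total vector sum is conserved for interior-supported fields). Applied at
#' the coarsest pyramid level, this gives each update a long physical reach
#' (see [pseudo_force_reach()]).
#'
#' @param increment a [dvf3d] force increment.
#' @param size odd box size in voxels (default 5).
#' @param sigma Gaussian sigma in voxels (default 1).
#' @return spread [dvf3d].
#' @export
pseudo_force_spread <- function(increment, size = 5, sigma = 1) {
  stopifnot(is_dvf3d(increment))
  k <- pseudo_kernel1d(size, sigma)
  dvf_map(increment, function(a)
    array(cpp_convolve_sep(as.numeric(a), dim(a), k, FALSE), dim(a)))
}

# One pyramid level of an image: Gaussian prefilter (sigma = factor/2) then
# trilinear resampling to factor * spacing.
pyramid_level <- function(img, factor) {
  if (factor == 1) return(img)
  pre <- image3d(smooth_gaussian(img$data, factor / 2), img$spacing,
                 img$origin)
  resample(pre, img$spacing * factor, method = "trilinear")
}

pyramid_mask <- function(roi, img, factor) {
  if (factor == 1) return(roi)
  m <- resample(image3d(array(as.numeric(roi), dim(roi)), img$spacing,
                        img$origin),
                img$spacing * factor, method = "block_mean")
  m$data > 0.25
}

#' Multi-resolution Demons registration
#'
#' Registers `moving` onto `static` (both normalized to \[0, 1\] on a common
#' grid) through a coarse-to-fine pyramid. At each level the loop is:
#' warp the moving image with the current field, evaluate the VID, compute
#' the Demons increment, spread it as a pseudo-force at coarse levels
#' (factor `>= pseudo_level`), accumulate additively, and Gaussian-smooth
#' the field. A level stops when the relative VID change drops below
#' `stop_dvid` or the iteration cap is reached; an iteration that increases
#' the VID by more than 5% is rejected and ends the level.
#'
#' @param static,moving [image3d] objects on the same grid, normalized.
#' @param roi logical array (e.g. the union of body masks); forces are zero
#'   outside it. Default: whole grid.
#' @param params a [demons_params].
#' @param init optional initial [dvf3d] on the static grid (warm start).
#' @param levels optional subset of pyramid factors to run (default all).
#' @return object of class `demons_registration`: `dvf`, `deformed`
#'   (`warp_image(moving, dvf)`), `iterations` per level, `final_vid`, and
#'   the per-level VID `trace`.
#' @export
register_demons <- function(static, moving, roi = NULL,
                            params = demons_params(), init = NULL,
                            levels = NULL) {
  stopifnot(is_image3d(static), is_image3d(moving))
  if (!same_grid(static, moving)) stop("images are on different grids")
  if (is.null(roi)) roi <- array(TRUE, dim(static$data))
  factors <- if (is.null(levels)) params$pyramid_factors else levels
  u <- init
  traces <- list()
  iters <- integer(0)
  vid <- NA_real_
  for (li in seq_along(factors)) {
    f <- factors[li]
    s_l <- pyramid_level(static, f)
    m_l <- pyramid_level(moving, f)
    roi_l <- pyramid_mask(roi, static, f)
    u <- if (is.null(u)) zero_dvf(s_l) else resample_dvf(u, s_l)
    spread <- f >= params$pseudo_level
    psf <- (params$psf_sigma %||% 0) / f     # sigma in this level's voxels
    cap <- params$max_iters[min(li, length(params$max_iters))]
    # coarse iterations are cheap and their convergence is what buys the
    # deformation range, so non-native levels use a 10x stricter criterion
    thr <- params$stop_dvid * if (f > 1) 0.1 else 1
    trace <- numeric(0)
    vid_prev <- Inf
    u_prev <- u
    it <- 0
    while (it < cap) {
      it <- it + 1
      mw <- warp_image(m_l, u)
      if (psf > 0.25)
        mw <- image3d(smooth_gaussian(mw$data, psf), mw$spacing, mw$origin)
      vid <- compute_vid(s_l, mw, roi_l)
      if (!is.finite(vid))
        stop("registration diverged: non-finite VID (trace attached)",
             call. = FALSE)
      trace <- c(trace, vid)
      if (is.finite(vid_prev)) {
        if (vid > 1.05 * vid_prev) {        # reject, keep previous field
          u <- u_prev
          vid <- vid_prev
          trace <- trace[-length(trace)]
          break
        }
        if (vid_prev == 0 || abs(vid_prev - vid) / vid_prev < thr) break
        # stagnation guard: noise can jitter the VID forever without net
        # progress; require real improvement over a 5-iteration window.
        # The coarsest (pseudo-force) level is exempt — its slow grind is
        # what recovers large displacements.
        if (!spread && it > 5 &&
              (trace[it - 5] - vid) / trace[it - 5] < 5 * thr)
          break
      }
      # noise shrinks under the pyramid prefilter, so the floor scales down
      # with the level factor — but residual blur mismatch does not vanish,
      # so it never drops below 0.015
      dth <- (params$diff_threshold %||% 0) / f
      if (dth > 0) dth <- max(dth, min(params$diff_threshold, 0.015))
      if (dth > 0) {
        sel <- abs(s_l$data - mw$data) < dth
        mw$data[sel] <- s_l$data[sel]
      }
      inc <- demons_update(s_l, mw, roi_l, params$force_epsilon,
                           force = params$force %||% "symmetric")
      if (spread)
        inc <- pseudo_force_spread(inc, params$pseudo_kernel_size,
                                   params$pseudo_sigma)
      if ((params$increment_sigma %||% 0) > 0)
        inc <- smooth_dvf(inc, params$increment_sigma)
      u_prev <- u
      u <- smooth_dvf(dvf_add(u, inc), params$regularization_sigma)
      if (!all(is.finite(u$ux)) || !all(is.finite(u$uy)) ||
            !all(is.finite(u$uz)))
        stop("registration diverged: non-finite field", call. = FALSE)
      vid_prev <- vid
    }
    traces[[li]] <- trace
    iters <- c(iters, it)
  }
  if (!identical(as.numeric(factors[length(factors)]), 1))
    u <- resample_dvf(u, static)
  structure(list(dvf = u, deformed = warp_image(moving, u),
                 iterations = iters, final_vid = vid, trace = traces),
            class = "demons_registration")
}

#' @export
print.demons_registration <- function(x, ...) {
  cat(sprintf("<demons_registration> levels: %s iterations, final VID %.5g\n",
              paste(x$iterations, collapse = "/"), x$final_vid))
  invisible(x)
}
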