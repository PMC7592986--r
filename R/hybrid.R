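# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(v, nbins = 256) {
  r <- range(v)
  if (r[1] == r[2]) stop("cannot threshold a constant image")
  h <- tabulate(pmin(pmax(
    as.integer((v - r[1]) / (r[2] - r[1]) * nbins) + 1L, 1L), nbins),
    nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nbins) - 0.5) * (r[2] - r[1]) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

largest_components <- function(mask, keep = 1L, min_voxels = 0L) {
  lab <- array(cpp_label6(as.logical(mask), dim(mask)), dim(mask))
  if (max(lab) == 0) return(list(mask = mask & FALSE, sizes = integer(0)))
  sizes <- tabulate(lab[lab > 0])
  ord <- order(sizes, decreasing = TRUE)
  ids <- ord[seq_len(min(keep, length(ord)))]
  ids <- ids[sizes[ids] >= min_voxels]
  list(mask = array(lab %in% ids, dim(mask)), sizes = sizes[ids])
}

fill_holes <- function(mask) {
  bg <- array(cpp_label6(!mask, dim(mask)), dim(mask))
  if (max(bg) == 0) return(mask)
  d <- dim(mask)
  border_labels <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                            bg[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

# Light morphological regularisation: Gaussian-smooth the indicator and
# re-threshold at 0.5 (closes pinholes, rounds staircase edges).
smooth_mask <- function(mask, sigma = 1) {
  smooth_gaussian(array(as.numeric(mask), dim(mask)), sigma) > 0.5
}

#' Automatic body segmentation
#'
#' Otsu threshold on the intensity histogram, largest 6-connected
#' component, then morphological hole filling. The registration ROI is the
#' voxelwise union of the two images' body masks.
#'
#' @param img an [image3d].
#' @return logical body mask.
#' @export
segment_body <- function(img) {
  stopifnot(is_image3d(img))
  v <- as.numeric(img$data)
  if (min(v) == max(v)) stop("empty segmentation: constant image")
  th <- otsu_threshold(v)
  cand <- img$data > th
  if (!any(cand)) stop("empty segmentation: no voxels above threshold")
  body <- fill_holes(largest_components(cand, 1L)$mask)
  if (!any(body)) stop("empty segmentation")
  body
}

#' Automatic lung segmentation inside a body mask
#'
#' Splits the body's bimodal histogram at its valley (Otsu over body
#' voxels), keeps the up-to-two largest low-intensity components above a
#' volume floor, and lightly closes the result. Intended to run on the
#' stage-1 deformed breath-hold image; the same contour is then reused
#' ("directly mapped") on the free-breathing-grid image.
#'
#' @param img an [image3d] (typically the stage-1 deformed image).
#' @param body logical body mask.
#' @param min_fraction volume floor as a fraction of the body volume
#'   (default 0.02); smaller dark blobs are bubbles, not lungs.
#' @return logical lung mask.
#' @export
segment_lungs <- function(img, body, min_fraction = 0.02) {
  stopifnot(is_image3d(img))
  if (!any(body)) stop("empty body mask")
  th <- otsu_threshold(img$data[body])
  cand <- body & (img$data < th)
  floor_vox <- max(1L, as.integer(min_fraction * sum(body)))
  comp <- largest_components(cand, 2L, floor_vox)
  if (!any(comp$mask))
    stop("no lung-scale low-intensity component found")
  smooth_mask(comp$mask, 1) & body
}

#' Detect and fill abdominal air bubbles
#'
#' Low-intensity connected components inside the bodyshell whose volume is
#' below the lung floor are re-assigned the mean intensity of the remaining
#' bodyshell voxels (air pockets do not correspond across breathing phases
#' and would otherwise attract the registration).
#'
#' @param img an [image3d].
#' @param bodyshell logical bodyshell (body minus lungs) mask.
#' @param threshold air/tissue intensity cutoff; pass the lung threshold
#'   when one is available (the pipeline does). Default: half the median
#'   bodyshell intensity, since air pockets sit near zero while soft tissue
#'   occupies the upper band.
#' @param max_fraction upper volume bound for a bubble as a fraction of the
#'   bodyshell volume (default 0.02).
#' @return list with `image` (filled [image3d]) and `bubble_mask`.
#' @export
fill_bubbles <- function(img, bodyshell, threshold = NULL,
                         max_fraction = 0.02) {
  stopifnot(is_image3d(img))
  if (!any(bodyshell)) stop("empty bodyshell mask")
  th <- threshold %||% (0.5 * stats::median(img$data[bodyshell]))
  cand <- bodyshell & (img$data < th)
  if (!any(cand))
    return(list(image = img, bubble_mask = cand))
  lab <- array(cpp_label6(as.logical(cand), dim(cand)), dim(cand))
  sizes <- tabulate(lab[lab > 0])
  cap <- max_fraction * sum(bodyshell)
  small <- which(sizes <= cap)
  bubble <- array(lab %in% small, dim(cand))
  if (!any(bubble))
    return(list(image = img, bubble_mask = bubble))
  fill_value <- mean(img$data[bodyshell & !bubble])
  out <- img$data
  out[bubble] <- fill_value
  list(image = image3d(out, img$spacing, img$origin), bubble_mask = bubble)
}

#' Renormalize a sub-ROI to the full dynamic range
#'
#' Contrast enhancement for a low-dynamic-range region: the 1%-trimmed
#' intensity window of the sub-ROI voxels is stretched to \[0, 1\]
#' (monotone inside the window), and everything outside the sub-ROI is set
#' to zero. This is what makes low-contrast structure drive the refinement
#' registrations.
#'
#' @param img an [image3d].
#' @param sub_roi logical mask (lungs or bodyshell).
#' @param trim_fraction window trim (default 0.01).
#' @param window optional precomputed window (list with `lo`, `hi`) applied
#'   instead of computing one from `img` — used to stretch two images of
#'   the same sub-ROI onto one common scale.
#' @return renormalized [image3d], zero outside `sub_roi`, with the window
#'   attached as attribute `"window"`.
#' @export
renormalize_subroi <- function(img, sub_roi, trim_fraction = 0.01,
                               window = NULL) {
  stopifnot(is_image3d(img))
  if (!any(sub_roi)) stop("empty sub-ROI")
  if (is.null(window)) {
    norm <- normalize_intensity(img, sub_roi, trim_fraction)
    out <- norm$image$data
    window <- norm$window
  } else {
    if (window$hi <= window$lo) stop("degenerate window")
    out <- pmin(pmax((img$data - window$lo) / (window$hi - window$lo), 0), 1)
  }
  out[!sub_roi] <- 0
  res <- image3d(out, img$spacing, img$origin)
  attr(res, "window") <- window
  res
}

#' Monotone histogram matching within an ROI
#'
#' Maps the moving image's intensity distribution onto the reference's by
#' quantile correspondence inside the ROI (the standard preprocessing for
#' intensity-difference-driven registration: without it, a global
#' brightness offset between the images masquerades as deformation).
#' Outside the ROI the image is left unchanged.
#'
#' @param img image to remap ([image3d]).
#' @param ref reference [image3d] on the same grid.
#' @param roi logical array over which the distributions are computed.
#' @param n_quantiles number of anchor quantiles (default 256).
#' @return remapped [image3d].
#' @export
histogram_match <- function(img, ref, roi = NULL, n_quantiles = 256) {
  stopifnot(is_image3d(img), is_image3d(ref))
  if (is.null(roi)) roi <- array(TRUE, dim(img$data))
  if (!any(roi)) stop("empty ROI")
  p <- seq(0, 1, length.out = n_quantiles + 1)
  qi <- stats::quantile(img$data[roi], p, names = FALSE, type = 7)
  qr <- stats::quantile(ref$data[roi], p, names = FALSE, type = 7)
  keep <- !duplicated(qi)
  if (sum(keep) < 2) return(img)  # constant source: nothing to match
  out <- img$data
  out[roi] <- stats::approx(qi[keep], qr[keep], xout = img$data[roi],
                            rule = 2)$y
  image3d(out, img$spacing, img$origin)
}

# Binary dilation by `r` voxels via box maximum (separable box mean > 0).
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  box_mean(array(as.numeric(mask), dim(mask)), 2 * r + 1) > 1e-12
}

#' Combine the two sub-ROI refinement fields
#'
#' The lung and bodyshell refinement fields have disjoint supports, so
#' their voxelwise sum stitches them; one Gaussian pass then replaces the
#' field inside a band of `band` voxels around the lung/bodyshell interface
#' to avoid a seam.
#'
#' @param dvf_lung,dvf_body [dvf3d] refinements supported on their own
#'   sub-ROI (zero outside).
#' @param lung_mask,bodyshell_mask the sub-ROI partition.
#' @param band half-width of the interface band in voxels (default 2).
#' @param sigma Gaussian sigma (voxels) of the seam smoothing (default 1).
#' @return combined [dvf3d].
#' @export
combine_dvfs <- function(dvf_lung, dvf_body, lung_mask, bodyshell_mask,
                         band = 2, sigma = 1) {
  stopifnot(is_dvf3d(dvf_lung), is_dvf3d(dvf_body))
  iface <- dilate_mask(lung_mask, band) & dilate_mask(bodyshell_mask, band)
  both <- (dvf_magnitude(dvf_lung) > 0) & (dvf_magnitude(dvf_body) > 0)
  if (any(both & !iface))
    warning("sub-ROI fields overlap beyond the interface band")
  combined <- dvf_add(dvf_lung, dvf_body)
  if (any(iface)) {
    sm <- smooth_dvf(combined, sigma)
    blend <- function(a, b) {
      a[iface] <- b[iface]
      a
    }
    combined <- dvf3d(blend(combined$ux, sm$ux), blend(combined$uy, sm$uy),
                      blend(combined$uz, sm$uz),
                      combined$spacing, combined$origin)
  }
  combined
}

# Sub-ROI refinement: evolve the whole-field warm start under forces
# restricted to the sub-ROI, with the renormalization window applied AFTER
# warping and point-spread matching (the same processing order the blurred
# acquisition went through), a symmetric Demons force, an intensity
# difference floor below the noise level, and fluid-dominant regularization
# (increment smoothing) with light field smoothing, which lets boundary
# corrections persist against the surrounding field.
refine_subroi <- function(static, moving, sub_roi, init, window,
                          pyramid = c(2, 1), psf_sigma = 0.9,
                          sigma_inc = 1.5, sigma_field = 0.5,
                          diff_threshold = 0.05, adaptive_floor = FALSE,
                          max_iters = c(40, 50),
                          stop_dvid = 1e-5, eps = 1e-6) {
  wmap <- function(x) {
    pmin(pmax((x - window$lo) / (window$hi - window$lo), 0), 1)
  }
  max_iters <- rep(max_iters, length.out = length(pyramid))
  u <- init
  iters <- integer(0)
  traces <- list()
  for (li in seq_along(pyramid)) {
    f <- pyramid[li]
    s_l <- pyramid_level(static, f)
    m_l <- pyramid_level(moving, f)
    roi_l <- pyramid_mask(sub_roi, static, f)
    u <- resample_dvf(u, s_l)
    psf <- psf_sigma / f
    s_n <- image3d({
      v <- wmap(s_l$data)
      v[!roi_l] <- 0
      v
    }, s_l$spacing, s_l$origin)
    u_prev <- u
    vid_prev <- Inf
    trace <- numeric(0)
    it <- 0
    # force floor adapted to this sub-ROI's own (window-amplified) noise,
    # estimated from the static image's high-frequency residual — robust
    # to genuine structure through the MAD
    dth <- diff_threshold
    if (adaptive_floor) {
      hf <- s_n$data - smooth_gaussian(s_n$data, 1)
      dth <- max(diff_threshold, 2.5 * stats::mad(hf[roi_l]))
    }
    while (it < max_iters[li]) {
      it <- it + 1
      mw <- warp_image(m_l, u)
      if (psf > 0.25)
        mw <- image3d(smooth_gaussian(mw$data, psf), mw$spacing, mw$origin)
      mwv <- wmap(mw$data)
      mwv[!roi_l] <- 0
      vid <- mean(abs(s_n$data[roi_l] - mwv[roi_l]))
      trace <- c(trace, vid)
      if (is.finite(vid_prev)) {
        if (vid > 1.05 * vid_prev) {
          u <- u_prev
          trace <- trace[-length(trace)]
          break
        }
        if (vid_prev == 0 || abs(vid_prev - vid) / vid_prev < stop_dvid)
          break
        if (it > 5 &&
              (trace[it - 5] - vid) / trace[it - 5] < 5 * stop_dvid)
          break
      }
      # zero the force where the residual is within the noise floor
      sel <- abs(s_n$data - mwv) < dth
      mwv[sel] <- s_n$data[sel]
      inc <- demons_update(s_n, image3d(mwv, mw$spacing, mw$origin),
                           roi_l, eps, force = "symmetric")
      if (sigma_inc > 0) inc <- smooth_dvf(inc, sigma_inc)
      u_prev <- u
      u <- dvf_add(u, inc)
      if (sigma_field > 0) u <- smooth_dvf(u, sigma_field)
      vid_prev <- vid
    }
    iters <- c(iters, it)
    traces[[li]] <- trace
  }
  if (pyramid[length(pyramid)] != 1) u <- resample_dvf(u, static)
  list(dvf = u, iterations = iters, trace = traces)
}

mask_dvf <- function(dvf, mask) {
  z <- function(a) {
    a[!mask] <- 0
    a
  }
  dvf3d(z(dvf$ux), z(dvf$uy), z(dvf$uz), dvf$spacing, dvf$origin)
}

#' One-step (conventional) super-resolution registration
#'
#' The control arm: normalization, body-union ROI, and a single
#' multi-resolution Demons registration of the breath-hold image onto the
#' (upsampled) free-breathing frame at `stop_dvid = 1e-4`.
#'
#' @param bh high-resolution breath-hold [image3d] (moving).
#' @param fb_low low-resolution free-breathing frame [image3d] (static;
#'   resampled internally onto the breath-hold grid).
#' @param params a [demons_params].
#' @param init optional warm-start [dvf3d].
#' @return list with `dvf`, `reconstructed`, `registration`, `roi`,
#'   `static` (the upsampled, normalized frame).
#' @export
run_conventional <- function(bh, fb_low, params = demons_params(),
                             init = NULL) {
  pre <- prepare_pair(bh, fb_low)
  p1 <- params
  p1$stop_dvid <- 1e-4
  # registering a sharp 2 mm image against a 5 mm-derived frame: match the
  # moving image's point-spread during force evaluation unless configured
  if ((p1$psf_sigma %||% 0) == 0) p1$psf_sigma <- 0.9
  reg <- register_demons(pre$static, pre$moving, pre$roi, p1, init = init)
  dvf <- unfold_dvf(reg$dvf, pre$roi)
  list(dvf = dvf, reconstructed = warp_image(pre$moving, dvf),
       registration = reg,
       roi = pre$roi, static = pre$static, moving = pre$moving)
}

# Shared front end: upsample the cine frame onto the BH grid, segment both
# bodies, remove each image's background offset (the mean intensity outside
# the body, non-zero for magnitude-MR noise), and normalize both images
# over their own body.
prepare_pair <- function(bh, fb_low) {
  stopifnot(is_image3d(bh), is_image3d(fb_low))
  fb <- if (same_grid(bh, fb_low)) fb_low else resample_to(fb_low, bh)
  body_bh <- segment_body(bh)
  body_fb <- segment_body(fb)
  strip_background <- function(img, body) {
    if (all(body)) return(img)
    # keep clear of the partial-volume ring around the body surface, which
    # would otherwise inflate the background estimate
    far <- !dilate_mask(body, 4L)
    if (!any(far)) far <- !body
    image3d(pmax(img$data - mean(img$data[far]), 0),
            img$spacing, img$origin)
  }
  fb <- strip_background(fb, body_fb)
  bh <- strip_background(bh, body_bh)
  roi <- body_bh | body_fb
  list(static = normalize_intensity(fb, body_fb)$image,
       moving = normalize_intensity(bh, body_bh)$image,
       roi = roi, body_bh = body_bh, body_fb = body_fb)
}

#' Two-step hybrid super-resolution registration
#'
#' The full pipeline: (1) conventional multi-resolution Demons registration
#' on the body-union ROI with a relaxed stopping criterion
#' (`stop_dvid = 1e-3`) to align high-contrast tissue; (2) global affine
#' intensity calibration of the frame against the deformed breath-hold,
#' lung segmentation on the deformed breath-hold image (contour reused on
#' the frame), air-bubble filling in the bodyshell of both images,
#' renormalization of each sub-ROI to the full dynamic range with a window
#' shared between the images, an independent warm-started Demons refinement
#' per sub-ROI, recombination of the two refinement fields with seam
#' smoothing, and a final fine-tuning registration restricted to the
#' lung/bodyshell interface band at native resolution.
#'
#' @param bh high-resolution breath-hold [image3d] (moving).
#' @param fb_low low-resolution free-breathing frame (static; resampled
#'   internally onto the breath-hold grid).
#' @param params a [demons_params] for stage 1.
#' @param refine_params named list overriding the sub-ROI refinement
#'   settings (`psf_sigma`, `sigma_inc`, `sigma_field`, `diff_threshold`,
#'   `max_iters`, `stop_dvid`).
#' @param finetune_iters iteration cap of the final interface tuning
#'   (default 15).
#' @param init optional warm-start [dvf3d] for stage 1.
#' @return object of class `hybrid_result`: `step1` registration, sub-ROI
#'   fields `dvf_lung`/`dvf_body`, `combined` field (stage 1 + refinements),
#'   `final` registration, total `dvf`, `reconstructed` high-resolution
#'   frame, the sub-ROI `partition`, `roi`, `static`, and `qa` report.
#' @export
run_two_step <- function(bh, fb_low, params = demons_params(),
                         refine_params = NULL, finetune_iters = 15,
                         init = NULL) {
  pre <- prepare_pair(bh, fb_low)
  p1 <- params
  p1$stop_dvid <- 1e-3
  if ((p1$psf_sigma %||% 0) == 0) p1$psf_sigma <- 0.9
  step1 <- register_demons(pre$static, pre$moving, pre$roi, p1, init = init)

  def1 <- step1$deformed
  # global affine intensity calibration of the frame onto the deformed BH:
  # after stage 1 most voxels correspond, and the bright/dark clusters pin
  # the fit, so residual scanner-scale differences do not masquerade as
  # deformation in the refinements
  fit <- stats::lm.fit(cbind(1, pre$static$data[pre$roi]),
                       def1$data[pre$roi])
  s_cal <- image3d(fit$coefficients[1] + fit$coefficients[2] *
                     pre$static$data, pre$static$spacing, pre$static$origin)

  lung <- segment_lungs(def1, pre$roi)
  shell <- pre$roi & !lung
  th_air <- otsu_threshold(def1$data[pre$roi])
  def_fill <- fill_bubbles(def1, shell, threshold = th_air)
  s_fill <- fill_bubbles(s_cal, shell, threshold = th_air)
  # clean the moving image's own air pockets (they sit elsewhere in its
  # breathing phase, so they get their own partition)
  lung_m <- segment_lungs(pre$moving, pre$roi)
  m_fill <- fill_bubbles(pre$moving, pre$roi & !lung_m,
                         threshold = otsu_threshold(
                           pre$moving$data[pre$roi]))

  if (is.null(refine_params)) refine_params <- list()
  w_lung <- attr(renormalize_subroi(def_fill$image, lung), "window")
  w_shell <- attr(renormalize_subroi(def_fill$image, shell), "window")
  ref_lung <- do.call(refine_subroi, c(
    list(static = s_fill$image, moving = m_fill$image, sub_roi = lung,
         init = step1$dvf, window = w_lung), refine_params))
  # the partial-volume ring at the outer body surface carries
  # resolution-dependent intensity, not anatomy: keep refinement forces
  # off it. The bodyshell holds large high-contrast organs, so it gets
  # conventional elastic regularization; the fluid-dominant setting is for
  # small rigid structures in the lungs.
  shell_core <- shell & !dilate_mask(!pre$roi, 2L)
  body_params <- utils::modifyList(
    list(sigma_inc = 1, sigma_field = 1, pyramid = 1, max_iters = 50,
         diff_threshold = 0.08), refine_params)
  ref_body <- do.call(refine_subroi, c(
    list(static = s_fill$image, moving = m_fill$image,
         sub_roi = shell_core,
         init = step1$dvf, window = w_shell), body_params))
  r_lung <- mask_dvf(dvf_sub(ref_lung$dvf, step1$dvf), lung)
  r_body <- mask_dvf(dvf_sub(ref_body$dvf, step1$dvf), shell)
  combined <- dvf_add(step1$dvf,
                      combine_dvfs(r_lung, r_body, lung, shell))

  # final tuning restricted to a band around the lung/bodyshell interface,
  # where the two independent refinements meet
  band <- dilate_mask(lung, 3L) & dilate_mask(shell, 3L) & pre$roi
  pf <- params
  pf$stop_dvid <- 1e-4
  pf$max_iters <- as.integer(finetune_iters)
  pf$psf_sigma <- max(pf$psf_sigma %||% 0, 0.9)
  final <- register_demons(s_fill$image, m_fill$image, band, pf,
                           init = combined, levels = 1)
  # keep only the band's own correction: the finetune's field smoothing
  # must not diffuse the sub-ROI refinements outside the band
  tune <- smooth_dvf(mask_dvf(dvf_sub(final$dvf, combined), band), 1)
  final$dvf <- unfold_dvf(dvf_add(combined, tune), pre$roi)
  final$deformed <- warp_image(m_fill$image, final$dvf)
  reconstructed <- warp_image(pre$moving, final$dvf)
  qa <- qa_report(reconstructed, pre$static, pre$roi, dvf = final$dvf)
  structure(list(step1 = step1, dvf_lung = r_lung,
                 dvf_body = r_body, combined = combined,
                 final = final, dvf = final$dvf,
                 reconstructed = reconstructed,
                 partition = list(lung_mask = lung, bodyshell_mask = shell,
                                  bubble_mask = def_fill$bubble_mask),
                 roi = pre$roi, static = pre$static, moving = pre$moving,
                 qa = qa),
            class = "hybrid_result")
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat(sprintf(
    "<hybrid_result> step1 %s iters, refinements lung/body, final VID %.5g\n",
    paste(x$step1$iterations, collapse = "/"), x$final$final_vid))
  invisible(x)
}

# Estimate the diaphragm's superior displacement encoded in a registration
# field: minus the mean z-displacement over the inferior band of the lungs.
extract_diaphragm_displacement <- function(dvf, lung_mask,
                                           band_fraction = 0.15) {
  zs <- which(apply(lung_mask, 3, any))
  if (!length(zs)) return(NA_real_)
  zmax <- min(zs) + max(1, ceiling(band_fraction * length(zs))) - 1
  band <- lung_mask
  band[, , setdiff(seq_len(dim(lung_mask)[3]), seq(min(zs), zmax))] <- FALSE
  -mean(dvf$uz[band])
}

#' Reconstruct a TR-4DMRI series
#'
#' Runs the two-step pipeline for every cine frame, warm-starting each
#' frame's stage 1 from the previous frame's combined field, and extracts a
#' diaphragm-displacement waveform from the final fields. A frame whose
#' registration fails is recorded and the series continues.
#'
#' @param bh high-resolution breath-hold [image3d].
#' @param cine list of low-resolution frame [image3d]s.
#' @param params a [demons_params].
#' @param warm_start reuse the previous frame's field as initialisation
#'   (default TRUE).
#' @param keep `"reconstruction"` (default) stores reconstructed images and
#'   QA; `"full"` stores entire `hybrid_result` objects.
#' @return list with `frames` (reconstructed [image3d] or NULL on failure),
#'   `qa` (list of `qa_report`), `waveform` (extracted diaphragm
#'   displacement per frame, mm), `errors` (messages per failed frame), and
#'   optionally `results`.
#' @export
reconstruct_series <- function(bh, cine, params = demons_params(),
                               warm_start = TRUE,
                               keep = c("reconstruction", "full")) {
  keep <- match.arg(keep)
  n <- length(cine)
  frames <- vector("list", n)
  qa <- vector("list", n)
  results <- if (keep == "full") vector("list", n) else NULL
  wave <- rep(NA_real_, n)
  errors <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch(
      run_two_step(bh, cine[[i]], params, init = if (warm_start) prev),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[i]] <- conditionMessage(res)
      prev <- NULL
      next
    }
    frames[[i]] <- res$reconstructed
    qa[[i]] <- res$qa
    wave[i] <- extract_diaphragm_displacement(res$dvf,
                                              res$partition$lung_mask)
    if (keep == "full") results[[i]] <- res
    prev <- res$combined
  }
  out <- list(frames = frames, qa = qa, waveform = wave, errors = errors)
  if (keep == "full") out$results <- results
  out
}

#' Cross-consistency check between two breath-hold reconstructions
#'
#' Reconstructs the same free-breathing frame independently from two
#' opposite breath-holds and scores their agreement with [ccc_index()]:
#' `CCC = 2 VIC(recI, recE) / (VIC(recI, FB) + VIC(recE, FB))`, ideally
#' unity.
#'
#' @param bhi,bhe breath-hold [image3d]s (full inhalation / exhalation).
#' @param fb_mid a free-breathing frame (typically mid-respiration).
#' @param params a [demons_params].
#' @return list with `ccc`, the three `vic` values, the two
#'   `hybrid_result`s, and the two `qa` reports.
#' @export
cross_consistency <- function(bhi, bhe, fb_mid, params = demons_params()) {
  rec_i <- run_two_step(bhi, fb_mid, params)
  rec_e <- run_two_step(bhe, fb_mid, params)
  roi <- rec_i$roi | rec_e$roi
  fb <- rec_i$static                      # frame upsampled on the BH grid
  v_ie <- vic(rec_i$reconstructed, rec_e$reconstructed, roi)
  v_if <- vic(rec_i$reconstructed, fb, roi)
  v_ef <- vic(rec_e$reconstructed, fb, roi)
  list(ccc = ccc_index(v_ie, v_if, v_ef),
       vic = c(rec_rec = v_ie, rec_i_fb = v_if, rec_e_fb = v_ef),
       rec_bhi = rec_i, rec_bhe = rec_e,
       qa = list(bhi = rec_i$qa, bhe = rec_e$qa))
}
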