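#' Voxel intensity correlation (VIC)
#'
#' Pearson correlation of the two images' intensity strings over an ROI.
#' Symmetric, and invariant to positive affine rescaling of either argument.
#'
#' @param a,b [image3d] objects on the same grid.
#' @param roi logical array; default whole grid.
#' @return correlation in `[-1, 1]`.
#' @export
vic <- function(a, b, roi = NULL) {
  stopifnot(is_image3d(a), is_image3d(b))
  if (!same_grid(a, b)) stop("images are on different grids")
  if (is.null(roi)) roi <- array(TRUE, dim(a$data))
  va <- a$data[roi]
  vb <- b$data[roi]
  if (length(va) < 2) stop("ROI must contain at least 2 voxels")
  if (sd(va) == 0 || sd(vb) == 0)
    stop("undefined correlation: zero intensity variance in ROI")
  cor(va, vb)
}

#' Cross-consistency check index (CCC)
#'
#' Compares two reconstructions of the same free-breathing frame obtained
#' from opposite breath-holds:
#' `CCC = 2 * VIC(recA, recB) / (VIC(recA, FB) + VIC(recB, FB))`.
#' Unity is ideal; values far from the cohort mean flag reconstructions for
#' review.
#'
#' @param vic_ab VIC between the two reconstructions.
#' @param vic_af,vic_bf VIC of each reconstruction against the acquired
#'   frame.
#' @return CCC value.
#' @export
ccc_index <- function(vic_ab, vic_af, vic_bf) {
  denom <- vic_af + vic_bf
  if (denom == 0) stop("zero denominator in CCC")
  2 * vic_ab / denom
}

#' Flag CCC outliers against a reference batch
#'
#' A value is an outlier when it falls outside `mean(x) +/- sd(x)` of the
#' reference set (by default the batch itself).
#'
#' @param values CCC values to flag.
#' @param reference values defining the acceptable band (default `values`).
#' @return logical vector.
#' @export
flag_ccc_outliers <- function(values, reference = values) {
  m <- mean(reference)
  s <- sd(reference)
  values < m - s | values > m + s
}

#' Structural similarity index (3-D SSIM)
#'
#' Mean local SSIM with a cubic moving window (box statistics) and the
#' standard constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic
#' range `L`.
#'
#' @param a,b [image3d] objects on the same grid.
#' @param window odd window edge length in voxels (default 7).
#' @param dynamic_range intensity range `L` (default 1 for normalized
#'   images).
#' @param roi logical array over which the local map is averaged (default
#'   whole grid).
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim3d <- function(a, b, window = 7, dynamic_range = 1, roi = NULL) {
  stopifnot(is_image3d(a), is_image3d(b))
  if (!same_grid(a, b)) stop("images are on different grids")
  if (any(window > dim(a$data))) stop("window larger than the image grid")
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mu_a <- box_mean(a$data, window)
  mu_b <- box_mean(b$data, window)
  s_aa <- box_mean(a$data * a$data, window) - mu_a^2
  s_bb <- box_mean(b$data * b$data, window) - mu_b^2
  s_ab <- box_mean(a$data * b$data, window) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + c1) * (2 * s_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2))
  if (is.null(roi)) mean(map) else mean(map[roi])
}

#' Dice similarity coefficient of two binary masks
#' @param m1,m2 logical arrays of equal dimension.
#' @return `2|m1 & m2| / (|m1| + |m2|)` in `[0, 1]`.
#' @export
dice_coefficient <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2))) stop("masks differ in dimension")
  n1 <- sum(m1)
  n2 <- sum(m2)
  if (n1 == 0 || n2 == 0) stop("empty mask")
  2 * sum(m1 & m2) / (n1 + n2)
}

mask_com <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask, arr.ind = TRUE)
  origin + (colMeans(idx) - 1) * spacing
}

#' Centre-of-mass distance between two masks (mm)
#' @param m1,m2 logical arrays on the same grid.
#' @param spacing voxel size in mm.
#' @param origin grid origin in mm.
#' @return Euclidean distance in mm.
#' @export
com_delta <- function(m1, m2, spacing, origin = c(0, 0, 0)) {
  if (!identical(dim(m1), dim(m2))) stop("masks differ in dimension")
  if (!any(m1) || !any(m2)) stop("empty mask")
  sqrt(sum((mask_com(m1, spacing, origin) -
              mask_com(m2, spacing, origin))^2))
}

#' Deformed-to-reference volume ratio
#' @param m_dir deformed-structure mask.
#' @param m_ref reference mask.
#' @return `|m_dir| / |m_ref|`.
#' @export
volume_ratio <- function(m_dir, m_ref) {
  if (!any(m_ref)) stop("empty reference mask")
  sum(m_dir) / sum(m_ref)
}

#' Landmark target registration error
#'
#' Per-point Euclidean distance between predicted and true landmark
#' positions; reports the mean and the population standard deviation.
#'
#' @param pred,truth n-by-3 matrices of coordinates (mm), matched by row.
#' @return list with `mean`, `sd`, and per-point `errors` (mm).
#' @export
landmark_tre <- function(pred, truth) {
  pred <- matrix(as.numeric(pred), ncol = 3)
  truth <- matrix(as.numeric(truth), ncol = 3)
  if (nrow(pred) != nrow(truth)) stop("landmark lists differ in length")
  e <- sqrt(rowSums((pred - truth)^2))
  list(mean = mean(e), sd = sqrt(mean((e - mean(e))^2)), errors = e)
}

# Central differences along one array axis, one-sided at the boundaries,
# divided by the grid step h.
diff_axis <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  idx_hi <- pmin(seq_len(n) + 1L, n)
  idx_lo <- pmax(seq_len(n) - 1L, 1L)
  denom <- (idx_hi - idx_lo) * h
  pick <- function(i) {
    switch(axis, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  out <- (pick(idx_hi) - pick(idx_lo))
  sweep_axis <- function(x, v, axis) {
    per <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, per)
    xp <- xp / v
    aperm(xp, order(per))
  }
  sweep_axis(out, denom, axis)
}

#' Jacobian determinant map of a displacement field
#'
#' `det(I + grad(U))` with the displacement gradient computed by central
#' finite differences of the mm-valued components over the mm grid (so the
#' entries are dimensionless). Negative determinants mark locally
#' non-invertible, folding deformations.
#'
#' @param dvf a [dvf3d] with at least 3 voxels per axis.
#' @param roi logical array restricting the summary statistics (default
#'   whole grid).
#' @return list with `map` (determinant array), `min`, and `pct_negative`
#'   (percentage of ROI voxels with negative determinant).
#' @export
jacobian_map <- function(dvf, roi = NULL) {
  stopifnot(is_dvf3d(dvf))
  if (any(dim(dvf$ux) < 3)) stop("grid must have at least 3 voxels per axis")
  s <- dvf$spacing
  a11 <- diff_axis(dvf$ux, 1, s[1]) + 1
  a12 <- diff_axis(dvf$ux, 2, s[2])
  a13 <- diff_axis(dvf$ux, 3, s[3])
  a21 <- diff_axis(dvf$uy, 1, s[1])
  a22 <- diff_axis(dvf$uy, 2, s[2]) + 1
  a23 <- diff_axis(dvf$uy, 3, s[3])
  a31 <- diff_axis(dvf$uz, 1, s[1])
  a32 <- diff_axis(dvf$uz, 2, s[2])
  a33 <- diff_axis(dvf$uz, 3, s[3]) + 1
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  if (is.null(roi)) roi <- array(TRUE, dim(det))
  list(map = det, min = min(det[roi]),
       pct_negative = 100 * mean(det[roi] < 0))
}

#' Curl map of a displacement field
#'
#' Central-difference curl `(dw/dy - dv/dz, du/dz - dw/dx, dv/dx - du/dy)`
#' of the field `(u, v, w)`; large magnitudes flag unrealistic local
#' rotational motion.
#'
#' @param dvf a [dvf3d] with at least 3 voxels per axis.
#' @return list with `cx`, `cy`, `cz` component arrays, `magnitude`, and
#'   `max` magnitude.
#' @export
curl_map <- function(dvf) {
  stopifnot(is_dvf3d(dvf))
  if (any(dim(dvf$ux) < 3)) stop("grid must have at least 3 voxels per axis")
  s <- dvf$spacing
  cx <- diff_axis(dvf$uz, 2, s[2]) - diff_axis(dvf$uy, 3, s[3])
  cy <- diff_axis(dvf$ux, 3, s[3]) - diff_axis(dvf$uz, 1, s[1])
  cz <- diff_axis(dvf$uy, 1, s[1]) - diff_axis(dvf$ux, 2, s[2])
  mag <- sqrt(cx^2 + cy^2 + cz^2)
  list(cx = cx, cy = cy, cz = cz, magnitude = mag, max = max(mag))
}

#' Assemble a per-registration QA report
#'
#' Bundles the image-similarity, tumor-fidelity and field-quality metrics
#' for one reconstructed frame.
#'
#' @param deformed reconstructed (deformed moving) [image3d].
#' @param reference reference [image3d] (ground truth or acquired frame).
#' @param roi logical array for the intensity metrics.
#' @param dvf final [dvf3d] (optional; enables Jacobian/curl entries).
#' @param mask_dir,mask_ref deformed and reference structure masks
#'   (optional; enable Dice/COM/volume entries).
#' @param landmarks_pred,landmarks_true matched landmark matrices (optional;
#'   enable TRE entries).
#' @return object of class `qa_report` (a named list; `NA` where inputs were
#'   not supplied).
#' @export
qa_report <- function(deformed, reference, roi = NULL, dvf = NULL,
                      mask_dir = NULL, mask_ref = NULL,
                      landmarks_pred = NULL, landmarks_true = NULL) {
  rep <- list(
    vic = vic(deformed, reference, roi),
    vid = compute_vid(deformed, reference, roi),
    ssim = ssim3d(deformed, reference, roi = roi),
    dice = NA_real_, delta_com = NA_real_, volume_ratio = NA_real_,
    tre_mean = NA_real_, tre_sd = NA_real_,
    jac_min = NA_real_, jac_neg_pct = NA_real_, curl_max = NA_real_)
  if (!is.null(mask_dir) && !is.null(mask_ref)) {
    rep$dice <- dice_coefficient(mask_dir, mask_ref)
    rep$delta_com <- com_delta(mask_dir, mask_ref, reference$spacing,
                               reference$origin)
    rep$volume_ratio <- volume_ratio(mask_dir, mask_ref)
  }
  if (!is.null(landmarks_pred) && !is.null(landmarks_true)) {
    tre <- landmark_tre(landmarks_pred, landmarks_true)
    rep$tre_mean <- tre$mean
    rep$tre_sd <- tre$sd
  }
  if (!is.null(dvf)) {
    jac <- jacobian_map(dvf, roi)
    rep$jac_min <- jac$min
    rep$jac_neg_pct <- jac$pct_negative
    rep$curl_max <- curl_map(dvf)$max
  }
  class(rep) <- "qa_report"
  rep
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %s\n", nm,
                ifelse(is.na(x[[nm]]), "-", format(x[[nm]], digits = 4))))
  invisible(x)
}

#' @export
as.data.frame.qa_report <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
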