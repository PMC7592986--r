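#' Parametric digital thorax phantom
#'
#' Specification of the synthetic T1w-like thorax used as ground truth: an
#' elliptical body, two lung ellipsoids truncated from below by a diaphragm
#' dome, a spherical tumor in the right lung, vessel-tree landmarks inside
#' the lungs, and air bubbles in the abdomen. Respiratory motion is a smooth
#' superior-inferior displacement: full amplitude at and below the diaphragm,
#' decaying linearly to zero at the lung apex. The tumor translates rigidly
#' at `tumor_motion_ratio` times the diaphragm displacement; its centre is
#' placed exactly at the height where the decaying motion field equals that
#' ratio, so the tumor and its surroundings move consistently.
#'
#' All anatomy is expressed as fractions of the grid's physical extent, so a
#' smaller grid yields a proportionally smaller thorax with the same
#' topology.
#'
#' @param grid_shape voxels per axis (default `c(96, 96, 120)`).
#' @param spacing mm per voxel (default 2 mm isotropic).
#' @param tumor_diameter tumor diameter in mm (default 30).
#' @param tumor_motion_ratio tumor-to-diaphragm motion amplitude ratio
#'   (default 2/3).
#' @param n_landmarks number of vessel-bifurcation landmarks (default 12).
#' @param bubble_count number of abdominal air bubbles (default 3).
#' @param texture_amplitude amplitude of the smooth intra-band texture as a
#'   fraction of the normalized intensity range (default 0.05).
#' @param seed integer controlling all stochastic phantom content (textures,
#'   landmark placement, organ blobs).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 120),
                         spacing = c(2, 2, 2),
                         tumor_diameter = 30,
                         tumor_motion_ratio = 2 / 3,
                         n_landmarks = 12,
                         bubble_count = 3,
                         texture_amplitude = 0.05,
                         seed = 1) {
  grid_shape <- as.integer(rep(grid_shape, length.out = 3))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(grid_shape < 8L)) stop("grid too small for the phantom anatomy")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (tumor_motion_ratio <= 0 || tumor_motion_ratio > 1)
    stop("`tumor_motion_ratio` must be in (0, 1]")
  if (tumor_diameter <= 0) stop("`tumor_diameter` must be positive")
  if (n_landmarks < 1) stop("need at least one landmark")
  spec <- list(grid_shape = grid_shape, spacing = spacing,
               tumor_diameter = tumor_diameter,
               tumor_motion_ratio = tumor_motion_ratio,
               n_landmarks = as.integer(n_landmarks),
               bubble_count = as.integer(bubble_count),
               texture_amplitude = texture_amplitude,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Derived anatomy in physical mm. Anatomy scales with the grid extent.
phantom_geometry <- function(spec) {
  ext <- spec$grid_shape * spec$spacing
  ctr <- (spec$grid_shape - 1) * spec$spacing / 2
  z_base <- 0.23 * ext[3]            # diaphragm level at full inhale
  dome_h <- 0.075 * ext[3]           # height of the diaphragm dome
  z_mb <- z_base + dome_h            # below this, motion weight is 1
  z_apex <- 0.83 * ext[3]            # motion weight reaches 0 here
  lung_ctr_z <- 0.55 * ext[3]
  g <- list(
    ext = ext, ctr = ctr,
    body_semi = c(0.42, 0.37, 0.47) * ext,
    lung_semi = c(0.17, 0.24, 0.30) * ext,
    lung_ctr_right = c(ctr[1] + 0.21 * ext[1], ctr[2], lung_ctr_z),
    lung_ctr_left = c(ctr[1] - 0.21 * ext[1], ctr[2], lung_ctr_z),
    z_base = z_base, dome_h = dome_h, z_mb = z_mb, z_apex = z_apex,
    h2 = z_apex - z_mb, dome_r = 0.45 * ext[1],
    tumor_r = spec$tumor_diameter / 2)
  g$tumor_ctr0 <- c(g$lung_ctr_right[1], ctr[2],
                    z_apex - spec$tumor_motion_ratio * g$h2)
  g
}

# Motion weight at material height Z: 1 below the dome, linear decay to 0 at
# the apex, 0 above.
motion_weight <- function(z, geom) {
  pmin(pmax((geom$z_apex - z) / geom$h2, 0), 1)
}

# Forward map (material -> current) and its analytic inverse, SI axis only.
forward_z <- function(z_mat, d, geom) z_mat + d * motion_weight(z_mat, geom)

inverse_z <- function(z_cur, d, geom) {
  if (d == 0) return(z_cur)
  out <- z_cur
  low <- z_cur <= geom$z_mb + d
  mid <- !low & z_cur < geom$z_apex
  out[low] <- z_cur[low] - d
  out[mid] <- (z_cur[mid] - d * geom$z_apex / geom$h2) / (1 - d / geom$h2)
  out
}

# Smooth pseudo-random scalar field: a sum of K random cosine waves with
# wavelengths in [lmin, lmax] mm, unit variance, evaluable at any point.
make_cosfield <- function(seed, K = 20, lmin = 15, lmax = 40) {
  pars <- with_seed(seed, {
    dir <- matrix(rnorm(3 * K), K, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    lambda <- runif(K, lmin, lmax)
    list(kvec = dir * (2 * pi / lambda), phase = runif(K, 0, 2 * pi))
  })
  amp <- 1 / sqrt(K / 2)
  function(x, y, z) {
    out <- 0
    for (i in seq_len(K)) {
      out <- out + cos(pars$kvec[i, 1] * x + pars$kvec[i, 2] * y +
                         pars$kvec[i, 3] * z + pars$phase[i])
    }
    pmin(pmax(out * amp, -2.5), 2.5)
  }
}

# Deterministic phantom content drawn once per spec: textures, landmark
# material positions, vessel-tree segments, organ blobs, bubble centres.
phantom_content <- function(spec) {
  g <- phantom_geometry(spec)
  tex_body <- make_cosfield(spec$seed + 101L, K = 18, lmin = 20, lmax = 55)
  tex_lung <- make_cosfield(spec$seed + 202L, K = 18, lmin = 12, lmax = 35)
  content <- with_seed(spec$seed + 303L, {
    # landmarks: material positions inside the lung ellipsoids, clear of the
    # tumor and of the moving diaphragm region
    pts <- matrix(0, 0, 3)
    sides <- rep_len(c(1, -1), spec$n_landmarks)
    tries <- 0
    while (nrow(pts) < spec$n_landmarks && tries < 5000) {
      tries <- tries + 1
      side <- sides[nrow(pts) + 1]
      lc <- if (side > 0) g$lung_ctr_right else g$lung_ctr_left
      u <- runif(3, -0.75, 0.75)
      p <- lc + u * g$lung_semi
      if (p[3] < g$z_mb + 0.12 * g$h2 || p[3] > g$z_apex - 0.1 * g$h2) next
      if (sum(((p - lc) / g$lung_semi)^2) > 0.72^2) next
      if (sqrt(sum((p - g$tumor_ctr0)^2)) < g$tumor_r + 10) next
      pts <- rbind(pts, p)
    }
    # vessel tree per lung: greedy MST rooted at a hilum point; landmarks are
    # the tree nodes (bifurcation analogs)
    segs <- list()
    for (side in c(1, -1)) {
      lc <- if (side > 0) g$lung_ctr_right else g$lung_ctr_left
      hilum <- lc + c(-side * 0.5 * g$lung_semi[1], 0, -0.1 * g$lung_semi[3])
      idx <- which((pts[, 1] - g$ctr[1]) * side > 0)
      if (!length(idx)) next
      nodes <- rbind(hilum, pts[idx, , drop = FALSE])
      connected <- 1L
      remaining <- setdiff(seq_len(nrow(nodes)), connected)
      while (length(remaining)) {
        dmat <- as.matrix(stats::dist(nodes))[connected, remaining,
                                              drop = FALSE]
        hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        a <- connected[hit[1]]
        b <- remaining[hit[2]]
        segs[[length(segs) + 1]] <- rbind(nodes[a, ], nodes[b, ])
        connected <- c(connected, b)
        remaining <- setdiff(remaining, b)
      }
    }
    # abdominal organ blobs: T1w abdomen shows strong organ-scale contrast
    # (liver/stomach/bowel), which is also what anchors deep registration
    nb <- 9
    organs <- list(
      ctr = cbind(runif(nb, g$ctr[1] - 0.55 * g$body_semi[1],
                        g$ctr[1] + 0.55 * g$body_semi[1]),
                  runif(nb, g$ctr[2] - 0.45 * g$body_semi[2],
                        g$ctr[2] + 0.45 * g$body_semi[2]),
                  runif(nb, 0.04 * g$ext[3], g$z_base)),
      sigma = runif(nb, 0.05, 0.12) * g$ext[3],
      amp = runif(nb, 0.08, 0.16) * rep_len(c(1, -1), nb))
    # air bubbles: material centres in the abdomen, below the dome at every
    # admissible displacement, mutually disjoint and clear of the body
    # surface (interior air pockets, not open to the background)
    k <- spec$bubble_count
    bub <- NULL
    if (k > 0) {
      ctr <- matrix(0, 0, 3)
      rr <- numeric(0)
      btries <- 0
      while (nrow(ctr) < k && btries < 5000) {
        btries <- btries + 1
        r <- runif(1, 0.022, 0.032) * g$ext[3]
        gap <- 0.015 * g$ext[3]
        p <- c(runif(1, g$ctr[1] - 0.4 * g$body_semi[1],
                     g$ctr[1] + 0.4 * g$body_semi[1]),
               runif(1, g$ctr[2] - 0.3 * g$body_semi[2],
                     g$ctr[2] + 0.3 * g$body_semi[2]),
               runif(1, 0.55 * g$z_base, 0.9 * g$z_base))
        # sphere (plus margin) must stay well inside the body ellipsoid
        ecc <- sqrt(sum(((p - g$ctr) / g$body_semi)^2))
        if (ecc + (r + gap) / min(g$body_semi) > 0.93) next
        if (nrow(ctr) &&
              any(sqrt(rowSums(sweep(ctr, 2, p)^2)) < rr + r + gap)) next
        ctr <- rbind(ctr, p)
        rr <- c(rr, r)
      }
      if (nrow(ctr) < k)
        stop("could not place the requested number of air bubbles")
      bub <- list(ctr = ctr, r = rr)
    }
    list(landmarks = pts, segments = segs, organs = organs, bubbles = bub)
  })
  if (nrow(content$landmarks) < spec$n_landmarks)
    stop("could not place the requested number of landmarks in the lungs")
  c(content, list(geom = g, tex_body = tex_body, tex_lung = tex_lung))
}

# Distance from points to a 3-D segment, vectorised over points.
seg_distance <- function(x, y, z, p1, p2) {
  v <- p2 - p1
  L2 <- sum(v^2)
  t <- ((x - p1[1]) * v[1] + (y - p1[2]) * v[2] + (z - p1[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (p1[1] + t * v[1]))^2 +
         (y - (p1[2] + t * v[2]))^2 +
         (z - (p1[3] + t * v[3]))^2)
}

#' Generate one phantom frame at a given diaphragm displacement
#'
#' Renders the phantom at diaphragm displacement `d` mm (0 = full
#' inhalation; positive displacement moves the diaphragm and abdominal
#' content superiorly, compressing the lungs). Lungs render in a low
#' intensity band (about 0.05-0.25) with smooth texture and bright tubular
#' vessels, the bodyshell in a high band (about 0.45-0.95), air bubbles near
#' zero; the tumor sits in the right lung at an intermediate intensity. All
#' masks, the tumor centre and the landmark coordinates move consistently
#' with the image content.
#'
#' @param spec a [phantom_spec].
#' @param displacement diaphragm displacement in mm, `>= 0`.
#' @return An object of class `phantom_frame`: list with `image` (normalized
#'   [image3d]), logical masks `body_mask`, `lung_mask`, `tumor_mask`,
#'   `bubble_mask`, an n-by-3 `landmarks` matrix (mm, current positions),
#'   `tumor_com` (mm), and `diaphragm_displacement` (mm).
#' @export
generate_frame <- function(spec, displacement) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- as.numeric(displacement)
  if (d < 0) stop("displacement must be >= 0")
  ct <- phantom_content(spec)
  g <- ct$geom
  if (d >= 0.9 * g$h2)
    stop("displacement too large for the phantom lung height")
  n <- spec$grid_shape
  grid <- voxel_coords(image3d(array(0, n), spec$spacing, c(0, 0, 0)))
  X <- grid$x; Y <- grid$y; Zc <- grid$z
  Zm <- array(inverse_z(as.numeric(Zc), d, g), n)

  ebody <- ((X - g$ctr[1]) / g$body_semi[1])^2 +
    ((Y - g$ctr[2]) / g$body_semi[2])^2 +
    ((Zc - g$ctr[3]) / g$body_semi[3])^2
  body <- ebody <= 1
  # lungs are clipped against a shrunken body surface so the bodyshell keeps
  # a non-trivial thickness everywhere (the cavity must not open to the
  # background even after 5 mm partial-volume averaging)
  inner_body <- ebody <= 0.9^2
  r2 <- (X - g$ctr[1])^2 + (Y - g$ctr[2])^2
  z_dome <- g$z_base + d + g$dome_h * pmax(0, 1 - r2 / g$dome_r^2)
  in_lung_ell <-
    (((X - g$lung_ctr_right[1]) / g$lung_semi[1])^2 +
       ((Y - g$lung_ctr_right[2]) / g$lung_semi[2])^2 +
       ((Zc - g$lung_ctr_right[3]) / g$lung_semi[3])^2 <= 1) |
    (((X - g$lung_ctr_left[1]) / g$lung_semi[1])^2 +
       ((Y - g$lung_ctr_left[2]) / g$lung_semi[2])^2 +
       ((Zc - g$lung_ctr_left[3]) / g$lung_semi[3])^2 <= 1)
  lung <- inner_body & in_lung_ell & (Zc > z_dome)
  tctr <- g$tumor_ctr0 + c(0, 0, spec$tumor_motion_ratio * d)
  tumor <- (X - tctr[1])^2 + (Y - tctr[2])^2 + (Zc - tctr[3])^2 <=
    g$tumor_r^2
  if (any(tumor & !lung))
    stop("tumor leaves the lung at this displacement (inadmissible)")
  shell <- body & !lung
  bubble <- array(FALSE, n)
  if (!is.null(ct$bubbles)) {
    for (i in seq_len(nrow(ct$bubbles$ctr))) {
      bc <- ct$bubbles$ctr[i, ] + c(0, 0, d)
      bubble <- bubble |
        ((X - bc[1])^2 + (Y - bc[2])^2 + (Zc - bc[3])^2 <= ct$bubbles$r[i]^2)
    }
    bubble <- bubble & shell
  }

  amp <- spec$texture_amplitude
  img <- array(0, n)
  ish <- which(shell)
  img[ish] <- 0.70 +
    (amp * 1.8 / 2.5) * ct$tex_body(X[ish], Y[ish], Zm[ish])
  for (i in seq_along(ct$organs$sigma)) {
    oc <- ct$organs$ctr[i, ]
    img[ish] <- img[ish] + ct$organs$amp[i] *
      exp(-((X[ish] - oc[1])^2 + (Y[ish] - oc[2])^2 + (Zm[ish] - oc[3])^2) /
            (2 * ct$organs$sigma[i]^2))
  }
  img[ish] <- pmin(pmax(img[ish], 0.46), 0.95)  # keep the bodyshell band
  il <- which(lung)
  lung_val <- 0.14 + (amp / 2.5) * ct$tex_lung(X[il], Y[il], Zm[il])
  # vessels and bifurcation landmarks, drawn in material coordinates
  vx <- X[il]; vy <- Y[il]; vz <- Zm[il]
  vessel <- numeric(length(il))
  for (s in ct$segments) {
    dist <- seg_distance(vx, vy, vz, s[1, ], s[2, ])
    vessel <- pmax(vessel, 0.17 * exp(-dist^2 / (2 * 1.6^2)))
  }
  for (i in seq_len(nrow(ct$landmarks))) {
    p <- ct$landmarks[i, ]
    dist2 <- (vx - p[1])^2 + (vy - p[2])^2 + (vz - p[3])^2
    vessel <- vessel + 0.10 * exp(-dist2 / (2 * 2.5^2))
  }
  img[il] <- lung_val + pmin(vessel, 0.2)
  it <- which(tumor)
  img[it] <- 0.30 + 0.4 * (amp / 2.5) * ct$tex_lung(X[it], Y[it], Zm[it])
  img[bubble] <- 0.02
  img <- pmin(pmax(img, 0), 1)

  lm_cur <- ct$landmarks
  lm_cur[, 3] <- forward_z(ct$landmarks[, 3], d, g)
  structure(list(
    image = image3d(img, spec$spacing, c(0, 0, 0)),
    body_mask = body, lung_mask = lung, tumor_mask = tumor,
    bubble_mask = bubble, landmarks = lm_cur,
    tumor_com = tctr, diaphragm_displacement = d),
    class = "phantom_frame")
}

#' Ground-truth displacement field between two phantom phases
#'
#' Returns the field that, applied with the backward-warp convention of
#' [warp_image()], maps the frame at `d_from` onto the frame at `d_to`:
#' `U_z(x) = forward(inverse(z; d_to); d_from) - z`, zero in x and y. Inside
#' the rigidly translating tumor the surrounding smooth field is a close
#' (but not exact) description of the motion.
#'
#' @param spec a [phantom_spec].
#' @param d_from,d_to diaphragm displacements (mm) of the moving and target
#'   phases.
#' @return a [dvf3d] on the phantom grid.
#' @export
phantom_true_dvf <- function(spec, d_from, d_to) {
  g <- phantom_geometry(spec)
  n <- spec$grid_shape
  z <- voxel_coords(image3d(array(0, n), spec$spacing, c(0, 0, 0)))$z
  zm <- inverse_z(as.numeric(z), d_to, g)
  uz <- array(forward_z(zm, d_from, g) - as.numeric(z), n)
  zero <- array(0, n)
  dvf3d(zero, zero, uz, spec$spacing, c(0, 0, 0))
}

#' Quasi-periodic breathing waveform with variable inhalation depth
#'
#' Emulates free breathing that is stable at full exhalation but variable at
#' full inhalation: the end-exhale level is constant while each cycle's
#' inhalation depth (and, proportionally, its period) varies. Displacement
#' is the diaphragm's superior displacement in mm (0 = deepest admissible
#' inhale).
#'
#' @param duration seconds (default 40).
#' @param frame_rate samples per second (default 2 Hz).
#' @param base_amplitude mean inhalation depth in mm (default 30).
#' @param inhale_variability coefficient of variation of the per-cycle
#'   inhalation depth (default 0.2); `0` gives a strictly periodic waveform.
#' @param mean_period mean breathing period in seconds (default 4).
#' @param seed integer seed.
#' @return object of class `breathing_waveform`: list with `time`,
#'   `displacement`, `frame_rate`, `duration`.
#' @export
irregular_waveform <- function(duration = 40, frame_rate = 2,
                               base_amplitude = 30, inhale_variability = 0.2,
                               mean_period = 4, seed = 1) {
  if (duration <= 0 || frame_rate <= 0) stop("duration and rate must be > 0")
  n <- round(duration * frame_rate)
  exhale_level <- base_amplitude * (1 + 2.5 * inhale_variability)
  ncyc <- ceiling(duration / mean_period) + 3
  cyc <- with_seed(seed, {
    eps_a <- pmin(pmax(rnorm(ncyc), -2.5), 2.5)
    eps_t <- pmin(pmax(rnorm(ncyc), -2.5), 2.5)
    list(depth = base_amplitude * (1 + inhale_variability * eps_a),
         period = mean_period * (1 + 0.15 * inhale_variability * eps_t))
  })
  starts <- cumsum(c(0, cyc$period))
  t <- (seq_len(n) - 1) / frame_rate
  idx <- findInterval(t, starts)
  phase <- (t - starts[idx]) / cyc$period[idx]
  disp <- exhale_level - cyc$depth[idx] * sin(pi * phase)^3
  structure(list(time = t, displacement = pmax(disp, 0),
                 frame_rate = frame_rate, duration = duration,
                 cycle_depths = cyc$depth[seq_len(max(idx))]),
            class = "breathing_waveform")
}

#' Simulate a low-resolution free-breathing 3D-cine series
#'
#' One frame per waveform sample: the phantom is rendered at the sampled
#' diaphragm displacement, down-sampled by overlap-weighted block averaging
#' to the cine voxel size, and degraded with additive Rayleigh noise.
#'
#' @param spec a [phantom_spec].
#' @param waveform a `breathing_waveform` (see [irregular_waveform()]).
#' @param noise_level Rayleigh scale as a fraction of the normalized range
#'   (default 0.02).
#' @param noise_seed integer; each frame uses an independent child seed.
#' @param lowres_spacing cine voxel size in mm (default 5 mm isotropic).
#' @param truth `"summary"` keeps per-frame landmarks/tumor COM/displacement;
#'   `"full"` keeps whole `phantom_frame` objects (memory heavy); `"none"`.
#' @return list with `frames` (list of low-resolution [image3d]), `truth`,
#'   and the input `waveform`.
#' @export
generate_cine <- function(spec, waveform, noise_level = 0.02,
                          noise_seed = 1, lowres_spacing = c(5, 5, 5),
                          truth = c("summary", "full", "none")) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(waveform, "breathing_waveform"))
  truth <- match.arg(truth)
  frames <- vector("list", length(waveform$time))
  truths <- if (truth == "none") NULL else vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- generate_frame(spec, waveform$displacement[i])
    low <- resample(fr$image, lowres_spacing, method = "block_mean")
    frames[[i]] <- add_noise(low, level = noise_level,
                             seed = noise_seed + 7919L * i)
    if (truth == "full") {
      truths[[i]] <- fr
    } else if (truth == "summary") {
      truths[[i]] <- list(landmarks = fr$landmarks,
                          tumor_com = fr$tumor_com,
                          diaphragm_displacement = fr$diaphragm_displacement)
    }
  }
  list(frames = frames, truth = truths, waveform = waveform)
}
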