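# Shared fixtures: small grids keep the suite fast; anatomy scales with the
# grid extent, so the phantom topology is the same as at full size.

# Tiny phantom for structural/IO tests (80 x 80 x 112 mm).
tiny_spec <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(40, 40, 56), spacing = c(2, 2, 2),
               tumor_diameter = 12, n_landmarks = 8, seed = seed, ...)
}

# Mid-size phantom for registration tests (128 x 128 x 160 mm); supports
# diaphragm displacements up to ~35 mm.
mid_spec <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(64, 64, 80), spacing = c(2, 2, 2),
               tumor_diameter = 16, n_landmarks = 10, seed = seed, ...)
}

# Simulate the low-resolution degraded counterpart of a phantom frame.
degrade_frame <- function(frame, level = 0.02, seed = 99) {
  add_noise(resample(frame$image, c(5, 5, 5), method = "block_mean"),
            level = level, seed = seed)
}

# Warp a logical mask with a registration field (0.5 threshold).
warp_mask <- function(mask, dvf, spacing, origin = c(0, 0, 0)) {
  img <- image3d(array(as.numeric(mask), dim(mask)), spacing, origin)
  warp_image(img, dvf)$data >= 0.5
}

# Linear-ramp image used for exact warp checks.
ramp_image <- function(n = c(16, 16, 16), spacing = c(2, 2, 2),
                       slope = c(0.01, 0, 0)) {
  g <- expand.grid(x = seq_len(n[1]) - 1, y = seq_len(n[2]) - 1,
                   z = seq_len(n[3]) - 1)
  v <- slope[1] * g$x * spacing[1] + slope[2] * g$y * spacing[2] +
    slope[3] * g$z * spacing[3]
  image3d(array(v, n), spacing)
}

uniform_dvf <- function(like, u = c(0, 0, 0)) {
  d <- dim(like$data)
  dvf3d(array(u[1], d), array(u[2], d), array(u[3], d),
        like$spacing, like$origin)
}
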