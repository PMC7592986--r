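test_that("frame generation is deterministic and validates inputs", {
  spec <- tiny_spec(seed = 4)
  f1 <- generate_frame(spec, 10)
  f2 <- generate_frame(spec, 10)
  expect_identical(f1$image$data, f2$image$data)
  expect_identical(f1$landmarks, f2$landmarks)
  expect_error(generate_frame(spec, -5), ">= 0")
  expect_error(generate_frame(spec, 1e4), "displacement too large")
})

test_that("masks nest correctly across the motion ladder", {
  spec <- mid_spec(seed = 2)
  for (d in seq(0, 30, by = 5)) {
    f <- generate_frame(spec, d)
    expect_true(all(f$body_mask[f$lung_mask]), info = paste("d =", d))
    expect_true(all(f$lung_mask[f$tumor_mask]), info = paste("d =", d))
    expect_false(any(f$bubble_mask & f$lung_mask), info = paste("d =", d))
    expect_true(all(f$body_mask[f$bubble_mask]), info = paste("d =", d))
    # landmarks inside the body
    vox <- round(sweep(f$landmarks, 2, spec$spacing, "/")) + 1
    expect_true(all(f$body_mask[vox]), info = paste("d =", d))
  }
})

test_that("tumor COM displacement is the configured fraction of the
           diaphragm displacement", {
  spec <- mid_spec(seed = 3)
  f0 <- generate_frame(spec, 0)
  com0 <- tr4dmri:::mask_com(f0$tumor_mask, spec$spacing)
  for (d in c(10, 20, 30)) {
    fd <- generate_frame(spec, d)
    comd <- tr4dmri:::mask_com(fd$tumor_mask, spec$spacing)
    shift <- sqrt(sum((comd - com0)^2))
    expect_lt(abs(shift - spec$tumor_motion_ratio * d),
              0.5 * max(spec$spacing))
    # analytic centre agrees with the voxelized mask centroid
    expect_lt(sqrt(sum((fd$tumor_com - comd)^2)), 0.5 * max(spec$spacing))
  }
})

test_that("lung and bodyshell intensities occupy disjoint bands", {
  f <- generate_frame(mid_spec(seed = 5), 15)
  lungv <- f$image$data[f$lung_mask]
  shellv <- f$image$data[f$body_mask & !f$lung_mask & !f$bubble_mask]
  cut <- (max(lungv) + min(shellv)) / 2
  overlap <- mean(lungv > cut) + mean(shellv < cut)
  expect_lt(overlap, 0.01)
  # bubbles are near zero, below everything else
  if (any(f$bubble_mask))
    expect_lt(max(f$image$data[f$bubble_mask]), min(shellv))
})

test_that("landmarks are bright local structures that move with the
           ground-truth motion field", {
  spec <- mid_spec(seed = 6)
  f0 <- generate_frame(spec, 0)
  f25 <- generate_frame(spec, 25)
  # contrast: landmark voxel intensity well above the local lung texture
  vox <- round(sweep(f0$landmarks, 2, spec$spacing, "/")) + 1
  lm_int <- f0$image$data[vox]
  lung_bg <- f0$image$data[f0$lung_mask]
  texture_sd <- stats::sd(lung_bg)
  expect_true(all((lm_int - stats::median(lung_bg)) / texture_sd > 2))
  # self-consistency: landmark motion equals the generator's motion field
  g <- tr4dmri:::phantom_geometry(spec)
  expected_z <- tr4dmri:::forward_z(f0$landmarks[, 3], 25, g)
  expect_equal(f25$landmarks[, 3], expected_z, tolerance = 1e-9)
  expect_equal(f25$landmarks[, 1:2], f0$landmarks[, 1:2])
  # and matches the stored ground-truth field at the landmark positions
  dvf <- phantom_true_dvf(spec, 0, 25)
  pred <- transfer_landmarks(f0$landmarks, dvf)
  expect_lt(landmark_tre(pred, f25$landmarks)$mean, 0.75)
})

test_that("irregular waveforms have stable exhales and variable inhales", {
  # 40 s at 2 Hz -> 80 samples
  w <- irregular_waveform(40, 2, 30, 0.2, seed = 8)
  expect_length(w$displacement, 80)
  expect_true(all(w$displacement >= 0))

  # zero variability: strictly periodic, peak-to-peak identical cycles
  w0 <- irregular_waveform(40, 10, 30, 0, seed = 8)
  expect_lt(stats::sd(w0$cycle_depths), 1e-9)

  # variability 0.2 over many cycles: depth CoV in a 3-sigma band of 0.2
  w2 <- irregular_waveform(200, 2, 30, 0.2, mean_period = 4, seed = 9)
  cv <- stats::sd(w2$cycle_depths) / mean(w2$cycle_depths)
  expect_gt(cv, 0.1)
  expect_lt(cv, 0.3)
  expect_error(irregular_waveform(-1, 2), "> 0")
})

test_that("cine simulation produces one degraded frame per sample", {
  spec <- tiny_spec(seed = 10)
  w <- irregular_waveform(1, 2, 10, 0, seed = 1)
  cine <- generate_cine(spec, w, noise_level = 0, noise_seed = 5)
  expect_length(cine$frames, 2)
  # noise level 0: frames equal the resampled rendered frames exactly
  fr <- generate_frame(spec, w$displacement[1])
  expect_equal(cine$frames[[1]]$data,
               resample(fr$image, c(5, 5, 5), "block_mean")$data,
               tolerance = 1e-12)
  expect_equal(cine$frames[[1]]$spacing, c(5, 5, 5))
  # determinism with noise on
  c1 <- generate_cine(spec, w, noise_level = 0.02, noise_seed = 5)
  c2 <- generate_cine(spec, w, noise_level = 0.02, noise_seed = 5)
  expect_identical(c1$frames[[2]]$data, c2$frames[[2]]$data)
  # per-frame ground truth is carried along
  expect_equal(c1$truth[[1]]$diaphragm_displacement, w$displacement[1])
})
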