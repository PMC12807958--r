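test_that("phantom generation is deterministic and respects its invariants", {
  p1 <- make_phantom(c(64, 64, 64), 4, seed = 1)
  p2 <- make_phantom(c(64, 64, 64), 4, seed = 1)
  expect_identical(p1$label_volume, p2$label_volume)
  expect_identical(p1$intensity_volume, p2$intensity_volume)

  # single label per voxel is structural (one array); ground-truth bookkeeping:
  for (i in seq_len(nrow(p1$structures))) {
    st <- p1$structures[i, ]
    expect_equal(sum(p1$label_volume == st$structure_id), st$vol_vox)
    expect_equal(st$vol_mm3, st$vol_vox * prod(p1$voxel_mm))
  }
  # intensity ordering WM > subcortical > GM > CSF > background
  ti <- p1$intensities
  expect_true(ti[["wm"]] > ti[["subcortical"]])
  expect_true(ti[["subcortical"]] > ti[["gm"]])
  expect_true(ti[["gm"]] > ti[["csf"]])
  expect_true(ti[["csf"]] > ti[["background"]])
  # ribbon thickness ground truth positive
  expect_true(all(p1$ribbon_spec$thickness_mm > 0))
})

test_that("phantom with no structures has no structure labels", {
  p <- make_phantom(c(64, 64, 64), 0, seed = 1)
  expect_true(all(p$label_volume < 4))
  expect_equal(nrow(p$structures), 0)
})

test_that("voxelized ellipsoid volume matches the analytic value", {
  sel <- csmprage:::ellipsoid_voxels(c(48, 48, 48), c(24.5, 24.5, 24.5),
                                     c(6, 5, 4))
  analytic <- 4 / 3 * pi * 6 * 5 * 4
  expect_lt(abs(length(sel) - analytic) / analytic, 0.10)
})

test_that("phantom construction rejects degenerate geometry", {
  expect_error(make_phantom(c(16, 16, 16), 0, seed = 1), "shape")
})

test_that("coil sets are normalized, smooth and deterministic", {
  co <- small_coils()
  rss <- coil_rss(co)
  expect_true(all(abs(rss - 1) < 1e-12))        # RSS-normalized everywhere
  ph <- small_phantom()
  expect_true(all(rss[ph$brain_mask] >= 0.5 & rss[ph$brain_mask] <= 2.0))
  # smoothness: bounded first differences of each magnitude map
  for (s in co$sens) {
    m <- Mod(s)
    expect_lt(max(abs(diff(m[, 24, 24]))), 0.1)
  }
  co2 <- make_coils(c(48, 48, 48), 4, seed = 2, width = 0.35)
  expect_identical(co$sens, co2$sens)
  expect_error(make_coils(c(48, 48, 48), 0), "n_coils")
})

test_that("flat single-coil override is identically one", {
  co <- make_coils(c(32, 32, 32), 1, flat = TRUE)
  expect_true(all(co$sens[[1]] == 1 + 0i))
  expect_equal(max(abs(coil_rss(co) - 1)), 0)
})

test_that("bias field is positive, smooth and mean-one in the brain", {
  ph <- small_phantom()
  b <- small_bias()
  expect_true(all(b > 0))
  expect_equal(mean(b[ph$brain_mask]), 1, tolerance = 1e-12)
  expect_true(max(b) <= 1.35 && min(b) >= 0.65)  # ~ +-20% after renorm
})

test_that("k-space simulation satisfies the DFT round-trip and Parseval", {
  ph <- small_phantom()
  co1 <- make_coils(c(48, 48, 48), 1, flat = TRUE)
  ks <- simulate_kspace(ph, co1, NULL, small_params(noise = FALSE))
  rec <- Re(fft(ks$data[[1]], inverse = TRUE)) / length(ks$data[[1]])
  expect_lt(max(abs(rec - ph$intensity_volume)) / max(ph$intensity_volume),
            1e-10)
  # Parseval under unnormalized-forward convention
  expect_equal(sum(Mod(ks$data[[1]])^2),
               length(ks$data[[1]]) * sum(ph$intensity_volume^2),
               tolerance = 1e-10)
})

test_that("k-space noise realizations are seed-deterministic", {
  ph <- small_phantom(); co <- small_coils()
  k1 <- simulate_kspace(ph, co, NULL, small_params(seed = 9))
  k2 <- simulate_kspace(ph, co, NULL, small_params(seed = 9))
  k3 <- simulate_kspace(ph, co, NULL, small_params(seed = 10))
  expect_identical(k1$data, k2$data)
  expect_false(identical(k1$data[[1]], k3$data[[1]]))
})

test_that("masked simulation zeroes unsampled phase-encode columns", {
  ph <- small_phantom(); co <- small_coils()
  mk <- phyllotaxis_mask(48, 48, R = 4, turbo = 48, seed = 7)
  ks <- simulate_kspace(ph, co, NULL, small_params(), mask = mk)
  shifted <- csmprage:::ifftshift2(mk$mask)
  unsampled <- which(!shifted, arr.ind = TRUE)
  pick <- unsampled[seq(1, nrow(unsampled), length.out = 25), , drop = FALSE]
  for (i in seq_len(nrow(pick)))
    expect_true(all(ks$data[[1]][, pick[i, 1], pick[i, 2]] == 0))
})

test_that("noise level calibration hits the target white-matter SNR", {
  ph <- small_phantom(); co <- small_coils()
  ks <- simulate_kspace(ph, co, NULL, small_params(seed = 21))
  zf <- zero_filled_recon(ks, co)
  wm <- ph$label_volume == 3
  snr <- mean(zf$volume[wm]) / sd(zf$volume[wm])
  expect_gt(snr, 15); expect_lt(snr, 22)  # target 18, Rician bias tolerated
})
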