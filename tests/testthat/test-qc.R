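test_that("tissue SNR matches the sample mean/sd definition", {
  set.seed(31)
  img <- array(50, dim = c(22, 22, 22))
  mask <- array(TRUE, dim = dim(img))
  img <- img + rnorm(length(img), 0, 5)
  s <- tissue_snr(img, mask)
  expect_equal(s, mean(img[mask]) / sd(img[mask]))   # definition
  expect_lt(abs(s - 10), 0.3)                        # analytic mu/sigma
  # sentinels and guards
  expect_identical(tissue_snr(array(7, c(4, 4, 4)), array(TRUE, c(4, 4, 4))), Inf)
  one <- array(FALSE, c(4, 4, 4)); one[1] <- TRUE
  expect_error(tissue_snr(array(1, c(4, 4, 4)), one), "2 voxels")
})

test_that("three-delta histograms are segmented exactly and deterministically", {
  set.seed(7)
  img <- array(sample(c(0.15, 0.65, 1.0), 8^3, replace = TRUE), dim = c(8, 8, 8))
  seg <- segment_tissues_basic(img, array(TRUE, dim = dim(img)))
  expect_identical(seg$csf, img == 0.15)
  expect_identical(seg$gm, img == 0.65)
  expect_identical(seg$wm, img == 1.0)
  seg2 <- segment_tissues_basic(img, array(TRUE, dim = dim(img)))
  expect_identical(seg[1:3], seg2[1:3])
  expect_error(segment_tissues_basic(array(1, c(8, 8, 8))), "distinct")
})

test_that("noise-free phantom segmentation recovers white matter", {
  ph <- small_phantom()
  seg <- segment_tissues_basic(ph$intensity_volume, ph$brain_mask)
  expect_gt(csmprage:::dice(seg$wm, ph$label_volume == 3), 0.95)
})

test_that("FWHM estimator recovers applied Gaussian kernels", {
  # rho(1) = exp(-1/(4 sigma^2)) for a Gaussian ACF; the estimator inverts it
  set.seed(12)
  mask <- array(TRUE, dim = c(64, 64, 64))
  est <- replicate(4, {
    noise <- array(rnorm(64^3), dim = c(64, 64, 64))
    sm <- gaussian_smooth3(noise, sigma = 4 / 2.3548)
    smoothness_fwhm(sm, mask)$fwhm_vox[["combined"]]
  })
  expect_lt(abs(mean(est) - 4), 0.6)

  # monotonicity: twice the smoothing, larger estimate
  noise <- array(rnorm(48^3), dim = c(48, 48, 48))
  m48 <- array(TRUE, dim = c(48, 48, 48))
  f1 <- smoothness_fwhm(gaussian_smooth3(noise, 1.2), m48)$fwhm_vox[["combined"]]
  f2 <- smoothness_fwhm(gaussian_smooth3(noise, 2.4), m48)$fwhm_vox[["combined"]]
  expect_gt(f2, f1)
})

test_that("white noise is flagged rougher-than-or-near the voxel scale", {
  # for i.i.d. noise the lag-1 autocorrelation fluctuates around zero, so the
  # estimator returns either the sentinel or a sub-voxel estimate
  set.seed(13)
  mask <- array(TRUE, dim = c(48, 48, 48))
  vals <- replicate(5, {
    noise <- array(rnorm(48^3), dim = c(48, 48, 48))
    suppressWarnings(
      smoothness_fwhm(noise, mask)$fwhm_vox[["combined"]]
    )
  })
  expect_true(all(is.na(vals) | vals < 1))
})

test_that("FWHM estimator guards its preconditions", {
  small <- array(FALSE, c(10, 10, 10)); small[1:50] <- TRUE
  expect_error(smoothness_fwhm(array(rnorm(1000), c(10, 10, 10)), small), "100")
  flat <- array(1, c(10, 10, 10))
  expect_error(smoothness_fwhm(flat, array(TRUE, c(10, 10, 10))), "variance")
})

test_that("SSIM satisfies identity, symmetry, bounds and contrast behaviour", {
  ph <- small_phantom()
  x <- ph$intensity_volume
  expect_equal(ssim3d(x, x)$mean_ssim, 1, tolerance = 1e-12)
  set.seed(5)
  y <- x + array(rnorm(length(x), 0, 0.05), dim = dim(x))
  s_xy <- ssim3d(x, y)$mean_ssim
  s_yx <- ssim3d(y, x)$mean_ssim
  expect_lt(abs(s_xy - s_yx), 1e-12)
  expect_true(s_xy >= -1 && s_xy <= 1)
  # inverted contrast image is structurally dissimilar
  inv <- max(x) - x
  expect_lt(ssim3d(x, inv)$mean_ssim, 0.5)
  expect_error(ssim3d(x, x[1:10, , ]), "shape")
})

test_that("SSIM decreases monotonically with added noise", {
  ph <- small_phantom()
  x <- ph$intensity_volume
  set.seed(17)
  s_prev <- 1
  for (sd_n in c(0.02, 0.06, 0.18)) {
    y <- x + array(rnorm(length(x), 0, sd_n), dim = dim(x))
    s <- ssim3d(x, y)$mean_ssim
    expect_lt(s, s_prev)
    s_prev <- s
  }
})

test_that("absolute difference maps behave as a metric ingredient", {
  ph <- small_phantom()
  a <- ph$intensity_volume
  expect_true(all(abs_difference(a, a) == 0))
  set.seed(3)
  b <- a + array(rnorm(length(a), 0, 0.02), dim = dim(a))
  expect_identical(abs_difference(a, b), abs_difference(b, a))
  expect_error(abs_difference(a, b[1:10, , ]), "shape")
})

test_that("differences grow with the regularization gap on shared k-space", {
  ph <- small_phantom(); co <- small_coils()
  mk <- phyllotaxis_mask(48, 48, R = 8, turbo = 48, seed = 7)
  ks <- simulate_kspace(ph, co, NULL, small_params(seed = 5), mask = mk)
  recs <- retro_reconstruct(ks, mk, co, c(1e-4, 3e-4, 12e-4), max_iter = 30)
  d_small <- mean(abs_difference(recs[[1]], recs[[2]])[ph$brain_mask])
  d_large <- mean(abs_difference(recs[[1]], recs[[3]])[ph$brain_mask])
  expect_gte(d_small, 0)
  expect_gt(d_large, d_small)
})
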