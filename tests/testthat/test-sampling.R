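shot_min_radius_centered <- function(mask) {
  for (s in mask$shots) {
    r <- sqrt((s[, 1] - mask$dc[1])^2 + (s[, 2] - mask$dc[2])^2)
    k <- length(r); i <- which.min(r)
    if (!(i > floor(k / 3) && i <= k - floor(k / 3))) return(FALSE)
  }
  TRUE
}

test_that("phyllotaxis masks meet the acceleration, center and shot contracts", {
  for (R in c(2, 4, 8)) {
    mk <- phyllotaxis_mask(96, 96, R = R, turbo = 96, seed = 7)
    expect_lt(abs(mk$R_achieved - R), 0.05 * R)
    # sampled points lie in the footprint; no duplicates by construction
    expect_true(all(mk$footprint[mk$mask]))
    # calibration disc fully sampled
    disc <- csmprage:::calib_disc(96, 96, mk$calib_radius)
    expect_true(all(mk$mask[disc]))
    # union of shots equals the sampled set
    pts <- do.call(rbind, mk$shots)
    expect_equal(nrow(pts), sum(mk$mask))
    expect_true(all(mk$mask[pts]))
    # temporal centering of the k-space center within each shot
    expect_true(shot_min_radius_centered(mk))
  }
})

test_that("masks are jitter-deterministic and differ across seeds", {
  m1 <- phyllotaxis_mask(64, 64, R = 4, turbo = 64, seed = 7)
  m2 <- phyllotaxis_mask(64, 64, R = 4, turbo = 64, seed = 7)
  m3 <- phyllotaxis_mask(64, 64, R = 4, turbo = 64, seed = 8)
  expect_identical(m1$mask, m2$mask)
  expect_gte(sum(m1$mask != m3$mask), 1)
})

test_that("unaccelerated spiral with footprint-wide calibration is full", {
  mk <- phyllotaxis_mask(48, 48, R = 1, turbo = 48, jitter = 0,
                         calib_radius = 34, seed = 1)
  expect_identical(mk$mask, mk$footprint)
  expect_equal(mk$R_achieved, 1)
})

test_that("infeasible or invalid accelerations are rejected", {
  expect_error(phyllotaxis_mask(48, 48, R = 0.5, turbo = 48), "R")
  expect_error(phyllotaxis_mask(48, 48, R = 1e6, turbo = 48), "infeasible")
})

test_that("full masks count their support correctly", {
  m <- full_mask(8, 8, elliptical = FALSE)
  expect_equal(sum(m$mask), 64)
  expect_equal(m$R_achieved, 1)
  me <- full_mask(240, 192, elliptical = TRUE)
  expect_lt(abs(sum(me$mask) - pi / 4 * 240 * 192) / (pi / 4 * 240 * 192), 0.01)
})

test_that("PSF metrics separate coherent from incoherent sampling", {
  pfull <- mask_psf_metrics(full_mask(64, 64))
  expect_lt(pfull$peak_sidelobe_ratio, 1e-12)
  p2 <- mask_psf_metrics(uniform_mask(64, 64, 2))
  expect_equal(p2$peak_sidelobe_ratio, 1, tolerance = 1e-10)
  pphy <- mask_psf_metrics(phyllotaxis_mask(64, 64, R = 4, turbo = 64, seed = 3))
  puni <- mask_psf_metrics(uniform_mask(64, 64, 4))
  expect_lt(pphy$peak_sidelobe_ratio, puni$peak_sidelobe_ratio)
  expect_error(mask_psf_metrics(matrix(FALSE, 4, 4)), "empty")
})

test_that("scan-time estimates follow shots x TR", {
  pars <- acq_params(matrix = c(16, 240, 192), TR_ms = 2300, turbo_factor = 192)
  mk <- full_mask(240, 192, elliptical = FALSE, turbo = 192)
  expect_equal(length(mk$shots), 240)
  expect_equal(estimate_scan_time(mk, pars), 552)   # printed protocol: 9:14
  mk6 <- phyllotaxis_mask(240, 192, R = 6, turbo = 192, seed = 1)
  t6 <- estimate_scan_time(mk6, pars)
  expect_equal(t6, length(mk6$shots) * 2.3)
  expect_lt(abs(t6 - 74), 10)                       # printed CSx6: 1:14
  m8 <- full_mask(8, 8, turbo = 64)
  expect_equal(length(m8$shots), 1)
  expect_equal(estimate_scan_time(m8, pars), 2.3)
})

test_that("mask export writes PNG, CSV and JSON sidecar", {
  mk <- phyllotaxis_mask(48, 48, R = 4, turbo = 48, seed = 7)
  stem <- file.path(tempdir(), "mask_test")
  paths <- write_mask(mk, stem)
  expect_true(all(file.exists(paths)))
  pts <- read.csv(paths[2])
  expect_equal(nrow(pts), sum(mk$mask))
  meta <- jsonlite::read_json(paths[3])
  expect_equal(meta$R_requested, 4)
  unlink(paths)
})
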