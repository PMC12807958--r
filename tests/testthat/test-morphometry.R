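test_that("noise-free pipeline recovers structure volumes within 5%", {
  ph <- make_phantom(c(64, 64, 64), 4, seed = 1)
  tb <- estimate_volumes(ph$intensity_volume, ph)
  expect_equal(nrow(tb), nrow(ph$structures))
  expect_true(all(is.finite(tb$estimate)))
  expect_true(all(abs(tb$estimate - tb$truth) / tb$truth <= 0.05))
})

test_that("overdriven regularization erases structures to the sentinel", {
  ph <- small_phantom(); co <- small_coils()
  mk <- phyllotaxis_mask(48, 48, R = 4, turbo = 48, seed = 7)
  ks <- simulate_kspace(ph, co, NULL, small_params(seed = 5), mask = mk)
  cr <- cs_recon(ks, mk, co, lambda = 0.5)   # console scale, far overdriven
  tb <- estimate_volumes(cr$volume, ph)
  expect_true(any(is.na(tb$estimate)))
})

test_that("morphometry is a pure function of the image", {
  ph <- small_phantom()
  t1 <- estimate_volumes(ph$intensity_volume, ph)
  t2 <- estimate_volumes(ph$intensity_volume, ph)
  expect_identical(t1, t2)
  th1 <- estimate_thickness(ph$intensity_volume, ph)
  th2 <- estimate_thickness(ph$intensity_volume, ph)
  expect_identical(th1, th2)
})

test_that("noise-free ribbon thickness is recovered within half a millimetre", {
  ph <- make_phantom(c(64, 64, 64), 0, seed = 2, thickness_mm = 4)
  tb <- estimate_thickness(ph$intensity_volume, ph)
  expect_equal(nrow(tb), 8)
  expect_true(all(is.finite(tb$estimate)))
  expect_true(all(abs(tb$estimate - 4) <= 0.5))
})

test_that("a thicker ribbon yields strictly larger estimates everywhere", {
  p4 <- make_phantom(c(64, 64, 64), 0, seed = 2, thickness_mm = 4)
  p6 <- make_phantom(c(64, 64, 64), 0, seed = 2, thickness_mm = 6)
  t4 <- estimate_thickness(p4$intensity_volume, p4)
  t6 <- estimate_thickness(p6$intensity_volume, p6)
  expect_true(all(t6$estimate > t4$estimate))
})

test_that("repeatability implements the percent-agreement formula", {
  t1 <- data.frame(id = c("a", "b"), kind = "volume", estimate = c(100, 50))
  t2 <- data.frame(id = c("a", "b"), kind = "volume", estimate = c(100, 50))
  r <- repeatability(t1, t2)
  expect_equal(r$repeatability_pct, c(100, 100))
  t3 <- data.frame(id = c("a", "b"), kind = "volume", estimate = c(90, 50))
  r2 <- repeatability(t1, t3)
  expect_equal(r2$repeatability_pct[1], 100 * (1 - 10 / 95), tolerance = 1e-12)
  # symmetry and scale invariance
  r3 <- repeatability(t3, t1)
  expect_equal(r2$repeatability_pct, r3$repeatability_pct)
  t1s <- t1; t3s <- t3
  t1s$estimate <- t1s$estimate * 7; t3s$estimate <- t3s$estimate * 7
  expect_equal(repeatability(t1s, t3s)$repeatability_pct, r2$repeatability_pct)
  expect_error(repeatability(t1, data.frame(id = "z", kind = "volume",
                                            estimate = 1)), "mismatched")
})

test_that("between-sequence R2 follows the squared Pearson correlation", {
  mk_tab <- function(e) data.frame(id = letters[seq_along(e)], kind = "volume",
                                   estimate = e)
  expect_equal(between_sequence_r2(mk_tab(c(1, 2, 3, 4)),
                                   mk_tab(c(1, 2, 3, 4)))$r2, 1)
  expect_equal(between_sequence_r2(mk_tab(c(1, 2, 3, 4)),
                                   mk_tab(2 * c(1, 2, 3, 4) + 5))$r2, 1)
  # hand-computed: r^2 = cov^2/(var_a var_b) = 4.7^2 / (5 * 4.5)
  r <- between_sequence_r2(mk_tab(c(1, 2, 3, 4)),
                           mk_tab(c(1.1, 1.9, 3.2, 3.8)))$r2
  expect_equal(r, 22.09 / 22.5, tolerance = 1e-10)
  # zero-variance sentinel
  expect_true(is.na(between_sequence_r2(mk_tab(c(1, 1, 1, 1)),
                                        mk_tab(c(1, 2, 3, 4)))$r2))
})

test_that("FreeSurfer-style stats tables can be ingested", {
  p <- file.path(tempdir(), "aseg_synthetic.stats")
  writeLines(c(
    "# Title Segmentation Statistics (synthetic example)",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    "  1  10  7408  7408.0  Left-Thalamus",
    "  2  11  3742  3742.0  Left-Caudate"
  ), p)
  tb <- read_aseg_stats(p)
  expect_equal(tb$id, c("Left-Thalamus", "Left-Caudate"))
  expect_equal(tb$estimate, c(7408, 3742))
  # two-column fallback
  writeLines(c("thalamus 7408", "caudate 3742"), p)
  tb2 <- read_aseg_stats(p)
  expect_equal(tb2$estimate, c(7408, 3742))
  unlink(p)
})
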