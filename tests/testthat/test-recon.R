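test_that("unregularized reconstruction of fully sampled data is exact", {
  ph <- small_phantom(); co <- small_coils()
  ks <- simulate_kspace(ph, co, small_bias(), small_params(seed = 5))
  zf <- zero_filled_recon(ks, co)
  cr <- cs_recon(ks, NULL, co, lambda = 0)
  expect_lt(max(abs(cr$volume - zf$volume)) / max(zf$volume), 1e-6)
  expect_true(all(cr$volume >= 0))
})

test_that("zero-filled error grows under under-sampling", {
  ph <- small_phantom(); co <- small_coils(); bias <- small_bias()
  pars <- small_params(seed = 5)
  ks_full <- simulate_kspace(ph, co, bias, pars)
  mk <- phyllotaxis_mask(48, 48, R = 4, turbo = 48, seed = 7)
  ks_r4 <- simulate_kspace(ph, co, bias, pars, mask = mk)
  truth <- ph$intensity_volume
  e_full <- csmprage:::rmse(zero_filled_recon(ks_full, co)$volume / bias,
                            truth, ph$brain_mask)
  e_r4 <- csmprage:::rmse(zero_filled_recon(ks_r4, co)$volume / bias,
                          truth, ph$brain_mask)
  expect_gt(e_r4, e_full)
})

test_that("well-regularized CS reconstruction beats zero-filling at R = 4", {
  # 64^3, R = 4; the l1 weight is set near the RMSE-optimal point of the
  # regularization curve (the console default sits lower: it trades RMSE for
  # resolution, see the methods vignette)
  ph <- make_phantom(c(64, 64, 64), 4, seed = 1)
  co <- make_coils(c(64, 64, 64), 4, seed = 2, width = 0.35)
  pars <- acq_params(matrix = c(64, 64, 64),
                     noise_sd = noise_sd_for_snr(ph, 18), seed = 5)
  mk <- phyllotaxis_mask(64, 64, R = 4, turbo = 64, seed = 11)
  ks <- simulate_kspace(ph, co, NULL, pars, mask = mk)
  e_zf <- csmprage:::rmse(zero_filled_recon(ks, co)$volume,
                          ph$intensity_volume, ph$brain_mask)
  cr <- cs_recon(ks, mk, co, lambda = 0.015, lambda_scale = "absolute")
  e_cs <- csmprage:::rmse(cr$volume, ph$intensity_volume, ph$brain_mask)
  expect_lt(e_cs, e_zf)
})

test_that("the objective trace is monotone non-increasing", {
  ph <- small_phantom(); co <- small_coils()
  mk <- phyllotaxis_mask(48, 48, R = 4, turbo = 48, seed = 7)
  ks <- simulate_kspace(ph, co, NULL, small_params(seed = 5), mask = mk)
  cr <- cs_recon(ks, mk, co, lambda = 3e-4)
  expect_true(all(diff(cr$trace) <= 1e-9 * cr$trace[1]))
  expect_lt(cr$trace[length(cr$trace)], cr$trace[1])
})

test_that("FISTA matches a long-run ISTA oracle on toy problems", {
  # a 500-iteration plain proximal-gradient run upper-bounds the optimum
  # (its sublinear tail keeps it slightly above); FISTA must reach at least
  # that objective. The acceptance suite adds the two-sided check in the
  # strong-threshold regime where the oracle converges.
  for (seed in c(1, 2)) {
    ph <- make_phantom(c(32, 32, 32), 0, seed = seed)
    co <- make_coils(c(32, 32, 32), 1, flat = TRUE)
    pars <- acq_params(matrix = c(32, 32, 32), noise_sd = 50, seed = seed)
    mk <- phyllotaxis_mask(32, 32, R = 2, turbo = 32, seed = seed)
    ks <- simulate_kspace(ph, co, NULL, pars, mask = mk)
    lam <- 0.01
    cr <- cs_recon(ks, mk, co, lambda = lam, max_iter = 2000, tol = 0,
                   lambda_scale = "absolute")
    f_fista <- cr$trace[length(cr$trace)]
    probs <- slice_problems(ks, mk, co, lam)
    f_ista <- sum(vapply(probs, function(p)
      objective(ista_solve(p, 500), p), 0))
    expect_lte(f_fista, f_ista + 1e-8)
  }
})

test_that("reconstruction cost function evaluates its definition", {
  y0 <- list(matrix(complex(real = 0), 16, 16))
  S <- list(matrix(complex(real = 1), 16, 16))
  m <- matrix(TRUE, 16, 16)
  p0 <- recon_problem(y0, m, S, lambda = 0.7)
  expect_equal(objective(matrix(complex(real = 0), 16, 16), p0), 0)
  # x = 0, ||y||^2 = 2 -> data term 1
  yv <- matrix(complex(real = 0), 16, 16); yv[1, 1] <- sqrt(2)
  p1 <- recon_problem(list(yv), m, S, lambda = 5)
  expect_equal(objective(matrix(complex(real = 0), 16, 16), p1), 1)
})

test_that("retro-reconstruction is deterministic across duplicate settings", {
  ph <- small_phantom(); co <- small_coils()
  mk <- phyllotaxis_mask(48, 48, R = 6, turbo = 48, seed = 7)
  ks <- simulate_kspace(ph, co, NULL, small_params(seed = 5), mask = mk)
  recs <- retro_reconstruct(ks, mk, co, c(3e-4, 3e-4), max_iter = 10)
  expect_identical(recs[[1]]$volume, recs[[2]]$volume)
  expect_equal(recs[[1]]$provenance, recs[[2]]$provenance)
  expect_error(retro_reconstruct(ks, mk, co, numeric(0)), "non-empty")
})

test_that("extreme regularization drives everything into the coarse band", {
  ph <- small_phantom(); co <- small_coils()
  mk <- phyllotaxis_mask(48, 48, R = 4, turbo = 48, seed = 7)
  ks <- simulate_kspace(ph, co, NULL, small_params(seed = 5), mask = mk)
  cr <- cs_recon(ks, mk, co, lambda = 1e3, lambda_scale = "absolute",
                 max_iter = 20)
  W <- dwt_matrix(48)
  cb <- csmprage:::coarse_band_mask(W)
  out_energy <- 0; tot <- 0
  for (s in seq_len(48)) {
    w <- W %*% cr$volume[s, , ] %*% t(W)
    out_energy <- out_energy + sum(Mod(w[!cb])^2)
    tot <- tot + sum(Mod(w)^2)
  }
  expect_lt(out_energy / max(tot, 1e-30), 1e-6)
})

test_that("coil compression keeps energy and degrades gracefully", {
  ph <- small_phantom(); co <- small_coils()
  ks <- simulate_kspace(ph, co, NULL, small_params(seed = 5))
  cc <- compress_coils(ks$data, co$sens, 4)   # keep all: exact
  expect_equal(cc$energy_kept, 1)
  cc2 <- compress_coils(ks$data, co$sens, 2)
  expect_gt(cc2$energy_kept, 0.5)
  expect_equal(length(cc2$data), 2)
})

test_that("calibration-based sensitivity estimates are usable", {
  ph <- small_phantom(); co <- small_coils()
  mk <- phyllotaxis_mask(48, 48, R = 2, turbo = 48, seed = 7)
  ks <- simulate_kspace(ph, co, NULL, small_params(seed = 5), mask = mk)
  est <- estimate_coils(ks)
  expect_s3_class(est, "coil_set")
  expect_true(est$params$estimated)
  rss <- coil_rss(est)
  expect_true(all(abs(rss[ph$brain_mask] - 1) < 1e-6))
  zf_est <- zero_filled_recon(ks, est)
  zf_true <- zero_filled_recon(ks, co)
  # approximate: correlated with the true-map reconstruction inside the brain
  expect_gt(cor(zf_est$volume[ph$brain_mask], zf_true$volume[ph$brain_mask]),
            0.95)
})
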