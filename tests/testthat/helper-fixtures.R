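# Shared fixtures, built once per test run. Sizes are kept small; the
# full-scale study conditions are exercised in test-acceptance.R.

fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (!exists(name, envir = cache)) assign(name, build(), envir = cache)
    get(name, envir = cache)
  }
})

small_phantom <- function() fix("ph48", function()
  make_phantom(c(48, 48, 48), n_structures = 4, seed = 1))

small_coils <- function() fix("co48", function()
  make_coils(c(48, 48, 48), 4, seed = 2, width = 0.35))

small_bias <- function() fix("bias48", function()
  make_bias_field(c(48, 48, 48), amplitude = 0.2, seed = 3,
                  brain_mask = small_phantom()$brain_mask))

small_params <- function(noise = TRUE, seed = 5) {
  sd <- if (noise) noise_sd_for_snr(small_phantom(), 18) else 0
  acq_params(matrix = c(48, 48, 48), noise_sd = sd, seed = seed)
}

# Per-slice reconstruction problems exactly as cs_recon poses them: readout
# decoupling, unitary 2D scaling, unit-max normalization, corner-DC mask.
slice_problems <- function(kspace, mask, coils, lambda, wavelet = "db4",
                           levels = 4) {
  shape <- kspace$params$matrix
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  sc <- max(zero_filled_recon(kspace, coils)$volume)
  mm <- csmprage:::ifftshift2(mask$mask)
  hybrid <- lapply(kspace$data, function(k) {
    km <- matrix(k, nrow = nx)
    hy <- mvfft(km, inverse = TRUE) / nx
    dim(hy) <- c(nx, ny, nz)
    hy / (sqrt(ny * nz) * sc)
  })
  lapply(seq_len(nx), function(s) {
    y <- lapply(hybrid, function(h) h[s, , ])
    S <- lapply(coils$sens, function(ss) ss[s, , ])
    recon_problem(y, mm, S, lambda, wavelet, levels)
  })
}

# Plain proximal-gradient (ISTA) solver, written independently of the
# package's FISTA path, for oracle comparisons on small problems.
ista_solve <- function(problem, iters, L = 1) {
  p <- problem
  ny <- nrow(p$y[[1]]); nz <- ncol(p$y[[1]])
  Ms <- ifelse(p$mask, 1, 0)
  f2 <- function(x) fft(x) / sqrt(length(x))
  if2 <- function(k) fft(k, inverse = TRUE) / sqrt(length(k))
  x <- matrix(complex(real = 0), ny, nz)
  for (c in seq_along(p$y)) x <- x + Conj(p$S[[c]]) * if2(p$y[[c]])
  for (k in seq_len(iters)) {
    grad <- matrix(complex(real = 0), ny, nz)
    for (c in seq_along(p$y))
      grad <- grad + Conj(p$S[[c]]) * if2(Ms * f2(p$S[[c]] * x) - p$y[[c]])
    v <- x - grad / L
    w <- soft_threshold(p$Wy %*% v %*% t(p$Wz), p$lambda / L)
    x <- t(p$Wy) %*% w %*% p$Wz
  }
  x
}
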