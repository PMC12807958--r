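# 3D inverse DFT with the package convention (unnormalized forward, 1/N inverse)
ifft3 <- function(k) fft(k, inverse = TRUE) / length(k)

#' Direct (zero-filled) reconstruction
#'
#' Inverse 3D DFT per coil followed by sensitivity-weighted coil combination
#' `sum(conj(S_c) * x_c) / sum(|S_c|^2)` (root-sum-of-squares when
#' sensitivities are not supplied). For fully sampled noise-free data this is
#' the exact reconstruction; for under-sampled data it is the unregularized
#' aliased baseline. Returns magnitude.
#'
#' @param kspace a `kspace_data`.
#' @param coils a `coil_set`, or NULL for RSS combination.
#' @return an object of class `recon_volume`.
#' @export
zero_filled_recon <- function(kspace, coils = NULL) {
  imgs <- lapply(kspace$data, ifft3)
  if (is.null(coils)) {
    mag <- sqrt(Reduce(`+`, lapply(imgs, function(x) Mod(x)^2)))
  } else {
    denom <- Reduce(`+`, lapply(coils$sens, function(s) Mod(s)^2))
    if (any(denom == 0))
      stop("all-zero coil sensitivities at some voxel; cannot combine", call. = FALSE)
    num <- Reduce(`+`, Map(function(s, x) Conj(s) * x, coils$sens, imgs))
    mag <- Mod(num / denom)
  }
  new_recon_volume(mag, lambda = 0, iterations = 0L, trace = numeric(0),
                   kspace = kspace, method = "zero_filled")
}

new_recon_volume <- function(mag, lambda, iterations, trace, kspace, method,
                             extra = list()) {
  structure(c(list(
    volume = mag, lambda = lambda, iterations = iterations, trace = trace,
    method = method,
    provenance = list(
      noise_seed = kspace$noise_seed,
      mask_seed = if (!is.null(kspace$mask)) kspace$mask$seed else NA_integer_,
      R_requested = if (!is.null(kspace$mask)) kspace$mask$R_requested else 1,
      R_achieved = if (!is.null(kspace$mask)) kspace$mask$R_achieved else 1
    )
  ), extra), class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("<recon_volume> %s, %s, lambda=%g, %d iterations\n",
              paste(dim(x$volume), collapse = "x"), x$method, x$lambda,
              max(x$iterations)))
  invisible(x)
}

#' Wavelet-regularized compressed-sensing reconstruction
#'
#' Minimizes, independently for every readout slice after a 1D inverse DFT
#' along the readout axis,
#' `f(x) = 1/2 sum_c || M o F(S_c x) - y_c ||_2^2 + lambda ||Psi x||_1`
#' with F the unitary 2D DFT, M the phase-encode sampling mask, S_c the
#' complex coil sensitivities and Psi an orthogonal 2D wavelet transform.
#' The solver is FISTA with a fixed step `1/L` (L from power iteration on the
#' normal operator) and a complex soft-thresholding prox with threshold
#' `lambda/L`; each slice stops at `max_iter` or when the relative objective
#' change drops below `tol`. Data are intensity-normalized to unit maximum
#' (of the zero-filled reconstruction) before solving so `lambda` is on the
#' dimensionless scale of scanner-console regularization settings.
#'
#' @param kspace a `kspace_data` (already masked if under-sampled).
#' @param mask a `sampling_mask`; defaults to the mask carried by `kspace`
#'   (a fully sampled rectangle when absent).
#' @param coils a `coil_set` matching the simulation.
#' @param lambda regularization factor (>= 0).
#' @param max_iter maximum FISTA iterations per slice (default 50).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param wavelet wavelet family for the sparsity transform (default "db4").
#' @param levels wavelet decomposition depth (default 4).
#' @param lambda_scale `"console"` (default) interprets `lambda` on the
#'   dimensionless scanner-console scale: a fixed console value maps to the
#'   effective l1 weight `lambda * 25 * f^2` (f = sampled fraction) on the
#'   unit-max, unitary-DFT cost, so the same console setting regularizes
#'   relatively less at higher acceleration (see the methods vignette for
#'   the calibration). `"absolute"` uses `lambda` directly as the l1 weight.
#' @param n_virtual_coils optional SVD coil compression: the coil dimension is
#'   rotated into its principal components (an exact unitary recombination)
#'   and only the strongest `n_virtual_coils` channels are reconstructed.
#'   NULL (default) keeps all physical coils.
#' @return a `recon_volume` with magnitude `volume`, the objective-per-
#'   iteration `trace` (summed over slices, on normalized data), per-slice
#'   iteration counts, the step bound `L`, the effective l1 weight
#'   `lambda_eff`, and provenance.
#' @export
cs_recon <- function(kspace, mask = NULL, coils, lambda, max_iter = 50,
                     tol = 1e-6, wavelet = "db4", levels = 4,
                     lambda_scale = c("console", "absolute"),
                     n_virtual_coils = NULL) {
  if (lambda < 0) stop_arg("lambda must be >= 0")
  if (max_iter < 1) stop_arg("max_iter must be >= 1")
  lambda_scale <- match.arg(lambda_scale)
  mask <- mask %||% kspace$mask
  shape <- kspace$params$matrix
  mmat <- if (is.null(mask)) matrix(TRUE, shape[2], shape[3]) else mask$mask
  if (!all(dim(mmat) == shape[2:3]))
    stop("mask does not match k-space phase-encode grid", call. = FALSE)

  # scale estimate from the zero-filled reconstruction (center of k-space is
  # densely sampled, so the maximum magnitude is well preserved)
  zf <- zero_filled_recon(kspace, coils)
  sc <- max(zf$volume)
  if (sc <= 0) stop("k-space contains no signal", call. = FALSE)

  kdata <- kspace$data
  sens <- coils$sens
  if (!is.null(n_virtual_coils) && n_virtual_coils < length(kdata)) {
    cmp <- compress_coils(kdata, sens, n_virtual_coils)
    kdata <- cmp$data; sens <- cmp$sens
  }

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  s2d <- sqrt(ny * nz)
  # hybrid space: 1D inverse DFT along readout, then unitary 2D scaling
  # (1/sqrt(ny*nz)) and unit-max normalization (1/sc); layout (ny, nz, nx) so
  # every C++ cube slice is one 2D reconstruction problem
  y_list <- lapply(kdata, function(k) {
    km <- matrix(k, nrow = nx)
    hy <- mvfft(km, inverse = TRUE) / nx
    dim(hy) <- c(nx, ny, nz)
    aperm(hy, c(2, 3, 1)) / (s2d * sc)
  })
  s_list <- lapply(sens, function(s) aperm(s, c(2, 3, 1)))

  filt <- wavelet_filter(wavelet)
  ly <- dwt_max_levels(ny, levels)
  lz <- dwt_max_levels(nz, levels)
  lambda_eff <- lambda
  if (lambda_scale == "console" && lambda > 0) {
    # console-scale mapping: a fixed console Reg value acts relatively more
    # weakly the fewer samples are acquired (lambda_eff = lambda * 25 * f^2,
    # f = sampled fraction); constants calibrated once, see methods vignette
    frac <- if (!is.null(mask) && !is.null(mask$footprint))
      sum(mask$mask) / sum(mask$footprint) else mean(mmat)
    lambda_eff <- lambda * 25 * min(frac, 1)^2
  }
  res <- cs_fista_cpp(y_list, s_list, ifelse(ifftshift2(mmat), 1, 0),
                      lambda_eff, as.integer(max_iter), tol, filt, ly, lz)
  vol <- aperm(Mod(res$x), c(3, 1, 2)) * sc
  new_recon_volume(vol, lambda = lambda, iterations = res$iters,
                   trace = as.numeric(res$trace), kspace = kspace,
                   method = "cs_fista",
                   extra = list(L = res$L, tol = tol, max_iter = max_iter,
                                wavelet = wavelet, levels = levels,
                                scale = sc, lambda_eff = lambda_eff,
                                lambda_scale = lambda_scale))
}

#' Estimate coil sensitivities from the calibration region
#'
#' Approximate self-calibration: each coil's k-space is restricted to the
#' fully sampled central disc (soft-windowed), inverse-transformed to a
#' low-resolution coil image, and normalized by the root-sum-of-squares
#' across coils. Useful when the true simulated maps are withheld; the
#' estimate is smooth but biased near the object boundary.
#'
#' @param kspace a `kspace_data`.
#' @param calib_radius radius (grid points) of the central (ky, kz) disc;
#'   default: the mask's calibration radius, or 6.
#' @return a `coil_set` with `params$estimated = TRUE`.
#' @export
estimate_coils <- function(kspace, calib_radius = NULL) {
  shape <- kspace$params$matrix
  r <- calib_radius %||%
    (if (!is.null(kspace$mask) && is.finite(kspace$mask$calib_radius))
       kspace$mask$calib_radius else 6)
  ny <- shape[2]; nz <- shape[3]
  cy <- ny %/% 2 + 1; cz <- nz %/% 2 + 1
  ky <- matrix(seq_len(ny), ny, nz); kz <- matrix(seq_len(nz), ny, nz, byrow = TRUE)
  d2 <- (ky - cy)^2 + (kz - cz)^2
  win <- exp(-d2 / (2 * (r / 2)^2)) * (d2 <= r^2)   # soft central window
  wk <- array(rep(ifftshift2(win), each = shape[1]), dim = shape)
  lows <- lapply(kspace$data, function(k) ifft3(k * wk))
  rss <- sqrt(Reduce(`+`, lapply(lows, function(x) Mod(x)^2)))
  rss[rss == 0] <- .Machine$double.eps
  sens <- lapply(lows, function(x) x / rss)
  structure(list(sens = sens, n_coils = length(sens),
                 params = list(estimated = TRUE, calib_radius = r)),
            class = "coil_set")
}

#' SVD coil compression
#'
#' Rotates multi-coil k-space and sensitivity maps into the principal
#' components of the coil dimension (computed from the k-space Gram matrix)
#' and keeps the `n_virtual` strongest virtual channels. The rotation is
#' unitary, so keeping all channels is exact; smooth overlapping arrays
#' concentrate nearly all signal energy in the first components.
#'
#' @param kdata list of complex k-space arrays (one per coil).
#' @param sens list of complex sensitivity arrays.
#' @param n_virtual number of virtual channels to keep.
#' @return list with compressed `data`, `sens`, and `energy_kept` (fraction
#'   of total k-space energy in the retained channels).
#' @export
compress_coils <- function(kdata, sens, n_virtual) {
  nc <- length(kdata)
  if (n_virtual >= nc) return(list(data = kdata, sens = sens, energy_kept = 1))
  K <- vapply(kdata, as.vector, complex(length(kdata[[1]])))
  G <- crossprod(Conj(K), K)  # nc x nc Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  V <- eg$vectors[, seq_len(n_virtual), drop = FALSE]
  mix <- function(lst) {
    lapply(seq_len(n_virtual), function(j) {
      acc <- 0
      for (c in seq_len(nc)) acc <- acc + Conj(V[c, j]) * lst[[c]]
      acc
    })
  }
  list(data = mix(kdata), sens = mix(sens),
       energy_kept = sum(eg$values[seq_len(n_virtual)]) / sum(eg$values))
}

#' Retrospective multi-regularization reconstruction
#'
#' Reconstructs the identical k-space matrix once per regularization value,
#' mirroring console retro-reconstruction: all settings share the same mask,
#' noise realization and provenance, differing only in `lambda`.
#'
#' @inheritParams cs_recon
#' @param lambdas non-empty numeric vector of regularization factors (>= 0).
#' @return a named list of `recon_volume`s (names = lambda values).
#' @export
retro_reconstruct <- function(kspace, mask = NULL, coils, lambdas,
                              max_iter = 50, tol = 1e-6, wavelet = "db4",
                              levels = 4,
                              lambda_scale = c("console", "absolute"),
                              n_virtual_coils = NULL) {
  if (length(lambdas) == 0) stop_arg("lambdas must be non-empty")
  if (any(lambdas < 0)) stop_arg("all lambdas must be >= 0")
  lambda_scale <- match.arg(lambda_scale)
  out <- lapply(lambdas, function(l)
    cs_recon(kspace, mask, coils, l, max_iter, tol, wavelet, levels,
             lambda_scale = lambda_scale, n_virtual_coils = n_virtual_coils))
  names(out) <- as.character(lambdas)
  out
}

#' Construct a single-slice reconstruction problem
#'
#' Bundles the ingredients of the per-slice cost function for use with
#' [objective()] and for small solver experiments: masked unitary-DFT data per
#' coil, mask, sensitivities and the wavelet descriptor.
#'
#' @param y list of complex matrices (one per coil), already masked and in the
#'   unitary 2D DFT convention.
#' @param mask logical matrix.
#' @param S list of complex sensitivity matrices.
#' @param lambda regularization factor (>= 0).
#' @param wavelet,levels sparsity transform settings.
#' @return a list of class `recon_problem` (carries the DWT matrices).
#' @export
recon_problem <- function(y, mask, S, lambda, wavelet = "db4", levels = 4) {
  if (lambda < 0) stop_arg("lambda must be >= 0")
  ny <- nrow(y[[1]]); nz <- ncol(y[[1]])
  structure(list(y = y, mask = mask, S = S, lambda = lambda,
                 Wy = dwt_matrix(ny, wavelet, levels),
                 Wz = dwt_matrix(nz, wavelet, levels)),
            class = "recon_problem")
}

# unitary 2D DFT pair used by the per-slice cost
fft2u <- function(x) fft(x) / sqrt(length(x))
ifft2u <- function(k) fft(k, inverse = TRUE) / sqrt(length(k))

#' Reconstruction cost function
#'
#' Evaluates `f(x) = 1/2 sum_c ||M o F(S_c x) - y_c||_2^2 + lambda ||Psi x||_1`
#' for a single-slice [recon_problem()].
#'
#' @param x complex (or real) image matrix.
#' @param problem a `recon_problem`.
#' @return non-negative scalar.
#' @export
objective <- function(x, problem) {
  p <- problem
  data_term <- 0
  for (c in seq_along(p$y)) {
    r <- ifelse(p$mask, 1, 0) * fft2u(p$S[[c]] * x) - p$y[[c]]
    data_term <- data_term + 0.5 * sum(Mod(r)^2)
  }
  w <- dwt2(x, p$Wy, p$Wz)
  data_term + p$lambda * sum(Mod(w))
}
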