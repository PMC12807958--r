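#' Tissue-class signal-to-noise ratio
#'
#' SNR of an image within a tissue mask: mean signal across the mask divided
#' by the standard deviation across the mask (denominator n - 1). A constant
#' (zero-sd) image yields `Inf` as an explicit sentinel.
#'
#' @param image a `recon_volume` or numeric array.
#' @param tissue_mask logical array, at least 2 voxels.
#' @return scalar SNR (possibly `Inf`).
#' @export
tissue_snr <- function(image, tissue_mask) {
  vol <- if (inherits(image, "recon_volume")) image$volume else image
  if (sum(tissue_mask) < 2) stop_arg("tissue mask must contain at least 2 voxels")
  v <- vol[tissue_mask]
  s <- sd(v)
  if (s == 0) return(Inf)
  mean(v) / s
}

#' Basic three-class tissue segmentation
#'
#' One-dimensional 3-class k-means on brain-mask voxel intensities, with
#' centroids initialized at the 10th/50th/90th intensity percentiles so the
#' result is deterministic. Classes are ordered by centroid: CSF < GM < WM.
#'
#' @param image a `recon_volume` or numeric array.
#' @param brain_mask logical array restricting the clustering; default is a
#'   simple intensity support heuristic (voxels above 5% of the robust
#'   maximum), standing in for upstream skull-stripping.
#' @return list of logical arrays `csf`, `gm`, `wm` plus the fitted `centers`.
#' @export
segment_tissues_basic <- function(image, brain_mask = NULL) {
  vol <- if (inherits(image, "recon_volume")) image$volume else image
  if (is.null(brain_mask)) {
    top <- quantile(vol, 0.999, names = FALSE)
    brain_mask <- vol > 0.05 * top
  }
  v <- vol[brain_mask]
  if (length(unique(round(v, 12))) < 3)
    stop("fewer than 3 distinct intensities; segmentation degenerate", call. = FALSE)
  init <- quantile(v, c(0.1, 0.5, 0.9), names = FALSE)
  # k-means needs distinct, well-placed centers: on near-discrete histograms
  # the percentiles can coincide, so fall back to value-space percentiles
  if (anyDuplicated(init)) init <- quantile(unique(v), c(0.1, 0.5, 0.9),
                                            names = FALSE)
  if (anyDuplicated(init)) init <- init + c(-1, 0, 1) * 1e-9 * max(abs(init), 1)
  km <- tryCatch(
    kmeans(v, centers = matrix(init, ncol = 1), iter.max = 100),
    error = function(e)
      kmeans(v, centers = matrix(quantile(unique(v), c(0.1, 0.5, 0.9),
                                          names = FALSE), ncol = 1),
             iter.max = 100, algorithm = "Lloyd"))
  ord <- order(km$centers)
  cls <- match(km$cluster, ord)  # 1 = lowest centroid (CSF), 3 = WM
  out <- lapply(1:3, function(k) {
    m <- array(FALSE, dim = dim(vol))
    m[brain_mask] <- cls == k
    m
  })
  names(out) <- c("csf", "gm", "wm")
  out$centers <- sort(as.numeric(km$centers))
  out
}

#' Image smoothness as spatial-autocorrelation FWHM
#'
#' Classical first-difference estimator: per axis `a`, with `v` the intensity
#' variance within the mask and `d` the variance of first differences along
#' `a` (both voxels of each pair inside the mask), the lag-1 autocorrelation
#' is `rho = 1 - d/(2v)` and `FWHM_a = sqrt(-2 ln 2 / ln rho)` voxels when
#' `0 < rho < 1`. Data rougher than white noise (`rho <= 0`) yield the
#' sentinel `NA` with a warning. The combined value is the geometric mean of
#' the per-axis estimates; results are reported in voxels and, via
#' `voxel_mm`, in mm.
#'
#' @param image a `recon_volume` or numeric array.
#' @param mask logical array with >= 100 voxels spanning >= 3 voxels per axis.
#' @param voxel_mm voxel size for the mm-scale report.
#' @return list with `fwhm_vox` (x, y, z, combined) and `fwhm_mm`.
#' @export
smoothness_fwhm <- function(image, mask, voxel_mm = c(1, 1, 1)) {
  vol <- if (inherits(image, "recon_volume")) image$volume else image
  if (sum(mask) < 100) stop_arg("mask must contain at least 100 voxels")
  rng <- apply(which(mask, arr.ind = TRUE), 2, function(i) diff(range(i)))
  if (any(rng < 2)) stop_arg("mask must span at least 3 voxels per axis")
  v <- var(vol[mask])
  if (v == 0) stop_arg("zero variance within mask")

  axis_fwhm <- function(ax) {
    n <- dim(vol)[ax]
    idx_lo <- slice_index(dim(vol), ax, 1:(n - 1))
    idx_hi <- slice_index(dim(vol), ax, 2:n)
    pair <- mask[idx_lo] & mask[idx_hi]
    dif <- (vol[idx_hi] - vol[idx_lo])[pair]
    if (length(dif) < 2) return(NA_real_)
    d <- var(dif)
    rho <- 1 - d / (2 * v)
    if (is.na(rho) || rho <= 0 || rho >= 1) return(NA_real_)
    sqrt(-2 * log(2) / log(rho))
  }
  f <- vapply(1:3, axis_fwhm, numeric(1))
  if (any(is.na(f)))
    warning("FWHM sentinel: data rougher than white noise along some axis")
  comb <- (f[1] * f[2] * f[3])^(1 / 3)
  fw <- c(x = f[1], y = f[2], z = f[3], combined = comb)
  fmm <- c(f * voxel_mm, comb * prod(voxel_mm)^(1 / 3))
  names(fmm) <- names(fw)
  list(fwhm_vox = fw, fwhm_mm = fmm)
}

# logical index array selecting positions `sel` along axis `ax`
slice_index <- function(dims, ax, sel) {
  idx <- array(FALSE, dim = dims)
  if (ax == 1) idx[sel, , ] <- TRUE
  if (ax == 2) idx[, sel, ] <- TRUE
  if (ax == 3) idx[, , sel] <- TRUE
  idx
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable convolution with a truncated Gaussian kernel; edge effects are
#' removed by renormalizing with the smoothed all-ones volume, so the output
#' is a proper weighted local mean everywhere.
#'
#' @param vol numeric 3D array.
#' @param sigma Gaussian standard deviation in voxels.
#' @param radius kernel half-width; default `round(3 * sigma)`.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth3 <- function(vol, sigma, radius = NULL) {
  r <- radius %||% max(1L, as.integer(round(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  num <- sepconv3_cpp(vol, k)
  den <- sepconv3_cpp(array(1, dim = dim(vol)), k)
  num / den
}

#' Volumetric structural similarity index (SSIM)
#'
#' Local Gaussian-window means, variances and covariance, combined as
#' `[(2 mu_a mu_b + C1)(2 sigma_ab + C2)] /
#'  [(mu_a^2 + mu_b^2 + C1)(sigma_a^2 + sigma_b^2 + C2)]`
#' with `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, L the dynamic range (max over both
#' volumes), then averaged over the volume (or a mask). Symmetric in its
#' arguments and equal to 1 for identical volumes.
#'
#' @param a,b numeric 3D arrays of equal shape (or `recon_volume`s).
#' @param window_sigma Gaussian window sd in voxels (default 1.5, truncated
#'   at 3 sigma).
#' @param K1,K2 stability constants (defaults 0.01, 0.03).
#' @param mask optional logical array restricting the average.
#' @return list with `mean_ssim`, `ssim_map`, and the settings used.
#' @export
ssim3d <- function(a, b, window_sigma = 1.5, K1 = 0.01, K2 = 0.03, mask = NULL) {
  va <- if (inherits(a, "recon_volume")) a$volume else a
  vb <- if (inherits(b, "recon_volume")) b$volume else b
  if (!all(dim(va) == dim(vb))) stop_arg("volumes must have equal shape")
  L <- max(max(va), max(vb)) - min(min(va), min(vb), 0)
  if (L <= 0) stop_arg("dynamic range must be positive")
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  r <- max(1L, as.integer(round(3 * window_sigma)))
  kern <- exp(-((-r:r)^2) / (2 * window_sigma^2))
  kern <- kern / sum(kern)
  den <- sepconv3_cpp(array(1, dim = dim(va)), kern)  # shared edge normalizer
  sm <- function(x) sepconv3_cpp(x, kern) / den
  mu_a <- sm(va); mu_b <- sm(vb)
  s_aa <- sm(va * va) - mu_a^2
  s_bb <- sm(vb * vb) - mu_b^2
  s_ab <- sm(va * vb) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  map <- num / den
  m <- if (is.null(mask)) mean(map) else mean(map[mask])
  list(mean_ssim = m, ssim_map = map, window_sigma = window_sigma,
       K1 = K1, K2 = K2, L = L)
}

#' Voxelwise absolute difference of two volumes
#'
#' Used between reconstructions of the identical k-space at adjacent
#' regularization settings; warns when the provenance differs (the map then
#' mixes reconstruction and acquisition differences).
#'
#' @param a,b `recon_volume`s or arrays of equal shape.
#' @return numeric array `|a - b|`.
#' @export
abs_difference <- function(a, b) {
  va <- if (inherits(a, "recon_volume")) a$volume else a
  vb <- if (inherits(b, "recon_volume")) b$volume else b
  if (!all(dim(va) == dim(vb))) stop_arg("volumes must have equal shape")
  if (inherits(a, "recon_volume") && inherits(b, "recon_volume")) {
    pa <- a$provenance; pb <- b$provenance
    if (!identical(pa$noise_seed, pb$noise_seed) ||
        !identical(pa$mask_seed, pb$mask_seed))
      warning("abs_difference: volumes come from different k-space provenance")
  }
  abs(va - vb)
}
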