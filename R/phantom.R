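#' Default nominal tissue intensities
#'
#' T1-weighted contrast is modeled by fixed nominal tissue means rather than a
#' Bloch simulation: the contrast ordering WM > subcortical > GM > CSF >
#' background is what drives segmentation, SNR and morphometry downstream.
#'
#' @return named numeric vector of nominal intensities (arbitrary units).
#' @export
tissue_intensities <- function() {
  c(background = 0, csf = 0.15, gm = 0.65, wm = 1.00, subcortical = 0.80)
}

# Label codes used in the phantom label volume.
LBL <- list(background = 0L, csf = 1L, gm = 2L, wm = 3L, struct0 = 4L)

#' Generate a digital brain phantom
#'
#' Builds a voxelized brain-like volume with CSF / cortical gray-matter ribbon /
#' white-matter compartments and non-overlapping ellipsoidal subcortical nuclei
#' of intermediate intensity. The cortical ribbon is the shell between two
#' star-shaped surfaces r_inner(theta, phi) and r_outer = r_inner + t, where the
#' thickness t is set per angular octant (in mm), so regional ground-truth
#' thickness is known by construction. Ground-truth structure volumes are voxel
#' counts times voxel volume.
#'
#' @param shape integer triple, grid size (>= 32 each).
#' @param n_structures number of subcortical ellipsoids (>= 0).
#' @param seed integer RNG seed; the phantom is a pure function of its inputs.
#' @param voxel_mm voxel size in mm (length-3).
#' @param thickness_mm ribbon thickness per octant in mm (length 1 or 8).
#'   The default varies regionally (3.2-5.2 mm around a 4.2 mm mean) so that
#'   between-region thickness variance exists for agreement statistics.
#' @param intensities named intensity overrides, see [tissue_intensities()].
#' @param csf_rim_mm thickness of the CSF layer outside the ribbon, mm.
#' @param star_amp amplitude of the smooth star-shape perturbation of the inner
#'   surface (fraction of base radius).
#' @param structure_axes range (min, max) of ellipsoid semi-axes in voxels.
#' @return an object of class `mr_phantom` with fields `label_volume`,
#'   `intensity_volume`, `structures` (data frame), `ribbon_spec`, `voxel_mm`,
#'   `brain_mask`, `center`, `seed`.
#' @export
make_phantom <- function(shape = c(96, 96, 96), n_structures = 6, seed = 1,
                         voxel_mm = c(1, 1, 1),
                         thickness_mm = c(3.2, 4.6, 3.8, 5.2, 4.2, 3.5, 4.9, 4.4),
                         intensities = NULL, csf_rim_mm = 3,
                         star_amp = 0.04, structure_axes = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 32))
    stop_arg("shape must be three integers, each >= 32")
  if (n_structures < 0) stop_arg("n_structures must be >= 0")
  ti <- tissue_intensities()
  if (!is.null(intensities)) ti[names(intensities)] <- intensities
  if (length(thickness_mm) == 1) thickness_mm <- rep(thickness_mm, 8)
  if (length(thickness_mm) != 8) stop_arg("thickness_mm must have length 1 or 8")

  set.seed(seed)
  ctr <- (shape + 1) / 2
  g <- coord_grids(shape)
  dx <- (g$x - ctr[1]) * voxel_mm[1]
  dy <- (g$y - ctr[2]) * voxel_mm[2]
  dz <- (g$z - ctr[3]) * voxel_mm[3]
  rho <- sqrt(dx^2 + dy^2 + dz^2)
  # direction angles of each voxel from the center
  theta <- atan2(dy, dx)
  phi <- acos(ifelse(rho > 0, dz / pmax(rho, 1e-12), 1))

  # outer extent must fit inside the grid with margin
  r_max_fit <- 0.48 * min(shape * voxel_mm)
  mean_t <- mean(thickness_mm)
  r_in0 <- r_max_fit - mean_t - csf_rim_mm - 1.5
  if (r_in0 < 6) stop("shape too small to contain the cortical ribbon", call. = FALSE)

  # smooth star-shaped perturbation: low-order angular harmonics, seeded
  a <- rnorm(6, 0, star_amp / 2)
  pert <- a[1] * sin(2 * theta) * sin(phi) + a[2] * cos(2 * theta) * sin(phi) +
    a[3] * cos(2 * phi) + a[4] * sin(3 * theta) * sin(phi)^2 +
    a[5] * cos(phi) + a[6] * sin(phi) * cos(theta)
  pert <- pmax(pmin(pert, star_amp), -star_amp)
  r_inner <- r_in0 * (1 + pert)

  # per-octant thickness field (mm)
  oct_id <- octant_index(g$x, g$y, g$z, ctr)
  t_field <- array(thickness_mm[oct_id], dim = shape)
  r_outer <- r_inner + t_field
  r_csf <- r_outer + csf_rim_mm

  lbl <- array(LBL$background, dim = shape)
  lbl[rho <= r_csf] <- LBL$csf
  lbl[rho <= r_outer] <- LBL$gm
  lbl[rho <= r_inner] <- LBL$wm

  # subcortical ellipsoids, non-overlapping, strictly inside WM; the default
  # size range is anatomically scaled (at 96 voxels ~ a 1 mm grid it spans
  # amygdala-to-thalamus-sized bodies), capped so several structures still
  # fit inside small grids' white matter
  ax_hi <- min(0.125 * min(shape), 0.3 * r_in0 / mean(voxel_mm))
  ax_rng <- structure_axes %||% c(min(0.075 * min(shape), 0.6 * ax_hi), ax_hi)
  structures <- data.frame(
    structure_id = integer(0), name = character(0),
    cx = numeric(0), cy = numeric(0), cz = numeric(0),
    ax = numeric(0), ay = numeric(0), az = numeric(0),
    intensity = numeric(0), vol_vox = numeric(0), vol_mm3 = numeric(0)
  )
  if (n_structures > 0) {
    occupied <- array(FALSE, dim = shape)
    for (s in seq_len(n_structures)) {
      placed <- FALSE
      # candidate centers: unoccupied white-matter voxels (the all-WM
      # clearance check below keeps structures off the boundary)
      cand <- which(lbl == LBL$wm & !occupied)
      for (attempt in seq_len(100)) {
        ax <- runif(3, ax_rng[1], ax_rng[2])
        cen <- as.numeric(arrayInd(cand[sample.int(length(cand), 1)], shape))
        sel <- ellipsoid_voxels(shape, cen, ax)
        if (length(sel) == 0) next
        ok <- all(lbl[sel] == LBL$wm) && !any(occupied[sel])
        if (!ok) next
        # margin of 1 voxel: dilate-check via slightly larger ellipsoid
        sel_marg <- ellipsoid_voxels(shape, cen, ax + 1)
        if (!all(lbl[sel_marg] == LBL$wm) || any(occupied[sel_marg])) next
        lab <- LBL$struct0 + s - 1L
        lbl[sel] <- lab
        occupied[sel_marg] <- TRUE
        structures <- rbind(structures, data.frame(
          structure_id = lab, name = sprintf("nucleus_%02d", s),
          cx = cen[1], cy = cen[2], cz = cen[3],
          ax = ax[1], ay = ax[2], az = ax[3],
          intensity = ti[["subcortical"]],
          vol_vox = length(sel), vol_mm3 = length(sel) * prod(voxel_mm)
        ))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place non-overlapping structure after 100 attempts", call. = FALSE)
    }
  }

  img <- array(ti[["background"]], dim = shape)
  img[lbl == LBL$csf] <- ti[["csf"]]
  img[lbl == LBL$gm] <- ti[["gm"]]
  img[lbl == LBL$wm] <- ti[["wm"]]
  if (nrow(structures) > 0) {
    for (i in seq_len(nrow(structures)))
      img[lbl == structures$structure_id[i]] <- structures$intensity[i]
  }

  structure(list(
    label_volume = lbl, intensity_volume = img, structures = structures,
    ribbon_spec = list(r_in0 = r_in0, star_coef = a, star_amp = star_amp,
                       thickness_mm = thickness_mm, regions = "octants"),
    voxel_mm = voxel_mm, brain_mask = lbl > 0, center = ctr,
    intensities = ti, shape = shape, seed = seed
  ), class = "mr_phantom")
}

# Linear indices of voxels inside an ellipsoid (center cen, semi-axes ax, voxels).
ellipsoid_voxels <- function(shape, cen, ax) {
  lo <- pmax(floor(cen - ax), 1)
  hi <- pmin(ceiling(cen + ax), shape)
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  q <- outer(outer(((xs - cen[1]) / ax[1])^2, ((ys - cen[2]) / ax[2])^2, "+"),
             ((zs - cen[3]) / ax[3])^2, "+")
  keep <- which(q <= 1, arr.ind = TRUE)
  if (nrow(keep) == 0) return(integer(0))
  ix <- xs[keep[, 1]]; iy <- ys[keep[, 2]]; iz <- zs[keep[, 3]]
  ix + (iy - 1L) * shape[1] + (iz - 1L) * shape[1] * shape[2]
}

#' Angular octant index (1..8) of voxels around a center
#'
#' Octants are defined by the signs of the (x, y, z) offsets from the center;
#' they serve as the regional parcellation of the cortical ribbon.
#' @param x,y,z coordinate arrays (same shape).
#' @param center length-3 center.
#' @return integer array of region indices in 1..8.
#' @export
octant_index <- function(x, y, z, center) {
  1L + (x > center[1]) + 2L * (y > center[2]) + 4L * (z > center[3])
}

#' @export
print.mr_phantom <- function(x, ...) {
  cat(sprintf("<mr_phantom> %s voxels, %.3g mm3/voxel, %d structures, seed %d\n",
              paste(x$shape, collapse = "x"), prod(x$voxel_mm),
              nrow(x$structures), x$seed))
  invisible(x)
}

#' Generate a smooth multiplicative intensity bias field
#'
#' Stand-in for receive/transmit (B1) intensity non-uniformity that scanner
#' pre-normalization removes. The field is a seeded combination of low-frequency
#' cosines, scaled to `1 +/- amplitude` and rescaled to mean 1 inside the brain
#' mask; it is strictly positive and therefore exactly removable by division.
#'
#' @param shape grid size.
#' @param amplitude peak relative deviation from unity (default 0.2, i.e. 20%).
#' @param seed integer seed.
#' @param brain_mask logical array used for the mean-1 normalization (default:
#'   whole volume).
#' @return real 3D array of the same shape.
#' @export
make_bias_field <- function(shape, amplitude = 0.2, seed = 1, brain_mask = NULL) {
  shape <- as.integer(shape)
  set.seed(seed)
  g <- coord_grids(shape)
  f <- array(0, dim = shape)
  for (k in 1:4) {
    w <- runif(3, 0.5, 1.5) * pi / shape     # low spatial frequencies
    ph <- runif(3, 0, 2 * pi)
    amp <- rnorm(1, 0, 1)
    f <- f + amp * cos(w[1] * g$x + ph[1]) * cos(w[2] * g$y + ph[2]) *
      cos(w[3] * g$z + ph[3])
  }
  f <- f / max(abs(f))
  field <- 1 + amplitude * f
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = shape)
  field <- field / mean(field[brain_mask])
  stopifnot(all(field > 0))
  field
}

#' Generate smooth complex coil sensitivity maps
#'
#' Coil magnitudes are Gaussian profiles centered on points on a ring around
#' the volume; phases are smooth seeded linear ramps. The set is normalized so
#' the voxelwise root-sum-of-squares (RSS) is exactly 1 everywhere, which makes
#' the SENSE forward operator norm at most 1 and simplifies noise calibration.
#'
#' @param shape grid size.
#' @param n_coils number of receive coils (>= 1).
#' @param seed integer seed.
#' @param flat if TRUE (only with `n_coils = 1`) return a single uniform coil
#'   with sensitivity identically 1.
#' @param width Gaussian profile width as a fraction of the grid extent.
#' @return an object of class `coil_set`: list with `sens` (list of complex 3D
#'   arrays), `n_coils`, and profile parameters.
#' @export
make_coils <- function(shape, n_coils = 8, seed = 1, flat = FALSE, width = 0.6) {
  shape <- as.integer(shape)
  if (n_coils < 1) stop_arg("n_coils must be >= 1")
  if (flat) {
    if (n_coils != 1) stop_arg("flat profile requires n_coils = 1")
    s <- array(complex(real = 1, imaginary = 0), dim = shape)
    return(structure(list(sens = list(s), n_coils = 1L,
                          params = list(flat = TRUE, seed = seed)),
                     class = "coil_set"))
  }
  set.seed(seed)
  ctr <- (shape + 1) / 2
  g <- coord_grids(shape)
  sig <- width * mean(shape)
  ring_r <- 0.62 * mean(shape)
  sens <- vector("list", n_coils)
  for (c in seq_len(n_coils)) {
    ang <- 2 * pi * (c - 1) / n_coils + runif(1, -0.2, 0.2)
    zoff <- ring_r * 0.3 * sin(2 * ang + runif(1, 0, pi))
    cen <- c(ctr[1] + ring_r * cos(ang), ctr[2] + ring_r * sin(ang), ctr[3] + zoff)
    d2 <- (g$x - cen[1])^2 + (g$y - cen[2])^2 + (g$z - cen[3])^2
    mag <- exp(-d2 / (2 * sig^2))
    ph <- runif(3, -1, 1) * pi / (2 * mean(shape))
    ph0 <- runif(1, 0, 2 * pi)
    phase <- ph0 + ph[1] * (g$x - ctr[1]) + ph[2] * (g$y - ctr[2]) + ph[3] * (g$z - ctr[3])
    sens[[c]] <- mag * exp(1i * phase)
  }
  rss <- sqrt(Reduce(`+`, lapply(sens, function(s) Mod(s)^2)))
  sens <- lapply(sens, function(s) s / rss)
  structure(list(sens = sens, n_coils = as.integer(n_coils),
                 params = list(flat = FALSE, seed = seed, width = width)),
            class = "coil_set")
}

#' Root-sum-of-squares magnitude of a coil set
#' @param coils a `coil_set`.
#' @return real 3D array.
#' @export
coil_rss <- function(coils) {
  sqrt(Reduce(`+`, lapply(coils$sens, function(s) Mod(s)^2)))
}

#' Acquisition parameter record
#'
#' TR/TI/TE are protocol metadata (they set the scan-time estimate and document
#' the emulated protocol); the matrix, turbo factor and noise level drive the
#' simulation. Defaults mirror an ADNI-3-style 3T protocol run at reduced
#' matrix for desk scale.
#'
#' @param matrix integer triple (n_readout, n_ky, n_kz), all >= 8.
#' @param TR_ms,TI_ms,TE_ms sequence timing metadata in ms.
#' @param voxel_mm voxel size (mm).
#' @param turbo_factor phase-encode steps per readout block (>= 1).
#' @param noise_sd complex k-space noise standard deviation per real/imaginary
#'   component (k-space units; see [noise_sd_for_snr()]).
#' @param seed noise seed.
#' @return a list of class `acq_params`.
#' @export
acq_params <- function(matrix = c(96, 96, 96), TR_ms = 2300, TI_ms = 900,
                       TE_ms = 2.9, voxel_mm = c(1, 1, 1), turbo_factor = 96,
                       noise_sd = 0, seed = 1) {
  matrix <- as.integer(matrix)
  if (any(matrix < 8)) stop_arg("matrix dimensions must be >= 8")
  if (turbo_factor < 1) stop_arg("turbo_factor must be >= 1")
  if (noise_sd < 0) stop_arg("noise_sd must be >= 0")
  structure(list(TR_ms = TR_ms, TI_ms = TI_ms, TE_ms = TE_ms, matrix = matrix,
                 voxel_mm = voxel_mm, turbo_factor = as.integer(turbo_factor),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "acq_params")
}

#' k-space noise level for a target white-matter SNR
#'
#' With RSS-normalized coils and the package's DFT convention (unnormalized
#' forward, 1/N inverse), complex k-space noise of standard deviation sigma per
#' component yields image-domain noise of sigma/sqrt(N) in the coil-combined
#' reconstruction. White matter is flat in the phantom, so its within-mask
#' standard deviation is the noise level and SNR_WM ~= WM_mean * sqrt(N) / sigma.
#'
#' @param phantom an `mr_phantom` (or anything with `$shape`, `$intensities`).
#' @param snr_wm target white-matter SNR of the fully sampled reconstruction
#'   (default 60; thermal noise only -- the phantom's tissues carry no
#'   anatomical texture, so the pure-noise SNR is set high enough that
#'   under-sampling artifact, not thermal noise, limits image quality).
#' @return noise standard deviation in k-space units.
#' @export
noise_sd_for_snr <- function(phantom, snr_wm = 60) {
  n <- prod(phantom$shape)
  phantom$intensities[["wm"]] * sqrt(n) / snr_wm
}

#' Simulate noisy multi-coil k-space from a phantom
#'
#' Forward model: for each coil c, `k_c = FFT3(bias * intensity * S_c) + noise`,
#' with the unnormalized forward DFT and i.i.d. circular complex Gaussian noise
#' of standard deviation `params$noise_sd` per real/imaginary component. If a
#' sampling mask is supplied, unsampled (ky, kz) columns are set exactly to
#' zero. Deterministic for a fixed `params$seed`.
#'
#' @param phantom an `mr_phantom`.
#' @param coils a `coil_set` on the same grid.
#' @param bias multiplicative bias field (same grid) or NULL for none.
#' @param params an `acq_params` whose matrix matches the phantom shape.
#' @param mask optional `sampling_mask` on the (ky, kz) plane.
#' @return an object of class `kspace_data`: `data` (list of complex arrays),
#'   `mask`, `params`, `noise_seed`.
#' @export
simulate_kspace <- function(phantom, coils, bias = NULL, params, mask = NULL) {
  shape <- phantom$shape
  if (!all(params$matrix == shape))
    stop("params$matrix does not match phantom shape", call. = FALSE)
  for (s in coils$sens)
    if (!all(dim(s) == shape)) stop("coil grid does not match phantom", call. = FALSE)
  img <- phantom$intensity_volume
  if (!is.null(bias)) {
    if (!all(dim(bias) == shape)) stop("bias grid mismatch", call. = FALSE)
    img <- img * bias
  }
  set.seed(params$seed)
  n <- prod(shape)
  ks <- vector("list", coils$n_coils)
  for (c in seq_len(coils$n_coils)) {
    k <- fft(img * coils$sens[[c]])
    if (params$noise_sd > 0) {
      k <- k + complex(real = rnorm(n, 0, params$noise_sd),
                       imaginary = rnorm(n, 0, params$noise_sd))
    }
    ks[[c]] <- k
  }
  if (!is.null(mask)) ks <- lapply(ks, apply_pe_mask, mask = mask$mask)
  structure(list(data = ks, mask = mask, params = params,
                 noise_seed = params$seed),
            class = "kspace_data")
}

# Circular shift moving a center-DC (ky, kz) mask to the DFT's corner-DC
# convention (inverse fftshift): element (1, 1) receives the mask center.
ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  c1 <- n1 %/% 2 + 1; c2 <- n2 %/% 2 + 1
  m[((seq_len(n1) - 1 + c1 - 1) %% n1) + 1,
    ((seq_len(n2) - 1 + c2 - 1) %% n2) + 1, drop = FALSE]
}

# Zero out unsampled phase-encode (ky, kz) columns of a 3D k-space array.
# The sampling mask is defined with DC at the grid center; the k-space array
# follows the DFT corner-DC convention, so the mask is inverse-shifted first.
apply_pe_mask <- function(k, mask) {
  stopifnot(all(dim(k)[2:3] == dim(mask)))
  ms <- ifftshift2(mask)
  mk <- array(rep(ms, each = dim(k)[1]), dim = dim(k))
  k * mk
}
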