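#' Jittered variable-density spiral-phyllotaxis sampling mask
#'
#' Generates an incoherent Cartesian phase-encode (ky, kz) under-sampling mask.
#' Candidate points are laid out on a golden-angle spiral: point m of M has
#' polar angle `m * 137.50776 deg + jitter` (jitter uniform in +/- `jitter`
#' degrees) and normalized radius `(m / M)^q`, mapped elliptically onto the
#' grid and snapped to the nearest unsampled point of the elliptical footprint
#' (expanding ring search on collision). A fully sampled calibration disc of
#' radius `calib_radius` grid points is added afterwards, and the total sample
#' count is trimmed back (largest spiral indices first) so the achieved
#' acceleration matches the request. Samples are partitioned into shots of
#' `turbo` consecutive spiral indices; each shot is reordered symmetrically so
#' its minimum-radius sample sits at the temporal midpoint, emulating
#' center-of-k-space-at-center-of-shot timing.
#'
#' @param n_ky,n_kz grid size (>= 8 each).
#' @param R requested acceleration factor (>= 1), relative to the footprint.
#' @param turbo shots hold up to this many phase encodes (>= 1).
#' @param q radial density exponent; q > 0.5 gives a center-dense pattern.
#' @param jitter angular jitter amplitude in degrees.
#' @param calib_radius radius of the fully sampled central disc (grid points).
#' @param seed integer seed (jitter realization).
#' @return an object of class `sampling_mask`: logical `mask` (n_ky x n_kz),
#'   `shots` (list of index matrices in temporal order), `R_requested`,
#'   `R_achieved`, `footprint`, `q`, `jitter`, `calib_radius`, `seed`, `turbo`.
#' @export
phyllotaxis_mask <- function(n_ky, n_kz, R, turbo = n_kz, q = 0.7, jitter = 20,
                             calib_radius = 6, seed = 1) {
  n_ky <- as.integer(n_ky); n_kz <- as.integer(n_kz)
  if (n_ky < 8 || n_kz < 8) stop_arg("grid must be at least 8x8")
  if (R < 1) stop_arg("acceleration R must be >= 1")
  if (turbo < 1) stop_arg("turbo must be >= 1")
  if (calib_radius < 0) stop_arg("calib_radius must be >= 0")

  fp <- elliptical_footprint(n_ky, n_kz)
  fp_count <- sum(fp)
  m_target <- round(fp_count / R)
  if (m_target < 1) stop("infeasible acceleration: fewer than one sample", call. = FALSE)
  if (m_target < turbo && R > 1 && m_target < 1)
    stop("infeasible acceleration for this turbo factor", call. = FALSE)

  # DC at (n_ky %/% 2 + 1, n_kz %/% 2 + 1)
  cy <- n_ky %/% 2 + 1
  cz <- n_kz %/% 2 + 1
  disc <- calib_disc(n_ky, n_kz, calib_radius)
  disc <- disc[fp[disc], , drop = FALSE]  # clamp to the footprint

  # spiral candidates at elliptical radial mapping, snapped to the footprint
  spiral_points <- function(m_spiral) {
    set.seed(seed)
    m <- seq_len(m_spiral)
    u <- runif(m_spiral, -jitter, jitter) * pi / 180
    theta <- m * (137.50776 * pi / 180) + u
    r <- (m / m_spiral)^q
    ty <- cy + r * (n_ky / 2 - 1) * cos(theta)
    tz <- cz + r * (n_kz / 2 - 1) * sin(theta)
    snap_to_footprint(cbind(ty, tz), fp)
  }
  calib_extras <- function(snapped) {
    occ <- matrix(FALSE, n_ky, n_kz)
    occ[snapped] <- TRUE
    extra <- disc[!occ[disc], , drop = FALSE]
    # temporal order: radius descending then angle (deterministic)
    if (nrow(extra) > 0) {
      er <- sqrt((extra[, 1] - cy)^2 + (extra[, 2] - cz)^2)
      ea <- atan2(extra[, 2] - cz, extra[, 1] - cy)
      extra <- extra[order(-er, ea), , drop = FALSE]
    }
    extra
  }
  # two passes: the first estimates how many calibration-disc points the
  # spiral leaves uncovered, the second shrinks the spiral by that number so
  # the total count stays on target without discarding outer k-space samples
  snapped <- spiral_points(m_target)
  e1 <- nrow(calib_extras(snapped))
  if (e1 > 0 && m_target - e1 >= 1) {
    snapped <- spiral_points(m_target - e1)
  }
  extra <- calib_extras(snapped)
  pts <- rbind(snapped, extra)

  mask <- matrix(FALSE, n_ky, n_kz)
  mask[pts] <- TRUE
  n_samp <- sum(mask)
  shots <- partition_shots(pts, turbo, c(cy, cz), c(n_ky, n_kz))

  structure(list(
    mask = mask, shots = shots, R_requested = R,
    R_achieved = fp_count / n_samp, footprint = fp, q = q, jitter = jitter,
    calib_radius = calib_radius, seed = as.integer(seed),
    turbo = as.integer(turbo), shape = c(n_ky, n_kz), dc = c(cy, cz)
  ), class = "sampling_mask")
}

#' Fully sampled mask
#'
#' @param n_ky,n_kz grid size.
#' @param elliptical sample only the inscribed elliptical footprint (TRUE) or
#'   the full rectangle (FALSE, the conventional fully sampled reference).
#' @param turbo shot length for the ordering metadata.
#' @return a `sampling_mask` with `R_achieved = 1` relative to its support.
#' @export
full_mask <- function(n_ky, n_kz, elliptical = FALSE, turbo = n_kz) {
  n_ky <- as.integer(n_ky); n_kz <- as.integer(n_kz)
  if (n_ky < 1 || n_kz < 1) stop_arg("grid must be at least 1x1")
  cy <- n_ky %/% 2 + 1; cz <- n_kz %/% 2 + 1
  if (elliptical) {
    mask <- elliptical_footprint(n_ky, n_kz)
    fp <- mask
  } else {
    mask <- matrix(TRUE, n_ky, n_kz)
    fp <- mask
  }
  pts <- which(mask, arr.ind = TRUE)
  colnames(pts) <- NULL
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]  # ky-line ordering
  shots <- partition_shots(pts, turbo, c(cy, cz), c(n_ky, n_kz))
  structure(list(mask = mask, shots = shots, R_requested = 1,
                 R_achieved = sum(fp) / sum(mask), footprint = fp,
                 q = NA_real_, jitter = 0, calib_radius = NA_real_,
                 seed = NA_integer_, turbo = as.integer(turbo),
                 shape = c(n_ky, n_kz), dc = c(cy, cz)),
            class = "sampling_mask")
}

#' Uniform 1-in-R phase-encode decimation mask (coherent reference pattern)
#'
#' Keeps every R-th ky line (all kz); the coherent counterpart used as the
#' point-spread-function comparison for the incoherent phyllotaxis pattern.
#' @param n_ky,n_kz grid size.
#' @param R integer decimation factor.
#' @return a `sampling_mask`.
#' @export
uniform_mask <- function(n_ky, n_kz, R) {
  n_ky <- as.integer(n_ky); n_kz <- as.integer(n_kz)
  R <- as.integer(R)
  if (R < 1) stop_arg("R must be >= 1")
  cy <- n_ky %/% 2 + 1; cz <- n_kz %/% 2 + 1
  mask <- matrix(FALSE, n_ky, n_kz)
  rows <- seq.int(from = ((cy - 1L) %% R) + 1L, to = n_ky, by = R)
  mask[rows, ] <- TRUE
  pts <- which(mask, arr.ind = TRUE); colnames(pts) <- NULL
  shots <- partition_shots(pts, n_kz, c(cy, cz), c(n_ky, n_kz))
  structure(list(mask = mask, shots = shots, R_requested = R,
                 R_achieved = (n_ky * n_kz) / sum(mask), footprint = matrix(TRUE, n_ky, n_kz),
                 q = NA_real_, jitter = 0, calib_radius = NA_real_,
                 seed = NA_integer_, turbo = as.integer(n_kz),
                 shape = c(n_ky, n_kz), dc = c(cy, cz)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %dx%d, R requested %.3g achieved %.3g, %d shots, seed %s\n",
              x$shape[1], x$shape[2], x$R_requested, x$R_achieved,
              length(x$shots), as.character(x$seed)))
  invisible(x)
}

# Inscribed elliptical footprint of a ky-kz rectangle (logical matrix).
elliptical_footprint <- function(n_ky, n_kz) {
  cy <- n_ky %/% 2 + 1; cz <- n_kz %/% 2 + 1
  ky <- matrix(seq_len(n_ky), n_ky, n_kz)
  kz <- matrix(seq_len(n_kz), n_ky, n_kz, byrow = TRUE)
  ((ky - cy) / (n_ky / 2))^2 + ((kz - cz) / (n_kz / 2))^2 <= 1
}

# Grid points of the central calibration disc (circular in grid units).
calib_disc <- function(n_ky, n_kz, radius) {
  if (radius <= 0) return(matrix(integer(0), 0, 2))
  cy <- n_ky %/% 2 + 1; cz <- n_kz %/% 2 + 1
  ys <- max(1, cy - radius):min(n_ky, cy + radius)
  zs <- max(1, cz - radius):min(n_kz, cz + radius)
  gr <- expand.grid(y = ys, z = zs)
  keep <- (gr$y - cy)^2 + (gr$z - cz)^2 <= radius^2
  as.matrix(gr[keep, c("y", "z")])
}

# Partition ordered sample points into shots and reorder each symmetrically so
# the minimum-radius sample lies at the temporal midpoint.
partition_shots <- function(pts, turbo, dc, shape) {
  n <- nrow(pts)
  if (n == 0) return(list())
  n_shots <- ceiling(n / turbo)
  shots <- vector("list", n_shots)
  r <- sqrt((pts[, 1] - dc[1])^2 + (pts[, 2] - dc[2])^2)
  for (s in seq_len(n_shots)) {
    idx <- ((s - 1L) * turbo + 1L):min(s * turbo, n)
    rs <- r[idx]
    ord <- order(-rs)         # descending radius
    k <- length(idx)
    pos <- integer(k)
    for (i in seq_len(k)) {
      pos[i] <- if (i %% 2 == 1) (i + 1) %/% 2 else k + 1L - i %/% 2
    }
    out <- matrix(0L, k, 2)
    out[pos, ] <- pts[idx[ord], , drop = FALSE]
    shots[[s]] <- out
  }
  shots
}

# Snap real-valued targets to nearest unsampled footprint grid points.
snap_to_footprint <- function(targets, footprint) {
  res <- snap_points_cpp(targets, footprint)
  res + 1L  # C++ is 0-based
}

#' Point-spread-function incoherence metrics of a sampling mask
#'
#' The PSF is the inverse 2D DFT of the mask. Returns the mainlobe (center)
#' amplitude and the peak sidelobe ratio: the maximum off-center PSF magnitude
#' divided by the center magnitude. Incoherent masks have low, noise-like
#' sidelobes; coherent decimation has replica peaks of ratio ~1.
#'
#' @param mask a `sampling_mask` or logical matrix.
#' @return list with `mainlobe` and `peak_sidelobe_ratio`.
#' @export
mask_psf_metrics <- function(mask) {
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  if (sum(m) == 0) stop_arg("mask is empty")
  psf <- fft(ifelse(m, 1, 0), inverse = TRUE) / length(m)
  a <- Mod(psf)
  main <- a[1, 1]       # DC-at-corner convention of the unshifted DFT
  a[1, 1] <- 0
  list(mainlobe = main, peak_sidelobe_ratio = max(a) / main)
}

#' Idealized scan-time estimate
#'
#' One shot (readout block) per TR: returns `n_shots * TR_ms / 1000` seconds.
#' This excludes vendor preparation and dummy shots, so printed protocol times
#' can differ by roughly one TR.
#'
#' @param mask a `sampling_mask` with shot structure.
#' @param params an `acq_params` (uses `TR_ms`).
#' @return scan time in seconds.
#' @export
estimate_scan_time <- function(mask, params) {
  if (length(mask$shots) == 0) stop_arg("mask has no shots")
  if (params$TR_ms <= 0) stop_arg("TR must be positive")
  length(mask$shots) * params$TR_ms / 1000
}
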