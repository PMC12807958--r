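#' Estimate subcortical structure volumes from a reconstructed image
#'
#' Ground-truth-seeded proxy for atlas-based subcortical segmentation: for
#' each structure in the phantom table, a region is grown (6-connectivity)
#' from the known center over voxels whose intensity lies within a band,
#' capped at `cap_frac` times the ground-truth volume. The band is fit
#' locally: a deterministic two-class split of the voxels in a ground-truth-
#' sized box around the center separates the dark structure from surrounding
#' white matter, the band's upper edge is the class midpoint (blur-invariant
#' for symmetric kernels) and its half-width is the midpoint-to-structure
#' contrast scaled by `band_frac`/0.5. A reconstruction that erases the
#' structure-to-WM contrast collapses the two classes (or floods the growth
#' to the cap) and is reported as the missing-structure sentinel (`NA`).
#'
#' @param image a `recon_volume` or numeric array on the phantom grid.
#' @param phantom an `mr_phantom` (uses `structures`, `voxel_mm`,
#'   `intensities`).
#' @param band_frac band half-width scale; at the default 0.5 the band is
#'   symmetric about the structure's fitted class mean with half-width equal
#'   to the midpoint-to-structure contrast.
#' @param cap_frac growth cap as a multiple of ground-truth volume (default 3).
#' @param smooth_sigma Gaussian pre-smoothing in voxels applied before region
#'   growing (default 0.6; segmentation-style noise suppression -- a symmetric
#'   kernel leaves the half-contrast boundary crossing in place, and at this
#'   width the curvature-induced shrinkage of small structures stays below
#'   the voxelization error).
#' @return a `morph_table` data frame with one `volume` row per structure:
#'   columns id, kind, estimate (mm^3), truth (mm^3).
#' @export
estimate_volumes <- function(image, phantom, band_frac = 0.5, cap_frac = 3,
                             smooth_sigma = 0.6) {
  vol <- if (inherits(image, "recon_volume")) image$volume else image
  if (!all(dim(vol) == phantom$shape))
    stop("image is not on the phantom grid", call. = FALSE)
  if (smooth_sigma > 0) vol <- gaussian_smooth3(vol, smooth_sigma)
  st <- phantom$structures
  vx <- prod(phantom$voxel_mm)
  dm <- dim(vol)
  rows <- lapply(seq_len(nrow(st)), function(i) {
    cap <- as.integer(ceiling(cap_frac * st$vol_vox[i]))
    seedv <- as.integer(round(c(st$cx[i], st$cy[i], st$cz[i])))
    cen <- c(st$cx[i], st$cy[i], st$cz[i])
    ax <- c(st$ax[i], st$ay[i], st$az[i])
    # the intensity band is measured from the image itself, using the known
    # geometry as the seeding prior: the structure level is the median over
    # the inner half-ellipsoid, the white-matter level the median over the
    # one-voxel shell just outside the structure (guaranteed WM by the
    # placement margin). The band's upper edge is their midpoint, which is
    # blur-invariant for symmetric kernels, so compressed contrast does not
    # bias the boundary; erased contrast (midpoint indistinguishable from
    # the local noise) yields the missing-structure sentinel.
    inner <- ellipsoid_voxels(dm, cen, pmax(ax / 2, 1))
    shell <- setdiff(ellipsoid_voxels(dm, cen, ax + 1),
                     ellipsoid_voxels(dm, cen, ax))
    if (length(inner) < 3 || length(shell) < 3)
      return(data.frame(id = st$name[i], kind = "volume",
                        estimate = NA_real_, truth = st$vol_mm3[i]))
    mu_s <- stats::median(vol[inner])
    mu_wm <- stats::median(vol[shell])
    noise <- 1.4826 * stats::mad(vol[shell])
    contrast <- mu_wm - mu_s
    if (contrast < 1.5 * noise || contrast <= 0) {
      est <- NA_real_   # contrast erased relative to the local noise level
    } else {
      t_mid <- (mu_s + mu_wm) / 2
      band_lo <- mu_s - (band_frac / 0.5) * contrast / 2
      half_box <- ceiling(2 * ax + 2)
      lo <- pmax(seedv - half_box, 1); hi <- pmin(seedv + half_box, dm)
      sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      # the growth region is the seeded prior: white matter plus the
      # structure's own territory. Without the wall, blur bridges the gap
      # to equally dark neighbours (all nuclei share the nominal intensity)
      # or to the blurred ribbon shell, and the growth merges across.
      lbl_sub <- phantom$label_volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      sub[!(lbl_sub == 3L | lbl_sub == st$structure_id[i])] <- Inf
      grown <- region_grow_cpp(sub, seedv - lo + 1L, band_lo, t_mid, cap)
      n <- sum(grown)
      est <- if (n == 0 || n >= cap) NA_real_ else n * vx
    }
    data.frame(id = st$name[i], kind = "volume", estimate = est,
               truth = st$vol_mm3[i])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("morph_table", class(out))
  out
}

#' Estimate regional cortical ribbon thickness
#'
#' Proxy for surface-based cortical thickness: tissues are segmented with
#' [segment_tissues_basic()], and for every gray-matter ribbon voxel the
#' thickness is the Euclidean distance to the nearest white-matter voxel plus
#' the distance to the nearest outside-brain/CSF voxel, minus one voxel so
#' that a flat ribbon of t voxels measures exactly t. Ribbon voxels are GM
#' voxels within `max_thickness_mm` of the outer boundary (which excludes
#' deep gray matter); estimates are averaged per angular octant around the
#' phantom center.
#'
#' @param image a `recon_volume` or numeric array.
#' @param phantom an `mr_phantom` (center, voxel size, brain mask,
#'   ground-truth per-octant thickness).
#' @param max_thickness_mm ribbon depth cutoff in mm (default 10).
#' @param seg optional precomputed [segment_tissues_basic()] result.
#' @return a `morph_table` data frame with one `thickness` row per octant
#'   region: columns id, kind, estimate (mm), truth (mm). Empty regions get
#'   the `NA` sentinel.
#' @export
estimate_thickness <- function(image, phantom, max_thickness_mm = 10,
                               seg = NULL) {
  vol <- if (inherits(image, "recon_volume")) image$volume else image
  if (!all(dim(vol) == phantom$shape))
    stop("image is not on the phantom grid", call. = FALSE)
  vm <- phantom$voxel_mm
  if (is.null(seg)) seg <- segment_tissues_basic(vol, phantom$brain_mask)
  outer_m <- (!phantom$brain_mask) | seg$csf
  d_wm <- edt3_cpp(array(as.numeric(seg$wm), dim = phantom$shape), vm)
  d_out <- edt3_cpp(array(as.numeric(outer_m), dim = phantom$shape), vm)
  thick <- d_wm + d_out - mean(vm)
  ribbon <- seg$gm & (d_out <= max_thickness_mm)
  g <- coord_grids(phantom$shape)
  octs <- octant_index(g$x, g$y, g$z, phantom$center)
  truth <- phantom$ribbon_spec$thickness_mm
  rows <- lapply(1:8, function(k) {
    sel <- ribbon & (octs == k)
    est <- if (sum(sel) == 0) NA_real_ else mean(thick[sel])
    data.frame(id = sprintf("octant_%d", k), kind = "thickness",
               estimate = est, truth = truth[k])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("morph_table", class(out))
  out
}

#' Test-retest repeatability of morphometric estimates
#'
#' Percent agreement between two repeats of the same protocol:
#' `100 * (1 - |e1 - e2| / ((e1 + e2) / 2))` per structure. Symmetric and
#' scale-invariant; 100 means identical estimates.
#'
#' @param t1,t2 `morph_table`s with matching structure ids (same protocol,
#'   different repeats).
#' @return data frame with columns id, kind, e1, e2, repeatability_pct.
#' @export
repeatability <- function(t1, t2) {
  if (!setequal(t1$id, t2$id) || nrow(t1) != nrow(t2))
    stop("morph tables have mismatched structure sets", call. = FALSE)
  t2 <- t2[match(t1$id, t2$id), ]
  m <- (t1$estimate + t2$estimate) / 2
  rep_pct <- 100 * (1 - abs(t1$estimate - t2$estimate) / m)
  data.frame(id = t1$id, kind = t1$kind, e1 = t1$estimate, e2 = t2$estimate,
             repeatability_pct = rep_pct)
}

#' Between-sequence agreement (squared Pearson correlation)
#'
#' Correlates morphometric estimates across structures between two protocols
#' (e.g. an accelerated acquisition vs the fully sampled reference) and
#' returns R^2, separately per `kind` present in the tables.
#'
#' @param ref_table,cs_table `morph_table`s with >= 3 matched structures.
#' @return data frame with columns kind, n, r2 (`NA` sentinel when either
#'   vector has zero variance or too few complete pairs).
#' @export
between_sequence_r2 <- function(ref_table, cs_table) {
  if (!setequal(ref_table$id, cs_table$id))
    stop("morph tables have mismatched structure sets", call. = FALSE)
  cs_table <- cs_table[match(ref_table$id, cs_table$id), ]
  kinds <- unique(ref_table$kind)
  rows <- lapply(kinds, function(k) {
    a <- ref_table$estimate[ref_table$kind == k]
    b <- cs_table$estimate[cs_table$kind == k]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0)
      return(data.frame(kind = k, n = sum(ok), r2 = NA_real_))
    data.frame(kind = k, n = sum(ok), r2 = cor(a[ok], b[ok])^2)
  })
  do.call(rbind, rows)
}

#' Read a FreeSurfer-style segmentation statistics table
#'
#' Ingests whitespace-delimited `aseg.stats`-like files (comment lines start
#' with `#`) and returns a `morph_table` usable with the agreement
#' operations. Expects the FreeSurfer column layout where column 4 is the
#' structure volume in mm^3 and column 5 the structure name; falls back to a
#' two-column (name, volume) layout.
#'
#' @param path file path.
#' @return a `morph_table` data frame (id, kind = "volume", estimate).
#' @export
read_aseg_stats <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  ncol_min <- min(lengths(fields))
  if (ncol_min >= 5) {
    est <- as.numeric(vapply(fields, `[[`, "", 4))
    id <- vapply(fields, `[[`, "", 5)
  } else if (ncol_min >= 2) {
    id <- vapply(fields, `[[`, "", 1)
    est <- as.numeric(vapply(fields, `[[`, "", 2))
  } else {
    stop("unrecognized stats table layout", call. = FALSE)
  }
  out <- data.frame(id = id, kind = "volume", estimate = est,
                    truth = NA_real_)
  class(out) <- c("morph_table", class(out))
  out
}
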