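#' Write a 3D volume as NIfTI-1
#'
#' @param vol numeric 3D array (or `recon_volume`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size recorded in the header.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_mm = c(1, 1, 1)) {
  v <- if (inherits(vol, "recon_volume")) vol$volume else vol
  img <- RNifti::asNifti(v, pixdim = voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#' @param path file path.
#' @return numeric array with attribute `voxel_mm`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "voxel_mm") <- RNifti::pixdim(img)
  out
}

#' Export a sampling mask (PNG image, CSV point list, JSON sidecar)
#'
#' Writes `<stem>.png` (mask visualization), `<stem>.csv` (two-column ky, kz
#' sample indices in temporal order) and `<stem>.json` (acceleration, density
#' and jitter settings, seed, shot boundaries).
#'
#' @param mask a `sampling_mask`.
#' @param stem output path stem (without extension).
#' @return character vector of the three paths, invisibly.
#' @export
write_mask <- function(mask, stem) {
  p_png <- paste0(stem, ".png")
  p_csv <- paste0(stem, ".csv")
  p_json <- paste0(stem, ".json")
  png::writePNG(t(ifelse(mask$mask, 1, 0))[rev(seq_len(ncol(mask$mask))), ,
                                           drop = FALSE], p_png)
  pts <- do.call(rbind, mask$shots)
  shot_len <- vapply(mask$shots, nrow, 0L)
  write.csv(data.frame(ky = pts[, 1], kz = pts[, 2]), p_csv, row.names = FALSE)
  jsonlite::write_json(list(
    n_ky = mask$shape[1], n_kz = mask$shape[2],
    R_requested = mask$R_requested, R_achieved = mask$R_achieved,
    q = mask$q, jitter_deg = mask$jitter, calib_radius = mask$calib_radius,
    seed = mask$seed, turbo = mask$turbo,
    shot_boundaries = cumsum(shot_len)
  ), p_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p_png, p_csv, p_json))
}

#' Export phantom volumes and the structure table
#'
#' Writes label, intensity and (optionally) bias volumes as NIfTI-1 plus the
#' ground-truth structure table as CSV into a directory.
#'
#' @param phantom an `mr_phantom`.
#' @param dir output directory.
#' @param bias optional bias field to include.
#' @return invisibly, the directory.
#' @export
write_phantom <- function(phantom, dir, bias = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume_nifti(phantom$label_volume * 1.0,
                     file.path(dir, "labels.nii.gz"), phantom$voxel_mm)
  write_volume_nifti(phantom$intensity_volume,
                     file.path(dir, "intensity.nii.gz"), phantom$voxel_mm)
  if (!is.null(bias))
    write_volume_nifti(bias, file.path(dir, "bias.nii.gz"), phantom$voxel_mm)
  st <- phantom$structures
  write.csv(st[, c("structure_id", "name", "cx", "cy", "cz",
                   "vol_vox", "vol_mm3")],
            file.path(dir, "structures.csv"), row.names = FALSE)
  invisible(dir)
}
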