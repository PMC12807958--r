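#' Sweep configuration
#'
#' Describes a full simulated experiment: per session and repeat, one fully
#' sampled reference acquisition plus one CS acquisition per acceleration
#' factor, each CS k-space retro-reconstructed at every regularization value.
#' Defaults are the desk-scale study conditions: 96^3 matrix, accelerations
#' {1, 2, 4, 6, 8}, the console regularization grid
#' {0.0001, 0.0003, 0.0006, 0.0009, 0.0012} with default 0.0003, two repeats
#' in each of two sessions, noise calibrated to a fully sampled white-matter
#' SNR of 60, and 2 receive coils (the desk-scale choice; coil count and SVD
#' compression are configurable).
#'
#' @param shape matrix size (isotropic triple or length-3).
#' @param R_list acceleration factors; 1 denotes the fully sampled reference.
#' @param lambdas regularization factors for retro-reconstruction.
#' @param default_lambda the acquisition-time regularization setting.
#' @param repeats repeats per protocol per session (>= 1).
#' @param sessions number of sessions (>= 1).
#' @param base_seed master seed; all child seeds derive from it.
#' @param snr_wm target fully-sampled white-matter SNR (noise calibration).
#' @param n_coils receive coils in the simulation.
#' @param n_structures subcortical structures in the phantom.
#' @param bias_amplitude relative amplitude of the multiplicative bias field.
#' @param max_iter,tol FISTA settings.
#' @param turbo turbo factor (phase encodes per shot).
#' @param calib_radius fully sampled central disc radius in grid points
#'   (default 6, matching the mask generator's default).
#' @param write_volumes also write reconstructed volumes as NIfTI (default
#'   FALSE; the tidy CSV outputs are always written).
#' @param n_virtual_coils optional SVD coil compression passed to
#'   [cs_recon()] (NULL keeps all physical coils).
#' @return a list of class `sweep_config`.
#' @export
sweep_config <- function(shape = c(96, 96, 96),
                         R_list = c(1, 2, 4, 6, 8),
                         lambdas = c(1e-4, 3e-4, 6e-4, 9e-4, 12e-4),
                         default_lambda = 3e-4,
                         repeats = 2, sessions = 2, base_seed = 1,
                         snr_wm = 60, n_coils = 2, n_structures = 6,
                         bias_amplitude = 0.2, max_iter = 50, tol = 1e-6,
                         turbo = NULL, write_volumes = FALSE,
                         n_virtual_coils = NULL, calib_radius = NULL) {
  if (length(shape) == 1) shape <- rep(shape, 3)
  if (length(R_list) == 0 || length(lambdas) == 0)
    stop_arg("R_list and lambdas must be non-empty")
  if (any(lambdas < 0)) stop_arg("all lambdas must be >= 0")
  if (repeats < 1 || sessions < 1) stop_arg("repeats and sessions must be >= 1")
  structure(list(shape = as.integer(shape), R_list = R_list, lambdas = lambdas,
                 default_lambda = default_lambda, repeats = as.integer(repeats),
                 sessions = as.integer(sessions), base_seed = as.integer(base_seed),
                 snr_wm = snr_wm, n_coils = as.integer(n_coils),
                 n_structures = as.integer(n_structures),
                 bias_amplitude = bias_amplitude, max_iter = as.integer(max_iter),
                 tol = tol, turbo = turbo %||% as.integer(shape[3]),
                 write_volumes = isTRUE(write_volumes),
                 n_virtual_coils = n_virtual_coils,
                 calib_radius = calib_radius %||% 6L),
            class = "sweep_config")
}

#' Run the full acquisition/reconstruction/evaluation sweep
#'
#' For every (session, repeat): simulates the fully sampled reference and, per
#' acceleration factor, a freshly jittered CS acquisition with fresh noise;
#' retro-reconstructs each CS k-space at every regularization value;
#' computes tissue SNR, FWHM smoothness, SSIM against the session-matched
#' reference and against the lowest-regularization reconstruction of the same
#' k-space, adjacent-regularization absolute-difference summaries, and
#' morphometric estimates. Deterministic for a fixed `base_seed`: child seeds
#' are derived per (session, repeat, protocol, role) so adding protocols never
#' perturbs existing ones. The intensity bias field is divided out of every
#' reconstruction before metrics, emulating scanner pre-normalization with a
#' known field.
#'
#' @param config a [sweep_config()].
#' @param out_dir output directory for `qc.csv`, `ssim.csv`, `morph.csv`,
#'   `agreement.csv` and `summary.json` (created if missing). NULL skips
#'   writing.
#' @param verbose print progress lines.
#' @return invisibly, a list with data frames `qc`, `ssim`, `morph`,
#'   `agreement`, the `config`, and `paths`.
#' @export
run_sweep <- function(config, out_dir = NULL, verbose = FALSE) {
  cf <- config
  phantom <- make_phantom(cf$shape, n_structures = cf$n_structures,
                          seed = derive_seed(cf$base_seed, 0, 0, 0, 1))
  coils <- make_coils(cf$shape, n_coils = cf$n_coils,
                      seed = derive_seed(cf$base_seed, 0, 0, 0, 2))
  bias <- make_bias_field(cf$shape, amplitude = cf$bias_amplitude,
                          seed = derive_seed(cf$base_seed, 0, 0, 0, 3),
                          brain_mask = phantom$brain_mask)
  noise_sd <- noise_sd_for_snr(phantom, cf$snr_wm)
  nyz <- cf$shape[2:3]

  qc_rows <- list(); ssim_rows <- list(); morph_rows <- list()
  refs <- list()  # reference volumes per session_repeat
  vol_dir <- NULL
  if (cf$write_volumes && !is.null(out_dir)) {
    vol_dir <- file.path(out_dir, "volumes")
    dir.create(vol_dir, recursive = TRUE, showWarnings = FALSE)
  }
  maybe_write <- function(vol, id) {
    if (!is.null(vol_dir))
      write_volume_nifti(vol, file.path(vol_dir, paste0(id, ".nii.gz")),
                         phantom$voxel_mm)
  }

  eval_image <- function(vol_corr, id, session, rep, Rv, lambda, nseed, jseed) {
    seg <- segment_tissues_basic(vol_corr, phantom$brain_mask)
    # smoothness estimated within the segmented WM mask: the phantom's flat
    # tissue interior satisfies the estimator's stationary-field assumption,
    # which the sharp synthetic edges in a whole-brain mask do not
    fw <- smoothness_fwhm(vol_corr, seg$wm, phantom$voxel_mm)
    qc <- data.frame(id = id, session = session, rep = rep, R = Rv,
                     lambda = lambda, noise_seed = nseed, jitter_seed = jseed,
                     snr_gm = tissue_snr(vol_corr, seg$gm),
                     snr_wm = tissue_snr(vol_corr, seg$wm),
                     fwhm_x = fw$fwhm_vox[["x"]], fwhm_y = fw$fwhm_vox[["y"]],
                     fwhm_z = fw$fwhm_vox[["z"]],
                     fwhm_vox = fw$fwhm_vox[["combined"]],
                     fwhm_mm = fw$fwhm_mm[["combined"]])
    mv <- estimate_volumes(vol_corr, phantom)
    mt <- estimate_thickness(vol_corr, phantom, seg = seg)
    morph <- rbind(mv, mt)
    morph$image_id <- id; morph$session <- session; morph$rep <- rep
    morph$R <- Rv; morph$lambda <- lambda
    list(qc = qc, morph = morph, seg = seg)
  }

  for (ses in seq_len(cf$sessions)) {
    for (rp in seq_len(cf$repeats)) {
      # ---- fully sampled reference ----
      nseed <- derive_seed(cf$base_seed, ses, rp, 0, 10)
      pars <- acq_params(matrix = cf$shape, noise_sd = noise_sd, seed = nseed,
                        turbo_factor = cf$turbo)
      ks <- simulate_kspace(phantom, coils, bias, pars)
      ref <- zero_filled_recon(ks, coils)
      ref_corr <- ref$volume / bias
      refs[[sprintf("s%d_r%d", ses, rp)]] <- ref_corr
      id <- sprintf("s%d_r%d_R1", ses, rp)
      ev <- eval_image(ref_corr, id, ses, rp, 1, 0, nseed, NA_integer_)
      qc_rows[[id]] <- ev$qc; morph_rows[[id]] <- ev$morph
      maybe_write(ref_corr, id)
      rm(ks)
      if (verbose) message("done ", id)

      # ---- CS protocols ----
      for (Rv in setdiff(cf$R_list, 1)) {
        jseed <- derive_seed(cf$base_seed, ses, rp, round(Rv * 10), 20)
        nseed <- derive_seed(cf$base_seed, ses, rp, round(Rv * 10), 30)
        msk <- phyllotaxis_mask(nyz[1], nyz[2], Rv, turbo = cf$turbo,
                                calib_radius = cf$calib_radius, seed = jseed)
        pars <- acq_params(matrix = cf$shape, noise_sd = noise_sd,
                          seed = nseed, turbo_factor = cf$turbo)
        ks <- simulate_kspace(phantom, coils, bias, pars, mask = msk)
        kchk <- sum(Mod(ks$data[[1]])^2)  # retro-recon provenance checksum
        recs <- retro_reconstruct(ks, msk, coils, cf$lambdas,
                                  max_iter = cf$max_iter, tol = cf$tol,
                                  n_virtual_coils = cf$n_virtual_coils)
        rm(ks)
        base_lam <- min(cf$lambdas)
        base_corr <- recs[[as.character(base_lam)]]$volume / bias
        prev_corr <- NULL; prev_lam <- NA_real_
        for (lam in cf$lambdas) {
          rv <- recs[[as.character(lam)]]
          vol_corr <- rv$volume / bias
          id <- sprintf("s%d_r%d_R%g_l%g", ses, rp, Rv, lam)
          ev <- eval_image(vol_corr, id, ses, rp, Rv, lam, nseed, jseed)
          qc_rows[[id]] <- ev$qc; morph_rows[[id]] <- ev$morph
          maybe_write(vol_corr, id)
          ref_corr <- refs[[sprintf("s%d_r%d", ses, rp)]]
          # SSIM averaged over the brain mask: the phantom's empty background
          # otherwise dominates (and distorts) the volume-wide mean
          s_ref <- ssim3d(ref_corr, vol_corr,
                          mask = phantom$brain_mask)$mean_ssim
          s_base <- ssim3d(base_corr, vol_corr,
                           mask = phantom$brain_mask)$mean_ssim
          mad_prev <- if (is.null(prev_corr)) NA_real_ else
            mean(abs_difference(prev_corr, vol_corr)[phantom$brain_mask])
          ssim_rows[[id]] <- data.frame(
            id = id, session = ses, rep = rp, R = Rv, lambda = lam,
            kspace_checksum = kchk,
            ssim_vs_ref = s_ref, ssim_vs_lambda_base = s_base,
            lambda_prev = prev_lam, mean_absdiff_prev = mad_prev)
          prev_corr <- vol_corr; prev_lam <- lam
          if (verbose) message("done ", id)
        }
        rm(recs)
      }
    }
  }

  qc <- do.call(rbind, qc_rows); rownames(qc) <- NULL
  ssim <- do.call(rbind, ssim_rows)
  if (is.null(ssim)) {  # reference-only sweeps have no CS comparisons
    ssim <- data.frame(id = character(0), session = integer(0),
                       rep = integer(0), R = numeric(0), lambda = numeric(0),
                       kspace_checksum = numeric(0), ssim_vs_ref = numeric(0),
                       ssim_vs_lambda_base = numeric(0),
                       lambda_prev = numeric(0), mean_absdiff_prev = numeric(0))
  }
  rownames(ssim) <- NULL
  morph <- do.call(rbind, morph_rows); rownames(morph) <- NULL
  agreement <- compute_agreement(morph, cf)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, c("qc.csv", "ssim.csv", "morph.csv",
                                  "agreement.csv", "summary.json"))
    write.csv(qc, paths[1], row.names = FALSE)
    write.csv(ssim, paths[2], row.names = FALSE)
    write.csv(morph, paths[3], row.names = FALSE)
    write.csv(agreement, paths[4], row.names = FALSE)
    summ <- list(config = unclass(cf), n_images = nrow(qc),
                 noise_sd = noise_sd,
                 phantom = list(n_structures = nrow(phantom$structures),
                                shape = phantom$shape))
    jsonlite::write_json(summ, paths[5], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(qc = qc, ssim = ssim, morph = morph, agreement = agreement,
                 config = cf, paths = paths, phantom = phantom))
}

# Repeatability (within session, same protocol, repeat pairs) and
# between-sequence R^2 (CS vs reference, matched repeat within session).
compute_agreement <- function(morph, cf) {
  rep_rows <- list(); r2_rows <- list()
  dlam <- cf$default_lambda
  sel_lambda <- function(d, Rv) {
    if (Rv == 1) d[d$R == 1, ] else d[d$R == Rv & d$lambda == dlam, ]
  }
  for (Rv in cf$R_list) {
    for (ses in seq_len(cf$sessions)) {
      d <- sel_lambda(morph[morph$session == ses, ], Rv)
      reps <- sort(unique(d$rep))
      if (length(reps) >= 2) {
        prs <- utils::combn(reps, 2)
        for (j in seq_len(ncol(prs))) {
          t1 <- d[d$rep == prs[1, j], c("id", "kind", "estimate")]
          t2 <- d[d$rep == prs[2, j], c("id", "kind", "estimate")]
          t1$id <- paste(t1$id, t1$kind); t2$id <- paste(t2$id, t2$kind)
          rr <- repeatability(t1, t2)
          rr$R <- Rv; rr$session <- ses
          rr$pair <- sprintf("%d-%d", prs[1, j], prs[2, j])
          rep_rows[[length(rep_rows) + 1]] <- rr
        }
      }
      # between-sequence: CS repeat r vs reference repeat r
      if (Rv != 1) {
        dref <- sel_lambda(morph[morph$session == ses, ], 1)
        for (r in intersect(unique(d$rep), unique(dref$rep))) {
          ta <- dref[dref$rep == r, c("id", "kind", "estimate")]
          tb <- d[d$rep == r, c("id", "kind", "estimate")]
          r2 <- between_sequence_r2(ta, tb)
          r2$R <- Rv; r2$session <- ses; r2$rep <- r
          r2_rows[[length(r2_rows) + 1]] <- r2
        }
      }
    }
  }
  rep_df <- if (length(rep_rows)) do.call(rbind, rep_rows) else NULL
  r2_df <- if (length(r2_rows)) do.call(rbind, r2_rows) else NULL
  if (!is.null(rep_df)) {
    rep_df$metric <- "repeatability_pct"
    rep_df$value <- rep_df$repeatability_pct
  }
  out <- rbind(
    if (!is.null(rep_df))
      data.frame(metric = "repeatability_pct", id = rep_df$id,
                 kind = rep_df$kind, R = rep_df$R, session = rep_df$session,
                 pairing = rep_df$pair, value = rep_df$repeatability_pct),
    if (!is.null(r2_df))
      data.frame(metric = "between_seq_r2", id = "all_structures",
                 kind = r2_df$kind, R = r2_df$R, session = r2_df$session,
                 pairing = as.character(r2_df$rep), value = r2_df$r2)
  )
  rownames(out) <- NULL
  out
}

#' Summarize acceleration and regularization trends from a sweep
#'
#' Produces the trend tables of the analysis: mean +/- SE of SSIM against the
#' fully sampled reference per acceleration factor; mean SSIM against the
#' lowest-regularization reconstruction per (R, lambda); tissue SNR and FWHM
#' smoothness by (R, lambda); and the repeatability / between-sequence R^2
#' summaries.
#'
#' @param sweep the list returned by [run_sweep()], or a directory containing
#'   its CSV outputs.
#' @return list of data frames `ssim_vs_R`, `ssim_vs_lambda`, `qc_trends`,
#'   `repeatability`, `between_r2`.
#' @export
summarize_trends <- function(sweep) {
  if (is.character(sweep)) {
    sweep <- list(qc = read.csv(file.path(sweep, "qc.csv")),
                  ssim = read.csv(file.path(sweep, "ssim.csv")),
                  morph = read.csv(file.path(sweep, "morph.csv")),
                  agreement = read.csv(file.path(sweep, "agreement.csv")))
  }
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  agg <- function(d, by, val) {
    f <- lapply(by, function(b) d[[b]])
    names(f) <- by
    out <- stats::aggregate(d[[val]], f, mean)
    names(out)[ncol(out)] <- "mean"
    out$se <- stats::aggregate(d[[val]], f, se)$x
    out$n <- stats::aggregate(d[[val]], f, length)$x
    rownames(out) <- NULL
    out[do.call(order, out[by]), ]
  }
  ssim <- sweep$ssim
  qc <- sweep$qc
  ag <- sweep$agreement
  # table-1 analogue: CS-vs-reference SSIM at the default (acquisition) lambda
  if (nrow(ssim) > 0) {
    dlam <- if (!is.null(sweep$config)) sweep$config$default_lambda else
      sort(unique(ssim$lambda))[2]
    t1 <- agg(ssim[ssim$lambda == dlam, ], "R", "ssim_vs_ref")
    t2 <- agg(ssim, c("R", "lambda"), "ssim_vs_lambda_base")
  } else {
    t1 <- t2 <- NULL   # reference-only sweeps have no CS comparisons
  }
  qc_tr <- agg(qc, c("R", "lambda"), "snr_wm")
  qc_tr$mean_snr_gm <- agg(qc, c("R", "lambda"), "snr_gm")$mean
  qc_tr$mean_fwhm_vox <- agg(qc, c("R", "lambda"), "fwhm_vox")$mean
  names(qc_tr)[names(qc_tr) == "mean"] <- "mean_snr_wm"
  rep_t <- ag[ag$metric == "repeatability_pct", ]
  r2_t <- ag[ag$metric == "between_seq_r2", ]
  list(ssim_vs_R = t1, ssim_vs_lambda = t2, qc_trends = qc_tr,
       repeatability = rep_t, between_r2 = r2_t)
}
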