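#!/usr/bin/env Rscript
# Image-quality trends from the sweep: white-matter/gray-matter SNR and FWHM
# smoothness against acceleration and regularization, SSIM against the fully
# sampled reference, and SSIM/absolute-difference against the
# lowest-regularization reconstruction. Requires 03_reconstruction_sweep.R.
# Outputs under results/04_trends/.

library(csmprage)

stopifnot(file.exists("results/03_sweep/qc.csv"))
out <- "results/04_trends"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tr <- summarize_trends("results/03_sweep")
write.csv(tr$ssim_vs_R, file.path(out, "ssim_vs_acceleration.csv"),
          row.names = FALSE)
write.csv(tr$ssim_vs_lambda, file.path(out, "ssim_vs_regularization.csv"),
          row.names = FALSE)
write.csv(tr$qc_trends, file.path(out, "snr_fwhm_trends.csv"),
          row.names = FALSE)

cat("SSIM vs fully sampled reference (acquisition regularization):\n")
print(tr$ssim_vs_R, digits = 4)
cat("\nWM SNR / FWHM by (R, lambda):\n")
print(tr$qc_trends, digits = 3)

dlam_rows <- tr$qc_trends$lambda %in% c(0, 3e-4)
snr <- tr$qc_trends$mean_snr_wm[dlam_rows]
cat(sprintf("\nWM SNR non-increasing in R at the default setting: %s\n",
            all(diff(snr[order(tr$qc_trends$R[dlam_rows])]) <= 0)))
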