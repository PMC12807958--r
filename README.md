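# csmprage

Simulation and evaluation of compressed-sensing (CS) accelerated MPRAGE-style
brain MRI, built for studying how the acceleration factor R and the
reconstruction regularization λ affect image quality and morphometric
measurements — entirely on synthetic data with known ground truth.

Accelerated 3D T1-weighted imaging acquires a fraction 1/R of the Cartesian
phase-encode plane with an incoherent, jittered variable-density
spiral-phyllotaxis pattern, and reconstructs each readout slice by minimizing

    f(x) = ½ Σ_c ‖ M ∘ F(S_c x) − y_c ‖₂² + λ ‖ Ψ x ‖₁

(M: sampling mask, F: 2D unitary DFT, S_c: complex coil sensitivities, Ψ:
orthogonal Daubechies-4 wavelet transform) with FISTA. The package provides:

* a digital brain phantom (CSF / cortical ribbon / white matter /
  subcortical nuclei) whose structure volumes and regional ribbon
  thicknesses are known exactly;
* multi-coil k-space simulation with complex Gaussian noise and a known
  multiplicative bias field;
* phyllotaxis sampling masks with turbo-factor shot structure, PSF
  incoherence diagnostics and scan-time estimates;
* the wavelet-regularized solver with retro-reconstruction at multiple λ
  from the identical k-space;
* the evaluation battery: tissue SNR, FWHM smoothness, volumetric SSIM,
  absolute-difference maps, structure volumes, ribbon thickness,
  test-retest repeatability and between-protocol Pearson R²;
* `run_sweep()` / `summarize_trends()`, which execute the whole experiment
  (sessions × repeats × R × λ) deterministically from one base seed.

The numbered scripts under `analysis/` run the study end to end and write
tidy tables under `results/`.

## Worked example

```r
library(csmprage)

ph   <- make_phantom(c(64, 64, 64), n_structures = 4, seed = 1)
co   <- make_coils(c(64, 64, 64), n_coils = 4, seed = 2)
pars <- acq_params(matrix = c(64, 64, 64),
                   noise_sd = noise_sd_for_snr(ph, 60), seed = 3)

mask <- phyllotaxis_mask(64, 64, R = 4, turbo = 64, seed = 7)
mask
#> <sampling_mask> 64x64, R requested 4 achieved 3.98, 13 shots, seed 7

ks  <- simulate_kspace(ph, co, bias = NULL, pars, mask = mask)
rec <- cs_recon(ks, mask, co, lambda = 3e-4)   # console-scale lambda
seg <- segment_tissues_basic(rec$volume, ph$brain_mask)
round(c(snr_wm = tissue_snr(rec, seg$wm),
        fwhm   = smoothness_fwhm(rec, seg$wm)$fwhm_vox[["combined"]],
        ssim   = ssim3d(rec$volume, ph$intensity_volume,
                        mask = ph$brain_mask)$mean_ssim), 3)
#> snr_wm   fwhm   ssim
#> 16.347  1.238  0.788

vols <- estimate_volumes(rec, ph)
round(100 * vols$estimate / vols$truth, 1)    # % of ground-truth volume
#> [1] 78.3 79.8 76.0 82.8
```

`snr_wm` is the white-matter mean/sd ratio: the fully sampled reference hits
the calibration target (60), and under-sampling at R = 4 with the default
console regularization brings it down to ~16 as residual aliasing
pseudo-noise accumulates. `fwhm` is the smoothness of the white-matter
interior in voxels (≈1 means noise-limited sharpness, larger means
blurrier), `ssim` the structural similarity to the noise-free phantom over
the brain. The volume ratios show the morphometry proxy's consistent
under-segmentation of blurred nuclei at R = 4 — the agreement statistics
(`repeatability`, `between_sequence_r2`) are exactly the tools that separate
such a stable bias from unreliable estimates.

The full experiment:

```r
res <- run_sweep(sweep_config(base_seed = 1), out_dir = "results/03_sweep")
summarize_trends(res)
```

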