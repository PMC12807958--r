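---
title: "Simulating and evaluating compressed-sensing MPRAGE acquisitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating compressed-sensing MPRAGE acquisitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmprage)
```

## What the package models

Accelerated 3D T1-weighted (MPRAGE-style) brain imaging acquires one readout
line per phase-encode point on a Cartesian (ky, kz) grid. Compressed sensing
(CS) shortens the scan by acquiring only a fraction 1/R of those points with
an *incoherent* pattern and reconstructing by wavelet-regularized iterative
optimization. The choice of the acceleration factor R and of the
regularization weight λ trades scan time against noise, and noise against
smoothing — and ultimately determines whether morphometric measurements
(structure volumes, cortical thickness) derived from the images remain
reliable.

Real scanner data for such a study are rarely shareable. This package instead
builds the entire experiment as a simulation with known ground truth:

1. **Digital phantom** (`make_phantom`): a brain-like volume with CSF, a
   cortical gray-matter ribbon between two star-shaped surfaces, white
   matter, and ellipsoidal subcortical nuclei of intermediate intensity.
   Every structure's volume and every ribbon region's thickness are known by
   construction.
2. **Acquisition** (`make_coils`, `make_bias_field`, `simulate_kspace`):
   multi-coil complex k-space with additive circular complex Gaussian noise
   and a smooth multiplicative intensity bias.
3. **Under-sampling** (`phyllotaxis_mask`): a jittered variable-density
   spiral-phyllotaxis pattern on the phase-encode plane, organized into
   turbo-factor shots.
4. **Reconstruction** (`cs_recon`): readout-direction FFT decouples the 3D
   problem into 2D slice problems, each solved by FISTA on
   ½ Σ_c ‖M∘F(S_c x) − y_c‖² + λ‖Ψx‖₁.
5. **Evaluation** (`tissue_snr`, `smoothness_fwhm`, `ssim3d`,
   `estimate_volumes`, `estimate_thickness`, `repeatability`,
   `between_sequence_r2`): image-quality metrics and agreement statistics
   against the phantom's ground truth.

`run_sweep` orchestrates the full study: per session and repeat, a fully
sampled reference plus one freshly jittered CS acquisition per R, each
retro-reconstructed at every λ from the identical k-space.

## Contrast model and noise calibration

No Bloch simulation is attempted: sequence timing (TR/TI/TE) is carried as
protocol metadata, and T1w contrast is modeled by fixed nominal tissue means
(WM 1.00, subcortical 0.80, GM 0.65, CSF 0.15). The contrast *ordering*, not
the signal equation, drives segmentation, SNR and morphometry, which is what
the downstream analyses measure. Consequences: the phantom's tissue classes
are internally homogeneous, so within-mask standard deviation is almost pure
noise/artifact, whereas real tissue adds anatomical texture; measured SNR
values here are therefore cleaner than scanner values at the same noise
level.

Coil sensitivities are smooth complex Gaussian profiles on a ring,
normalized so the root-sum-of-squares is exactly 1 everywhere. With the
package's DFT convention (unnormalized forward, 1/N inverse), k-space noise
of standard deviation σ per component then yields image noise σ/√N after
coil combination, so `noise_sd_for_snr` can set σ to hit a target
white-matter SNR of the fully sampled reconstruction exactly. The default
target is 60. That is deliberately higher than SNR readings on real scans
(typically 15–25 by this within-mask definition), because real readings are
dominated by anatomical texture that this phantom does not have: with pure
thermal noise at a scanner-like reading level, thermal noise (which *falls*
with under-sampling, as fewer noisy samples are acquired) would swamp the
aliasing pseudo-noise that actually drives image-quality differences across
acceleration factors. At target 60 the simulation sits in the same
artifact-limited regime as the emulated study, and white-matter SNR declines
monotonically with acceleration as observed there.

The ±20% multiplicative bias field stands in for B1-related intensity
non-uniformity. Because the simulated field is known, it is divided out of
every reconstruction before metrics — emulating a scanner's pre-scan
normalization, which the emulated protocol treats as solved upstream.

## The sampling pattern

Candidate points are placed on a golden-angle spiral (angle increment
137.50776°, uniform angular jitter ±20°) with radius `(m/M)^q`; the default
density exponent q = 0.7 concentrates samples at the k-space center. Points
snap to the nearest unsampled grid point of the inscribed elliptical
footprint, and a fully sampled calibration disc (default radius 6 grid
points) is added. A two-pass count adjustment holds the achieved
acceleration within 5% of the request without discarding outer k-space
samples.
Samples are chunked into turbo-factor shots; each shot is reordered
symmetrically so its minimum-radius sample sits at its temporal midpoint,
mirroring center-of-k-space-at-center-of-shot acquisition timing. Shot
ordering is bookkeeping only — no signal evolution along the echo train is
simulated, so the ordering affects the scan-time estimate and nothing else.

The scan-time estimate is `n_shots × TR`; it excludes vendor preparation
and dummy shots, and printed protocol times in the emulated protocol family
differ from it by roughly one TR (e.g. 552 s estimated vs 9:14 printed for
the fully sampled 240×192 reference).

## Reconstruction: solver and the λ scale

Each readout slice is solved independently by FISTA with a fixed step 1/L,
where L is estimated by power iteration on the mid-slice normal operator
(with RSS-normalized coils L ≤ 1 analytically; the estimate is inflated by
2% for safety). The prox is complex soft-thresholding of an orthogonal
periodic Daubechies-4 (8-tap) tensor-wavelet transform, 4 decomposition
levels. A slice stops at `max_iter` (default 50) or when its relative
objective change drops below `tol` (default 1e-6). The data are normalized
to unit maximum (of the zero-filled reconstruction) before solving.

Scanner consoles quote the regularization as a small dimensionless number
(the emulated protocol family uses 0.0001–0.0012 with 0.0003 recommended).
That scale is meaningful only relative to the console's internal
normalization, which is not public. The package fixes the correspondence
once: a fixed console value λ maps to the effective l1 weight

    λ_eff = λ · 25 · f²,   f = sampled fraction of the nominal support,

on the unit-max, unitary-DFT cost. The decreasing dependence on f makes a
fixed console setting *relatively weaker* at higher acceleration —
reproducing the observed behaviour of such protocols, where images acquired
at higher R with the same console setting come out grainier (declining
white-matter SNR), and where raising the console value restores SNR toward
the fully sampled level. The constants were calibrated once so that the
recommended console value 0.0003 sits at a sensible operating point
(white-matter SNR just below the fully sampled reference at R = 2, visibly
noisy images at R = 8); they are properties of this simulation's
normalization, not tunable analysis knobs. One observable consequence: a
fixed console *step* (say 0.0003 to 0.0006) is a smaller effective step at
higher acceleration, so retro-reconstructions at neighbouring console
settings differ *less*, not more, at high R in this simulation — the
opposite of systems whose effective weight does not shrink with sampling.
`lambda_scale = "absolute"` bypasses the mapping for solver-level
experiments.

Two further solver notes. First, with a center-dense variable-density
pattern the zero-filled reconstruction is a surprisingly strong baseline in
RMSE terms — it is effectively a soft low-pass filter, and RMSE rewards
blur. The iterative reconstruction beats it in RMSE when the l1 weight is
pushed toward the RMSE-optimal (strongly smoothing) end of its range, while
at the console default it deliberately trades RMSE for resolution and
noise realism; both regimes are exercised in the tests. Second, an SVD
coil-compression option
(`n_virtual_coils`) rotates the coil dimension into its principal
components; keeping all channels is exact, and dropping the weakest
channels trades a small energy loss for proportionally faster iterations.

## Metrics

* **Tissue SNR** — mean over a tissue mask divided by the standard deviation
  over the mask (n−1 denominator). Masks come from a deterministic 3-class
  1D k-means on brain-mask intensities (centroids initialized at the
  10th/50th/90th percentiles), applied to the image under test, so
  segmentation imperfection is part of the metric.
* **FWHM smoothness** — the sweep reports smoothness within the segmented
  white-matter mask: the estimator below assumes a stationary random field,
  which holds inside the phantom's flat tissue interior but not across its
  sharp synthetic edges (a whole-brain estimate is dominated by edge
  content and saturates under heavy under-sampling blur). The estimator is
  the classical first-difference form: per axis,
  ρ = 1 − d/(2v) from the variance v of intensities and variance d of
  within-mask first differences, FWHM = √(−2 ln 2 / ln ρ) voxels; the
  combined value is the geometric mean, reported in voxels and mm. Data
  rougher than white noise (ρ ≤ 0) produce an `NA` sentinel; note that for
  exactly white noise the estimator is unstable by construction (ρ
  fluctuates around 0), which is why tests characterize it on *smoothed*
  noise where the Gaussian autocorrelation model holds.
* **SSIM** — local Gaussian-window (σ = 1.5 voxels, radius 4) means,
  variances and covariance combined in the standard two-term form with
  K1 = 0.01, K2 = 0.03 and the dynamic range taken over both volumes; edge
  windows are renormalized by the smoothed all-ones volume. Volumes share a
  grid by construction, so no registration is applied. The sweep averages
  the SSIM map over the brain mask: unlike real scans, the synthetic
  background is exactly empty, and including it dilutes the mean towards
  the (uninformative) background similarity.
* **Absolute difference maps** between reconstructions of the identical
  k-space at adjacent λ settings quantify what the regularization changes.

## Morphometry proxy

Full surface-based morphometry pipelines cannot run on a desk-scale phantom,
and re-implementing one is out of scope. The proxy uses the phantom's ground
truth as the seed but measures the *image*: structure volumes by
6-connected region growing from the known center over an intensity band
(half-width 0.5 × the structure-to-WM contrast, capped at 3× the true
volume — flooding to the cap yields the missing-structure sentinel, which is
exactly what happens when over-regularization erases the nucleus-WM
contrast); ribbon thickness per angular octant as the mean over
gray-matter ribbon voxels of distance-to-WM plus distance-to-outside minus
one voxel (exact on flat geometry), with Euclidean distance transforms and a
10 mm ribbon depth cutoff that excludes deep gray matter. The agreement
statistics are percent test-retest agreement, 100×(1 − |Δ|/mean) — chosen as
the simplest symmetric, scale-invariant definition, stated here because the
emulated analyses report repeatability percentages without printing a
formula — and squared Pearson correlation across structures between
protocols.

## Study conditions and problem sizes

The default `sweep_config` is the desk-scale study: 96³ matrix at 1 mm,
R ∈ {1, 2, 4, 6, 8}, λ ∈ {0.0001, 0.0003, 0.0006, 0.0009, 0.0012} with
0.0003 as the acquisition-time setting, 2 repeats × 2 sessions (84
reconstructions), 6 subcortical structures, 2 receive coils, fully sampled
WM SNR target 60. Each repeat draws fresh
noise and jitter seeds derived deterministically from the base seed, so
within-session repeats differ exactly as repeated scans would. Full
protocol scale (256×240×192, 4 repeats, 32 channels) is one configuration
change away but is not the tested default. Tests exercise smaller grids
(32–64³) except for the study-condition checks, which run the default sweep
once.

## Numerical choices and degenerate inputs

* DFT: unnormalized forward / (1/N) inverse everywhere outside the solver
  (Parseval: Σ|k|² = N Σ|x|²); unitary 2D transforms inside the solver.
* Sampling masks are defined with DC at the grid center and inverse-shifted
  to the DFT's corner-DC convention when applied.
* k-means ties in segmentation are broken by deterministic centroid nudges;
  fewer than 3 distinct intensities is an error.
* Zero-variance masks, singleton masks, empty masks, R < 1, negative λ or
  τ, mismatched shapes and infeasible accelerations raise immediate errors;
  infinite SNR and rougher-than-noise FWHM return explicit sentinels.
* All generators are pure functions of their seeds; `derive_seed` mixes
  integer tags so adding protocols to a sweep never perturbs existing seeds.

## Known limitations

* No skull/scalp, motion, or susceptibility effects; no signal evolution
  along the echo train; no Rician-bias correction (at SNR ≥ 18 the bias is
  under 1%).
* The phantom's piecewise-constant tissues make SNR and SSIM cleaner than
  in vivo; passing trends here demonstrate the pipeline's internal
  consistency, not scanner-grade image quality.
* The console-λ correspondence is this package's calibration; absolute λ
  values should not be compared against other reconstruction software.
* The morphometry proxy is seeded by ground truth and cannot drift the way
  registration-based pipelines can; its agreement numbers are accordingly
  optimistic relative to full morphometry suites.
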