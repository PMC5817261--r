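---
title: "Detecting myeloma bone lesions on simulated PET/CT: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting myeloma bone lesions on simulated PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiple myeloma seeds dozens of focal lesions throughout the skeleton.
On hybrid PET/CT with a CXCR4-targeted tracer the lesions appear as
skeletal hot spots with an accompanying (usually lytic) CT change, but
reading a whole-body volume lesion by lesion is slow and error-prone.
`petlesion` packages a complete, self-contained testbed for automated
voxelwise lesion segmentation and lesionwise detection: because no public
cohort of this kind exists, the package generates its own ground truth
with a digital phantom and a physics-based PET measurement simulator, and
then trains and evaluates volumetric neural networks and classical
voxel classifiers on those phantoms.

## The phantom generator

`build_anatomy()` composes a stylized torso from geometric primitives:
an elliptical soft-tissue body, two lungs, liver, spleen and kidneys, and
a connected skeleton (femora, pelvic ring, vertebrally modulated spine,
rib-cage shell, sternum, erector column, shoulder girdle, humeri). The
anatomy is defined in coordinates normalised to the grid extent, so any
grid from desk-scale (a few dozen voxels per axis) upward produces the
same body plan. CT values are drawn per tissue class (soft tissue
~40 HU, lung ~-700 HU, bone ~700 +/- 60 HU); activity is a per-class
baseline (marrow background 1.5 in arbitrary units) times mild smooth
multiplicative noise. Everything is a pure function of `(grid, seed,
config)`.

`sample_lesions()` draws a uniform number of lesions per phantom
(default 5-40 for a whole-body grid), centres them uniformly over
skeleton voxels, and draws ellipsoid semi-axes from 6-24 mm, an uptake
multiplier from 2-10x marrow background, and a CT change from -400 to
+200 HU. Shapes are deformed by a smooth direction-dependent radial
perturbation of up to 30% of the semi-axis. `apply_lesions()` relabels
the voxels, multiplies their activity by the uptake (at most once --
overlapping lesions merge), and shifts CT by `ct_delta * severity` with
`severity = uptake / 10`, coupling metabolic avidity to structural
damage. Lesion masks are clipped to the (1-voxel-dilated) skeleton.

Defaults worth knowing, with the reasoning behind the two that were
revised during development:

* **Lesion semi-axes 6-24 mm.** Focal myeloma lesions of 1-5 cm
  diameter are typical of symptomatic disease. Equally important, at the
  grids this package is meant to run on, smaller lesions subtend so few
  voxels that a pooled Dice score measures boundary discretisation
  rather than detection: with a median lesion radius of ~2.4 voxels a
  systematic one-voxel halo alone caps Dice near 40. The default keeps
  the simulated task in the resolution regime where voxelwise Dice is
  meaningful.
* **Bone CT noise sd 60 HU.** A digital phantom assigns smooth values
  per tissue class; a larger spread (an early draft used 150 HU) buries
  every lesion's severity-scaled CT change and contradicts the premise
  that lesion severity is visible on CT at all.
* Uptake and CT-delta ranges, the lesion-count range, and the 30%
  deformation cap are free parameters of the generator; all are in
  `phantom_config()`.

What the generator does **not** emulate: realistic organ shapes,
respiratory or cardiac motion, extramedullary disease, marrow
heterogeneity, or inter-patient anatomical variability (the body plan is
fixed; only noise, lesions and their parameters vary). Results on these
phantoms therefore demonstrate that the pipeline can learn and be scored
end-to-end -- they do not certify clinical performance.

## The PET measurement simulator

`simulate_study()` chains:

1. **Attenuation map**: a bilinear HU-to-mu mapping anchored at water
   (0.0096/mm at 511 keV), falling to zero at air and rising with a
   shallower slope (5.1e-6 per HU per mm) above 0 HU.
2. **Resolution**: an isotropic Gaussian PSF (default FWHM 4 mm) applied
   in the image domain before projection, standing in for positron range
   (Ga-68 has a long one) plus detector blur.
3. **Forward projection**: per-slice parallel-beam line integrals on a
   90-radial-bin x 160-angle sinogram. The projector is a sparse matrix
   assembled from bilinear line samples, so its transpose is the exact
   adjoint -- the dot-product test holds to machine precision, which in
   turn makes the MLEM convergence guarantee hold in practice.
   Attenuation multiplies each line of response by `exp(-integral of
   mu)`, which is exact for PET.
4. **Scatter and randoms**: scatter is modelled analytically as the
   trues sinogram convolved with a wide radial Gaussian (default FWHM
   80 mm) and scaled to 30% of the total count budget; randoms are
   spatially uniform at another 30%. The composed expectation sums to
   the configured total (default 1e6 counts) exactly.
5. **Poisson noise** per bin, then **MLEM** reconstruction (default 20
   iterations, no post-filter) with the known scatter+randoms mean as an
   additive background in the forward model. The reconstruction models
   the acquisition PSF inside its projector (resolution recovery) using
   an exactly self-adjoint separable Gaussian, which substantially
   improves the recovered contrast of small lesions at these count
   levels. Iterates stay nonnegative and the Poisson log-likelihood is
   non-decreasing; a two-voxel toy system reproduces the brute-force
   maximum-likelihood solution.

A full-scanner Monte-Carlo scatter simulation and cylindrical scanner
geometry are deliberately out of scope; only the count budget, the
sinogram dimensions, the scatter/randoms fractions and the noise model
are treated as fixed study conditions.

## Segmentation networks

`build_vnet()` constructs an encoder-decoder volumetric network:
3x3x3 same-padded convolutions, stride-2 downsampling convolutions,
stride-2 transposed convolutions for decompression, skip concatenations
from each compression stage to its mirror, leaky-ReLU activations
(slope 0.01), and a single-logit voxel head. Feature widths double per
stage from `base_width` (capped at 128). A single network uses 3
resolution stages. `build_wnet()` cascades two of them: stage 1 (5
stages) segments the skeleton from CT alone; stage 2 (3 stages) receives
CT, PET and the binarised stage-1 mask and predicts lesions, with stage
1 frozen while stage 2 trains. The convolution forward/backward kernels
are written directly in C++ (row-contiguous tap accumulation); an
im2col+GEMM reference implementation ships alongside and the test suite
checks the two against each other, as well as the whole-network gradient
against finite differences.

The loss is class-weighted binary cross-entropy,
`L = -(1/N) sum_i w_i [t_i log p_i + (1-t_i) log(1-p_i)]`, with
inverse-frequency weights normalised so `sum_c w_c n_c = N` and
probabilities clipped at 1e-7. The weights are computed over the
balanced pretraining patch pool rather than over whole volumes: the loss
is only ever applied to patch inputs, and whole-body inverse frequency
(roughly 1:300 at the defaults) pushes the 0.5-threshold operating point
into gross over-segmentation.

Training follows a two-phase schedule (`training_schedule()`): SGD with
learning rate 0.001 and momentum 0.95 throughout; phase 1 pretrains for
1000 iterations on the top-30 patches per volume ranked by foreground
ratio; phase 2 continues on the full patch grid until the checkpointed
loss (every 100 iterations) stops improving by more than 1e-4 for 5
consecutive checkpoints. Patches overlap by 5 voxels and the final
patch per axis is shifted flush with the boundary, so the grid covers
every voxel. Inference (`predict_volume()`) uses the same tiling,
averages overlapping logits, and thresholds the sigmoid at 0.5.

One consequence of inverse-frequency weighting deserves emphasis: with
a foreground weight an order of magnitude above the background weight,
the probability at which weighted risk balances sits well above 0.5, so
a 0.5 threshold is a deliberately recall-heavy operating point. The
reference study (`run_phantom_study()`) therefore calibrates its
decision threshold on the *training* volumes — it sweeps a fixed grid
of thresholds over the trained model's training-set probability maps
and keeps the pooled-Dice-optimal one — and applies that single
threshold unchanged to the held-out phantoms. `predict_volume()` keeps
the plain 0.5 default.

Whole-volume gradient steps were considered for phase 2 and rejected:
with im2col-free kernels the bottleneck is activation memory, and a
full-volume backward pass at realistic grids exceeds desk-scale budgets;
sampling the complete patch grid optimises the same objective in
expectation.

## Evaluation

Voxelwise: Dice (`2|A.B| / (|A|+|B|)`, defined as 100 for two empty
masks), sensitivity, specificity and precision, with undefined
denominators reported as `NA` rather than 0. Pooled figures sum the
confusion counts over test volumes before forming ratios; per-volume
rows are also reported.

Lesionwise: the patch-overlap rule. The evaluation region (by default
the truth bounding box, or a supplied skeleton mask, plus a 9-voxel
margin) is tiled with 9x9x9 patches overlapping by 4 voxels; a patch is
positive when strictly more than 10% of its voxels are lesion, and a
truth-positive patch counts as detected when the same rule marks it
positive in the prediction. One consequence worth knowing: a lesion
smaller than ~73 voxels can never make an interior patch positive, so
sensitivity is reported as `NA` when the truth contains no positive
patch.

`half_max_segment()` implements the half-maximum annotation rule used
for delineating individual hot spots: the 26-connected component around
a seed among voxels at or above half the local maximum within a
15-voxel search radius.

## The scaled-down phantom study

`phantom_study_defaults()` fixes the package's reference experiment,
used by the acceptance script and the end-to-end tests: 12 phantoms on a
64x64x96 grid at 3 mm spacing (a torso section), 5-15 lesions each, the
full acquisition model (1e6 counts, 30%/30%, MLEM-20), a V-Net with
base width 8 trained on z-scored CT+PET with 16^3 patches, and the last
3 phantoms held out. Two scaling choices matter:

* **3 mm spacing** keeps lesion diameters at 4-16 voxels, matching the
  resolution regime of a clinical-matrix phantom experiment; at coarser
  spacing pooled Dice is dominated by discretisation, not detection.
* **16^3 patches** preserve the ratio of patch count to volume (several
  hundred patches per volume) so that selecting the top 30 actually
  balances classes; a patch size chosen for clinical volumes tiles a
  desk-scale volume only a few dozen times and the selection step
  becomes vacuous.

The problem sizes were chosen so the whole study (simulation, training,
inference, scoring) runs in well under half an hour on a single CPU
core.

## Numerical choices and degenerate inputs

* Probabilities clipped at 1e-7 in the loss; logits averaged (not
  probabilities) when stitching overlapping patches.
* MLEM masks voxels with sensitivity below 1e-9 of the maximum and
  starts from a flat image matched to the data scale; zero-count bins
  contribute zero ratio.
* `compose_expectation()` refuses an all-zero trues sinogram; Poisson
  draws require nonnegative expectations.
* Ties in top-k patch selection break by lexicographic corner order, so
  selection is deterministic.
* A class absent from a training target is an error for the networks
  (nothing to learn) and a warning plus unweighted fallback for
  `class_weights()`.
* All randomness flows through explicit integer seeds; child seeds are
  derived with fixed multipliers and stay below 2^31.

## Known limitations

* The anatomy is a fixed stylized body plan; networks trained here see
  no anatomical variability.
* The scatter model is a radial Gaussian expectation, not a transport
  simulation; detector effects beyond a Gaussian PSF (normalisation,
  dead time, time-of-flight) are absent.
* Severity coupling makes low-uptake lesions faint in both modalities
  simultaneously; some drawn lesions are genuinely near-invisible, which
  bounds attainable sensitivity -- mirroring the failure mode reported
  for small, low-contrast lesions in clinical reading.
* The classical baselines classify voxels independently; their
  characteristic signature (high sensitivity and specificity, low
  precision and Dice) is reproduced, not remedied.
* On these phantoms the PET channel carries nearly all of the lesion
  information, so the margin of the PET+CT network over a PET-only
  network is small (within seed-to-seed noise), unlike on clinical data
  where anatomical context matters far more. The single-modality CT
  network, by contrast, trails both by a wide margin.
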