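# petlesion

Whole-body bone-lesion detection for multiple myeloma on hybrid PET/CT,
as a fully self-contained R package: a digital-phantom generator and
physics-based PET simulator provide ground-truth data, volumetric neural
networks (V-Net and a cascaded W-Net) segment the lesions, classical
voxel classifiers (random forest, k-NN, linear SVM) serve as baselines,
and voxelwise plus lesionwise patch-overlap metrics score everything.

## Who this is for

Researchers in medical image analysis who want a reproducible,
CPU-scale testbed for multimodal (PET+CT) lesion segmentation methods —
in particular for studying class imbalance, multimodal fusion and
cascade architectures — without access to clinical data. No external
data are needed; every experiment in the package synthesises its own
inputs from a seed.

## The model at the core

Segmentation is voxelwise binary classification of 3D volumes. A V-Net
style encoder–decoder (3×3×3 same-padded convolutions, stride-2
compression and decompression, skip concatenations) maps the z-scored
CT and PET channels to per-voxel foreground logits. Training minimises
a class-weighted cross-entropy

L = −(1/N) Σᵢ ωᵢ [ p̂ᵢ log pᵢ + (1 − p̂ᵢ) log(1 − pᵢ) ],

with ω inversely proportional to the voxel count of each class
(normalised so Σ ω_c n_c = N), by SGD (lr 0.001, momentum 0.95) in two
phases: 1000 iterations of pretraining on the 30 patches per volume
with the highest foreground ratio (patches overlap by 5 voxels and tile
the volume flush to its boundary), then fine-tuning on the full patch
grid until the checkpointed loss (every 100 iterations) converges. The
W-Net cascades two V-Nets — skeleton from CT (5 stages), then lesions
from CT + PET + the binarised skeleton mask (3 stages).

The PET simulator performs attenuated parallel-beam forward projection
(90 radial bins × 160 angles per slice) of the phantom activity, adds
an analytic scatter expectation (30% of counts) and uniform randoms
(30%), scales the expectation to 10⁶ counts, draws Poisson noise and
reconstructs with MLEM (20 iterations) using the exact adjoint of the
projector.

Detection is additionally scored lesionwise: 9×9×9 patches with 4-voxel
overlap tile the skeleton region; a patch is positive when more than
10% of its voxels are lesion, and sensitivity/specificity/precision are
computed over patches.

## Worked example

Simulate a small cohort, train a V-Net on PET+CT, and score the
held-out phantoms:

```r
library(petlesion)

cfg   <- phantom_study_defaults()          # 12 phantoms, 64x64x96 @ 3 mm
cases <- simulate_cases(4, cfg$grid, base_seed = 7,
                        config = cfg$phantom)

# one phantom: CT in HU, reconstructed PET, integer tissue labels
cases[[1]]$ct[30, 30, 48]     # 66.8  (soft tissue, HU)
sum(cases[[1]]$lesion)        # 2768 lesion voxels
length(cases[[1]]$lesions)    # 11 lesions in the ledger

sched <- training_schedule(pretrain_iters = 200, max_finetune_iters = 200,
                           patch_size = 16, batch_size = 4)
res <- run_phantom_study(cases, holdout = 1, channels = c("ct", "pet"),
                         base_width = 8, schedule = sched, seed = 1)
round(res$pooled, 2)
#>        dice sensitivity specificity   precision
#>       68.79       60.06       99.93       80.48
round(res$lesionwise, 2)
#> sensitivity specificity   precision
#>       67.27       99.85       94.87
```

`res$pooled` holds the voxelwise metrics pooled over held-out phantoms
(percent): `dice` is the overlap score 2|A∩B|/(|A|+|B|), `specificity`
the true-negative rate over all non-lesion voxels, and `precision` the
fraction of predicted lesion voxels that are real — here roughly 80% of
flagged voxels are true lesion, while almost no healthy tissue is
flagged (specificity 99.93). `res$lesionwise` reports the patch-overlap
detection metrics (two thirds of lesion-bearing patches found in this
deliberately short run), and `res$per_volume` a row per held-out
phantom. A 200-iteration schedule underfits; the full study in the
reproduction section trains five times longer and reaches pooled Dice
near 80.

A command-line front end covers the same pipeline on disk:

```sh
inst/cli/petlesion simulate --out cohort --n 4 --seed 7
inst/cli/petlesion train    --data cohort --out model.rds
inst/cli/petlesion predict  --model model.rds --case cohort/phantom_004 --out mask.nii.gz
inst/cli/petlesion evaluate --pred mask.nii.gz --truth cohort/phantom_004/labels.nii.gz --out report.json
```

## Package tour

| area | entry points |
|---|---|
| phantoms | `build_anatomy()`, `sample_lesions()`, `apply_lesions()`, `generate_phantom()`, `generate_cohort()` |
| PET simulation | `pet_geometry()`, `hu_to_mu()`, `forward_project()`, `compose_expectation()`, `add_poisson()`, `mlem_reconstruct()`, `simulate_study()` |
| networks | `vnet_spec()`, `build_vnet()`, `build_wnet()`, `train_vnet()`, `train_wnet()`, `predict_volume()` |
| loss & patches | `class_weights()`, `weighted_cross_entropy()`, `extract_patches()`, `select_top_patches()` |
| baselines | `patch_features()`, `sample_training_set()`, `fit_baseline()`, `predict_baseline()` |
| evaluation | `dice_score()`, `voxel_confusion()`, `lesionwise_detection()`, `half_max_segment()`, `kfold_split()`, `metric_report()` |
| study & I/O | `simulate_cases()`, `run_phantom_study()`, `phantom_study_defaults()`, `read_volume()`, `write_volume()`, `cli()` |

The methods vignette (`vignettes/phantom-study.Rmd`) documents the
model assumptions, simulator physics, parameter defaults and their
rationale, and known limitations.
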