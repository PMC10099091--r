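# dirgan

Unsupervised deformable image registration (DIR) for longitudinal
cone-beam CT (CBCT), built for the radiotherapy setting where a patient is
imaged at every treatment fraction and the anatomy (and the image quality)
drifts between sessions. The package implements a two-stage, adversarially
regularized spatial-transformer approach: a **global** generator predicts a
coarse whole-volume displacement field (DVF), and a **local** generator
refines the globally deformed volume on overlapping 64³ patches whose
per-patch fields are tiled and averaged; the final DVF is the composition
of the two. No ground-truth deformations are used anywhere — training is
driven entirely by an image-similarity objective.

The objective per generator is

```
L = α·SIM(I_d, I_t) + β·ADV(I_d) + γ·R(u)
SIM = [1 − NCC(MIND(I_d), MIND(I_t))] + δ·GD(MIND(I_d), MIND(I_t))
R(u) = μ₁·mean‖∇u‖² + μ₂·mean‖∇²u‖²
```

with defaults α, β, γ, δ = 200, 1, 10, 5 and μ₁, μ₂ = 1, 0.5. `MIND` is the
modality-independent neighbourhood descriptor — a per-voxel patch
self-similarity vector that is exactly invariant to affine HU maps, which
is what makes the similarity robust to the scatter-driven HU inconsistency
between CBCT fractions. `ADV` is the binary cross entropy of a fully
convolutional discriminator trained to tell deformed volumes from real
ones. Everything — the 3D conv networks, their backward passes, MIND and
its gradient, the warping layer, Adam — is implemented in the package
itself (R + Rcpp kernels) and verified against finite differences and
brute-force oracles in the test suite.

Because patient CBCT data cannot be shipped, the package includes a
synthetic abdomen phantom generator (body, spine, ribs, organ-like blobs,
implanted fiducial markers, fraction-specific streak/bias/shift
degradations, smooth invertible ground-truth DVFs) so that the full
pipeline is exercised end to end, plus the standard evaluation suite:
landmark target registration error (TRE, mm), body-masked MAE (HU) and
NCC, bony-mask Dice, and Jacobian-determinant regularity (%N = fraction of
body voxels with det ≤ 0).

## Worked example

Register a degraded, deformed phantom fraction back onto its target
fraction and score the result:

```r
library(dirgan)

spec <- phantom_spec(seed = 3, artifact_strength = 10, intensity_shift_hu = 20)
pair <- make_registration_pair(spec)   # target, moving, landmarks, gt field

cfg <- recovery_train_config(seed = 1)
g <- train_global(list(list(moving = pair$moving, target = pair$target)), cfg)
l <- train_local(list(list(moving = pair$moving, target = pair$target)),
                 g$checkpoint, cfg)
r <- register_pair(pair$moving, pair$target, g$checkpoint, l$checkpoint)

pre  <- tre(pair$landmarks_moving, pair$landmarks_target,
            zero_dvf(dim(pair$target$data), pair$target$spacing))
ev <- evaluate_registration(r$deformed, pair$target, r$final_dvf,
                            pair$landmarks_moving, pair$landmarks_target)
mean(pre); ev$tre_mean_mm; ev$mae_hu; ev$ncc; ev$dsc_bone
ev$regularity$pct_nonpositive
```

On this configuration (64×64×48 phantom at 2 mm spacing, ground-truth
field with 3-voxel peak displacement, +20 HU inter-fraction shift, 10 HU
streaks; ~8 minutes on one CPU) the run prints:

```
mean(pre)        1.962403      # mm, before registration
ev$tre_mean_mm   0.9087449     # mm, after registration (54% reduction)
ev$mae_hu        29.72117      # body-masked MAE, down from 40.6 HU
ev$ncc           0.9550962     # body-masked NCC, up from 0.848
ev$dsc_bone      0.9714811     # bony Dice, up from 0.838
ev$regularity$pct_nonpositive  8.954355e-05   # folding fraction
```

i.e. the landmark error is halved to sub-voxel level, image agreement
improves on every metric, and fewer than 0.01% of body voxels fold.

A thin command-line front end with `simulate`, `train`, `register` and
`evaluate` subcommands lives at `inst/cli/dirgan.R`.

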