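---
title: "Multi-scale adversarial deformable registration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale adversarial deformable registration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The registration problem

Fractional cone-beam CT (CBCT) volumes acquired across a radiotherapy
course show two kinds of disagreement: genuine anatomical deformation
(organ motion, filling, weight change) and nuisance variation (scatter-
driven HU inconsistency between sessions, streak artifacts). Deformable
image registration (DIR) estimates a dense displacement vector field (DVF)
`u` aligning a moving fraction onto a target fraction. `dirgan` implements
an unsupervised two-stage scheme: a *global* generator works on the whole
(down-sampled) volume pair and captures coarse deformation; a *local*
generator refines the globally deformed volume on overlapping patches whose
per-patch fields are tiled and averaged back into a whole-volume local
field. The final field is the composition of the two, and the deformed
volume is produced by a single trilinear warp of the original moving
volume (avoiding double-resampling blur).

Both generators are trained adversarially against fully convolutional
discriminators that score volumes as "real CBCT" versus "deformed", with
no ground-truth DVFs anywhere in the interface: training consumes image
pairs only.

## Objective

Each generator minimizes

```
alpha * SIM(Id, It) + beta * ADV(Id) + gamma * R(u),
```

with the defaults `alpha = 200`, `beta = 1`, `gamma = 10` exposed through
`loss_weights()`. The similarity term operates on the
modality-independent neighbourhood descriptor (MIND) of both volumes:

```
SIM = [1 - NCC(MIND(Id), MIND(It))] + delta * GD(MIND(Id), MIND(It)),
```

with `delta = 5`. MIND replaces raw HU by a per-voxel vector of patch
self-similarities, exactly invariant under affine intensity maps
`a*I + b` (a > 0) — the property that makes the similarity robust to
inter-fraction HU drift; the invariance is asserted to 1e-6 in the test
suite. NCC pools all descriptor channels jointly into one global
statistic; GD is the mean squared difference of spatial derivatives
(central differences, one-sided at borders), averaged over the three axes.
The regularizer is

```
R(u) = mu1 * mean |grad u|^2 + mu2 * mean |lap u|^2,    mu1 = 1, mu2 = 0.5,
```

the standard diffusion + curvature penalty. The published notation for
these two norms is ambiguous between sums and means; we read both as mean
squared magnitudes so the weights are resolution-independent. The
adversarial terms are plain binary cross entropy over patch-level score
maps; the discriminator loss averages its real and fake halves so a
chance-level discriminator scores `-ln 0.5` on both sides.

## MIND parameters

The descriptor is cited without parameters in the source literature, so
the package fixes the most common configuration and documents it: a
6-connected offset set (one offset per face neighbour), patch radius 1,
and a variance floor of 1e-6 times the volume's intensity variance. Patch
means are taken over the voxels actually inside the grid (no padding), and
shifted samples are edge-clamped. Each voxel's channel vector is divided
by its own maximum, making "normalized intensity" concrete: values lie in
(0, 1] with the maximum channel exactly 1, and a constant volume maps to
all-ones. Both choices are covered by brute-force oracle tests.

## Networks

Exact layer tables are not published for the generator, so the
architecture is config-driven and matches every stated constraint: an
encoder with two max-pooling downsamples whose two skip connections are
pooled onto the coarse grid and gated by additive attention against the
bottleneck features (1x1x1 projections, ReLU, 1x1x1, sigmoid,
multiplicative gating), LeakyReLU activations throughout, and a 1x1x1
linear head that emits the 3-component DVF *at quarter resolution*; the
field is then trilinearly upsampled (with displacement rescaling) to the
input grid. Generating the displacement field on a reduced grid and
upsampling is part of the published design, and it matters: producing
per-voxel displacements at full resolution gives the optimizer enough
freedom to chase artifact structure, while the coarse parametrization is
structurally restricted to smooth fields and recovers the true
deformation far more accurately (roughly two-fold better landmark error
on the phantom study than a full-resolution head under the identical
objective). The head is zero-initialized so an untrained generator
performs exactly the identity registration — standard for unsupervised
DIR and load-bearing for the tests that compare against the identity
arm. The discriminator is a three-layer FCN with a sigmoid head at 1/4
resolution.

No deep-learning runtime exists in this package's dependency footprint;
forward passes, all backward passes (convolution, pooling, trilinear
resampling, warping, MIND, the losses) and the Adam optimizer are
implemented in the package itself (R driving Rcpp kernels). Every
backward path is verified against central finite differences in the test
suite, which is the property that makes the hand-written training loop
trustworthy.

## Training

The global stage resamples each volume pair to a configurable grid
(`global_downsample_shape`) and alternates one discriminator update with
one generator update under the total objective. The local stage applies
the trained global generator, warps the moving volume once, extracts
co-located patch pairs on the `plan_patches()` grid (production geometry:
64^3 patches, 32x32x48 overlap), and trains the local pair on patch-level
losses, visiting the full patch grid in order each epoch. Inputs are
normalized by a fixed HU/1000 scale; Adam uses the GAN-conventional betas
(0.5, 0.999) by default, and every random draw flows from the single
config seed, so reruns are bit-identical.

The learning rate deserves a note: because the DVF head starts at zero and
Adam moves each weight by at most ~lr per step, the attainable
displacement magnitude after `n` iterations scales like
`dvf_scale * lr * n` times the feature scale — the generator therefore
carries a fixed output multiplier (`dvf_scale`, default 8) so that
multi-voxel displacements are reachable within a few hundred iterations
without touching identity-at-initialization. Short desk-scale runs use a
larger learning rate than long production runs would;
`recovery_train_config()` packages the schedule used by the phantom
recovery study: 5e-3 for the coarse global stage, 5e-4 for the local
stage (which only corrects sub-voxel residuals and destabilizes at
aggressive rates), betas (0.9, 0.999), 500 and 450 iterations.

## Synthetic phantom

Patient CBCT data is not distributable, so the phantom module generates
abdomen-like test volumes: a superelliptical soft-tissue body (~40 HU,
with smooth seeded texture of +/-60 HU and organ-like blobs) on an air
background (-1000 HU), a spine-like posterior column with a spinous
process, two rib-like arcs (700 HU), and implanted 3-voxel fiducial
markers at 2500 HU. Landmarks sit at fiducial centres and bone tips,
mirroring how TRE landmarks are chosen clinically. Ground-truth fields
come from `make_smooth_dvf()` (Gaussian-smoothed white noise, rescaled to
a stated peak displacement; fold-free by construction when the peak is
below half the smoothing width, and re-drawn from a sub-seed otherwise).
`degrade()` adds the CBCT-like nuisance: a global HU shift, a smooth
multiplicative bias field on the attenuation above air, and incoherent
angular streak noise in the axial plane (a superposition of many random
angular modes). Two modelling details were forced by measurement rather
than taste. First, the structural phantom is blurred by a 0.7-voxel
Gaussian before the metal fiducials are inserted: binary one-voxel edges
at ~1000 HU contrast have no counterpart in PSF-limited CT and otherwise
dominate every intensity metric under sub-voxel interpolation. Second,
the streaks must be *incoherent*: an early single-sinusoid streak model
could be aligned by a smooth rotation-like deformation, handing the
optimizer an artifact-matching shortcut that beat anatomical alignment;
independent multi-mode angular noise is uncorrelated under every
rotation, as real inter-fraction streaks are.

A registration pair is built as *moving = degrade(warp(phantom, gt))*
versus a target that carries its own independent artifact realization
(the inter-fraction +20 HU shift stays on the moving side). Both
fractions carry artifacts because both are cone-beam acquisitions;
against a pristine target the descriptor loss can be lowered simply by
squeezing the moving image's artifact structure into uniformity — we
measured the similarity at the exact ground-truth alignment to be no
better than unregistered under that construction — a shortcut real
longitudinal pairs do not offer. Moving-frame landmark positions are
obtained by fixed-point inversion of the backward-mapping ground truth,
so the pre-registration TRE is exact. What the phantom does **not**
emulate: real projection physics (scatter, beam hardening, cone-beam
reconstruction artifacts beyond stylized streaks), sliding organ
interfaces, and topology changes (gas pockets appearing between
fractions). Passing the recovery test therefore demonstrates that the
optimization machinery can recover smooth, invertible deformation under
HU inconsistency — not clinical-grade performance on patient anatomy.

## Evaluation suite

* **TRE** — landmarks live in physical mm. The stored field is
  backward-mapping, so propagating a moving landmark needs the forward
  map; we invert by fixed-point iteration (tolerance 1e-3 voxel, max 50
  iterations, non-convergence flagged). With a zero field TRE reduces to
  the plain inter-set distance.
* **MAE / NCC** — restricted to the body mask, defined as HU > -300
  (strict, per the "higher than" convention); the HU-thresholded region
  itself is used rather than its bounding box, following the explicit
  mask-determination wording.
* **DSC** — Dice overlap of the bony masks (HU > 300) of deformed and
  target volumes.
* **Regularity** — the fraction of body voxels with `det(I + grad u) <= 0`
  (%N, folding), plus a scalar Jacobian summary. The literature's
  "Jacobian determinant index" is not given a formula, so the report's
  summary is configurable and defaults to the standard deviation of the
  determinant within the body mask; the choice is recorded in the output
  and not claimed to reproduce any published table.

## Numerical choices

* 0-based voxel indexing; voxel `(i,j,k)` sits at `origin + (i,j,k) *
  spacing` mm.
* Warping samples the moving volume at `x + u(x)` with trilinear
  interpolation and *edge clamping* (zero filling would create spurious
  HU edges at the body boundary).
* DVF composition is `local(x) + global(x + local(x))` with trilinear
  sampling; at integer sample points the interpolation weights collapse
  to 0/1, so composing with a zero field is bit-exact — which is what
  makes the "local generator zeroed equals global-only arm" check exact
  rather than approximate.
* Up-sampling a DVF multiplies each component by the axis grid ratio so
  displacements stay in voxel units of the new grid; resampling uses
  zero-origin scaling (source coordinate = target * in/out), under which
  constant and linear fields are reproduced exactly away from the clamped
  trailing edge.
* Patch fusion is an unweighted mean over covering patches ("averaged",
  taken literally); extract-then-fuse is exactly the identity.
* Jacobians use central differences with one-sided borders; the
  regularizer's Laplacian is zero at border planes where the second
  derivative is undefined, which makes linear fields exact closed-form
  cases.
* The discrete operators used in losses have exact adjoints implemented
  alongside them; gradient correctness is enforced by finite-difference
  tests rather than assumed.

## Problem sizes

The test and acceptance runs use a 64x64x48 phantom at 2 mm spacing, a
ground-truth field with 3-voxel peak displacement and 8-voxel smoothness,
degradation with a 20 HU shift and 10 HU streaks, a global stage trained
on the whole 64x64x48 grid (filter width 4) and a local stage on 32^3
patches with (16,16,12) overlap, 500 and 450 Adam iterations — the
`recovery_train_config()` protocol. These sizes keep a full recovery
experiment to minutes on a single CPU while leaving every algorithmic
component identical to the production configuration (64^3 patches,
32x32x48 overlap, full filter widths), which remains the package
default. One caveat on the recovery score: it is reported as the ratio
of post- to pre-registration mean landmark TRE, and the pre-registration
TRE depends on where the random landmarks happen to sit in the random
field. Seeds whose landmarks land in low-displacement regions start
below one voxel of error, where the ratio is a harsh yardstick even when
the absolute accuracy is as good as in any other run.

## Known limitations

* Training is single-threaded CPU; production-scale 512x512x88 volumes
  are out of reach without a GPU runtime, which is out of scope here.
* No rigid pre-alignment is performed (deliberately, matching the
  method's stated design); pairs with large rigid offsets will spend
  global-stage capacity on translation.
* The adversarial term with a small discriminator mostly acts as a weak
  regularizer at desk scale; ablation hooks (`beta = 0`) are exposed and
  tested instead of claiming GAN-specific gains.
* MIND uses the single-scale 6-neighbour configuration; self-similarity
  context variants are out of scope.
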