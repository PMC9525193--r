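---
title: "Cross-phase hepatic vessel segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-phase hepatic vessel segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Contrast-enhanced abdominal CT is acquired in phases: early (arterial), when
arteries are maximally opacified, and later (venous), when veins are. Vessel
annotations consequently exist only for the class that is conspicuous in each
phase — arteries in arterial-phase scans, veins in venous-phase scans. A
surgeon planning a liver resection wants *both* trees in one coordinate
frame, but the patient breathes and shifts between acquisitions, so the two
phases are related by a smooth, unknown deformation and the two label sets
cannot simply be overlaid. Registration-based fusion inherits exactly the
deformation error it tries to remove.

`vesselda` implements the alternative: segment both vessel classes on the
venous-phase image alone.

1. **Stage 1** learns an unpaired image translation from arterial-phase to
   venous-phase appearance (and back), so that arterial scans — with their
   artery annotations — can be restyled as "pseudo-venous" images. No paired
   or registered data are used.
2. **Stage 2** trains a 3D U-shaped segmentation network on those translated
   volumes (arteries) and on native venous volumes (veins), with a loss that
   couples voxel overlap to the global 3D geometry of the vessel tree.

## Stage 1: vascular-reinforced unpaired translation

The translation network is a cycle-consistent adversarial pair: generators
$G_{AB}$, $G_{BA}$ map 2D slices between the arterial (A) and venous (B)
domains; global discriminators $D_A$, $D_B$ judge realism of whole slices.
Four losses are combined:

$$L = \lambda_1 L_{cycle} + \lambda_2 L_{adv} + \lambda_3 L_{local}
      + \lambda_4 L_{idt}, \qquad
  \lambda_1 = 10,\ \lambda_2 = \lambda_3 = 1,\ \lambda_4 = 5 .$$

$L_{cycle}$ penalises the squared error of round-trip reconstructions
$G_{BA}(G_{AB}(I_A)) \approx I_A$ (both directions); $L_{idt}$ asks each
generator to leave images already in its output domain unchanged; $L_{adv}$
is the usual cross-entropy adversarial loss on sigmoid score grids.

The distinctive term is $L_{local}$: a second pair of discriminators sees
only *mask-activated* inputs — the image multiplied by its vessel
annotation, background set to the normalization floor $-1$. Whole-slice
discriminators are dominated by large-area appearance and tolerate the
erasure of branches a few pixels wide; a discriminator that sees nothing
*but* the vessels cannot. The generated slice is activated with the source
slice's annotation (the only mask it is spatially aligned with), the real
slice with its own phase's annotation.

Design notes, where the printed formulation left choices open:

* **Masking both inputs.** Activating only the generated input would let the
  local discriminator separate real from fake by background alone (real
  slices have texture outside vessels, activated fakes are flat $-1$),
  yielding no vessel-specific gradient. The default masks both; a
  strict-as-printed mode is available (`mask_real = FALSE`).
* **Cycle norm.** The squared-norm form is the default
  (`cycle_type = "l2"`); an L1 option exists, as both appear in the
  cycle-consistency literature.
* **Identity loss operands.** Implemented in the standard sense
  ($G_{AB}$ applied to venous images and compared to themselves); the
  alternative pairing of a translated arterial image with an unrelated
  venous image would compare different subjects.
* **Adversarial objective.** Cross-entropy (matching the loss as written);
  a least-squares option is provided since the lineage commonly uses it.
* **Architecture.** Generators are residual encoder–decoders (7×7 stem, two
  stride-2 downsamplings, six residual blocks, nearest-upsample + conv
  decoder, tanh output); global discriminators are 4-layer strided patch
  classifiers, local discriminators 3-layer (a smaller receptive field for
  few-pixel structures). Channel counts are configurable; 64 base channels
  at clinical resolution, 8 in the desk-scale test fixtures.
* **Optimizer.** Adam, learning rate 2e-4, betas (0.5, 0.999), linear decay
  to zero over the second half of the step budget.

## Stage 2: segmentation with an orthogonal depth-projection loss

The segmenter is a 3D U-Net: four encoder levels of two 3×3×3 convolutions
(batch-normalised, ReLU) followed by 2×2×2 max-pooling, a two-convolution
bottleneck, and four decoder levels that upsample, halve channels, and
concatenate the matching encoder features before two more convolutions; a
1×1×1 sigmoid head emits per-voxel probabilities. Inputs must be divisible
by 16 per axis (four halvings); the constructor enforces this rather than
padding silently. Batch normalisation runs with one patch per step
(per-patch statistics) during training and keeps running moments
(momentum 0.1 updates) that are used at inference, the standard BN
semantics — so a model carries its training domain's intensity statistics
with it, which is part of why cross-domain transfer fails without
translation.

The loss couples soft Dice,

$$L_{dice} = 1 - \frac{2\sum XY + \varepsilon}{\sum X + \sum Y +
\varepsilon},$$

with a projection-similarity term. Summing a (soft) mask along each
coordinate axis gives three density matrices — parallel-ray projections of
the predicted vessel tree onto the coordinate planes. Flattened to vectors
$P_a(\cdot)$, the loss is

$$L_{ps} = 1 - \tfrac13 \sum_{a \in \{x,y,z\}}
  \cos\!\big(P_a(X),\, P_a(Y)\big), \qquad
  L_{seg} = L_{dice} + \lambda\, L_{ps} .$$

A voxelwise overlap loss is indifferent to *where* missing mass sits;
the projections are not — a dropped distal branch changes all three
shadows. The term is differentiable because the projection is a linear map
and the cosine is smooth away from zero norms.

Numerical conventions, chosen for stable training:

* Two empty projections count as similarity 1 (identical emptiness), so
  $L_{ps}(\varnothing,\varnothing) = 0$; exactly one empty counts as 0.
  Norms are $\varepsilon$-stabilised so gradients stay finite on soft masks.
* Flattening order is row-major over the two remaining axes. Any fixed
  order is valid (cosine similarity is permutation-equivariant when applied
  consistently); the order is frozen for checkpoint compatibility.
* $\lambda$ defaults to 1.0 and is swept (0, 0.1, 1) in the ablation
  harness; the weight is genuinely a free parameter of the method.
* Training uses soft (probability) masks inside $L_{ps}$ for
  differentiability; evaluation uses hard masks.

## Preprocessing

* **Windowing.** Intensities are clipped to a 420 HU window centred at
  190 HU — the band `[-20, 400]` that contains essentially all annotated
  vessel voxels on contrast CT — then mapped affinely to $[-1, 1]$ (the
  generators' tanh range), with the window level at 0. The map uses the
  window's fixed endpoints, not per-volume extrema, so anchor intensities
  mean the same thing in every volume; `label_window_coverage()` reports
  the in-band fraction of annotated voxels for any given dataset.
* **Slice selection.** Only the annotated z-range is kept
  (`crop_to_labeled_slices()`, margin 0 by default); no annotated voxel is
  ever dropped.
* **Resizing.** Images are resampled per slice with natural cubic splines
  (separable), labels with nearest-neighbour so they stay exactly binary;
  512×512 → 352×352 by default, rescaling the recorded in-plane spacing.
* **Patching.** Depth patches of 96 slices are taken top-to-bottom at
  stride 80, always including the top- and bottom-aligned patches, so every
  slice is covered and at least two patches exist whenever the volume is
  deeper than a patch. Overlapping predictions are mean-pooled at
  inference (max-pooling available) — the recombination rule is a package
  choice.
* **Augmentation.** In-plane random rotation (±10°) and scaling
  (0.9–1.1×), the same draw applied to image and mask, bicubic vs
  nearest-neighbour interpolation, reflection padding so no empty corners
  enter adversarial training. Magnitudes are configurable; they model
  small body twists and girth variation between subjects.

## The phantom: what it emulates, and what it does not

Clinical two-phase data with vessel annotations are not publicly
distributable, so the package ships a synthetic stand-in
(`phantom_spec()`, `phantom_case()`) that reproduces the *statistical
premise* of the method:

* **Anatomy.** Random bifurcating trees (recursive, branching angles drawn
  in a cone, radii shrinking by the Murray-law factor 0.79 per generation,
  floored at 1 voxel) — connected, tapering, with branches only 1–2 voxels
  across, the structures the local discriminators and the projection loss
  exist for. At the clinical default (512×512, 0.8 mm) trees run seven
  generations; desk-scale fixtures (64×64) use five so vessel density
  stays near the clinical ~2%.
* **Two phases, one anatomy.** The arterial phase renders arteries at full
  contrast (300 pseudo-HU over a 60 pseudo-HU background) and veins at 10%
  of their venous contrast; the venous phase renders veins fully
  (220 over 80) and arteries at 30% — faint but present, as in real venous
  scans. All intensities sit inside the `[-20, 400]` window so the
  clinical preprocessing applies unchanged.
* **Inter-phase motion.** The venous-phase geometry is displaced by a
  smooth random field (coarse Gaussian noise upsampled with splines,
  amplitude 2 voxels) — respiration and repositioning, without sliding
  discontinuities. Labels follow their phase: artery masks are delivered
  in arterial geometry, vein masks in venous geometry, and the warped
  artery mask is kept separately as the cross-phase ground truth that a
  radiologist would otherwise have to annotate by hand.
* **Noise.** Additive Gaussian (15 pseudo-HU).

Deliberately absent: organs, tumors, beam-hardening, scanner texture,
through-plane motion. Passing tests on phantoms therefore demonstrates that
the pipeline's machinery — translation that preserves small vessels,
projection-constrained segmentation, domain-gap behaviour — works as
designed; it does not certify clinical accuracy, which the original
framework established on private patient data.

## Problem sizes in the shipped tests

The test suite and the acceptance script exercise the full pipeline at
phantom scale, sizes chosen as the smallest at which the studied effects are
visible: stage 1 trains 8-channel networks for 200 steps on six 32×64×64
cases (the checked properties: cycle-loss decrease and >50% shrinkage of the
artery contrast gap after translation); the stage-2 generator is the same
run continued to 800 steps (translation quality keeps improving after the
200-step checkpoint); stage 2 trains base-8 U-Nets on 32³ patches from ten
cases, three seeds per λ ∈ {0, 1}, with four held-out cases for evaluation.
Full-size configurations (352×352 slices, 96×352×352 patches, base 64/16)
are retained in the defaults.

## Known limitations

* The conv-net engine is CPU-only and single-threaded; clinical-resolution
  training is out of reach in reasonable time. The engine exists to make
  the method executable and testable end to end; its gradients are verified
  against finite differences in the suite.
* Convolution arithmetic is single precision internally (the engine is
  memory-bandwidth-bound); losses and optimizer state are double.
* NIfTI volumes are read in on-disk order and the package's own writer
  emits identity orientation; arbitrary clinical orientation matrices are
  not reoriented to a canonical frame.
* The identity loss assumes both domains share one intensity normalization;
  scanner harmonisation is out of scope.
* DSC is the only evaluation metric, matching the framework's own
  reporting; surface-distance and centerline metrics are not implemented.
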