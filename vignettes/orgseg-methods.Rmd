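---
title: "Multi-organ CT segmentation and PET quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-organ CT segmentation and PET quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orgseg)
```

orgseg implements a complete multi-organ CT segmentation and PET
quantification stack: a 100-organ label registry, intensity normalisation
and grid resampling, two small fully convolutional networks (a semantic
network for plain organs and an instance network for vertebrae and ribs),
clustering of predicted instance centres, morphological postprocessing,
overlap metrics, per-label quantification including standardised uptake
values (SUV), DICOM/NIfTI I/O and DICOM de-identification. A synthetic
phantom generator supplies seeded CT/PET volumes with exact ground truth, so
every stage is testable end to end without patient data. This vignette
explains the models, the tunable parameters, the numerical choices, and what
the phantom experiments do and do not demonstrate.

## The segmentation model

Organ segmentation uses two networks rather than one because vertebrae and
ribs are *instances*: many structures of nearly identical local appearance
whose identity (L3 versus L4) is not decidable from a local window. The
semantic network assigns each voxel one of the plain-organ labels (one
SoftMax channel per label plus background). The instance network classifies
voxels into background/vertebra/rib (3 SoftMax channels) and additionally
regresses, through 3 linear output channels, the spatial centre of the
instance that owns each foreground voxel. Clustering those per-voxel centre
predictions separates the instances; anatomical numbering is then assigned
by sorting cranio-caudally.

Both networks are fully convolutional stacks of *valid* (unpadded) 3D
convolutions. Valid convolutions make tiled whole-volume inference exactly
composable: each output voxel depends only on its own receptive-field
window, so any tiling plan reproduces the untiled result bit for bit
(`predict_volume()`, verified in the tests). Input volumes are normalised by
clamping Hounsfield units to [-800, 800] and dividing by 800, mapping any CT
input into [-1, 1] with fixed points 800 HU -> 1, 0 HU -> 0, -2000 HU -> -1
(`clamp_scale()`).

### Configurations and the receptive field

`network_config()` describes a stack as a list of convolution, average
pooling and nearest-neighbour upsampling layers; a 1x1x1 output convolution
is appended automatically. `receptive_field()` derives the per-axis input
extent seen by one output voxel directly from the layer list, so the
geometry of any configuration is checkable rather than asserted.

Two presets are shipped:

* **`"full"`** reproduces the declared constraints of the full-scale
  design: four resolutions (three pooling stages early in the stack), two
  kernel shapes — (5, 5, 3) and (3, 3, 3) — compensating the anisotropic
  (1.36, 1.36, 3) mm voxels, valid convolutions throughout, and a derived
  receptive field of exactly (136, 136, 72) voxels, i.e. (184.96, 184.96,
  216) mm at the training spacing — approximately a cube in millimetres.
  The exact depths and filter counts of the original full-scale networks
  are not recoverable from their published description, so they are
  configurable here; the preset satisfies every stated constraint and the
  receptive-field check is part of the acceptance suite.
* **`"desk"`** is the reduced network the package's experiments train:
  three 3x3x3 convolutions (8/12/12 filters) with leaky-ReLU activations
  plus the output convolution, receptive field 7^3 voxels. It is sized to
  train on one CPU core in a few minutes.

Training (`train_network()`) and tiled inference (`predict_volume()`)
support single-resolution stacks (unit output stride, odd receptive field).
Multi-resolution stacks are buildable and runnable forward — which is what
the receptive-field verification needs — but pooling makes a network
equivariant only to shifts that are multiples of the pooling stride, so
arbitrary-origin tiling would no longer be exactly composable. Restricting
the exact-tiling guarantee (and hence training) to unit-stride stacks keeps
that guarantee honest.

### Training procedure

Studies are split 80%/20% into training and validation sets at the study
level. Each optimisation step samples a batch of patches from random
training studies, computes the masked categorical cross-entropy (plus the
centre-regression term for instance networks), and applies one update of
the adaptive-moment method with Nesterov momentum (Nadam; `beta1 = 0.9`,
`beta2 = 0.999`). Everything is seeded: the same configuration reproduces
the same loss trajectory exactly, and a non-finite loss aborts with an
error rather than being swallowed.

Partially annotated studies are handled through a per-voxel validity mask:
voxels whose true label is not in the study's annotation set carry zero
weight in the loss (`annotation_weights()`), so missing organ annotations
contribute nothing. Background is always treated as annotated.

Patch sampling is uniform over valid origins, with a configurable
foreground bias (`fg_bias`): with that probability the patch is centred on
a random foreground voxel instead. Volumes smaller than the patch are
mirror-padded, which avoids the intensity discontinuities of constant
padding. Augmentation (`augment()`) draws an in-plane rotation uniformly
from +-0.15 rad, an isotropic scale from +-10 %, and an intensity shift
from +-100 HU. The geometric transforms are applied identically to the
image (trilinear) and to the label and mask channels (nearest neighbour,
because labels are categorical); the intensity shift applies to the image
only, and in HU *before* clamping and normalisation — a +-100 HU shift only
has meaning on the HU scale, and a shift of +100 on an 800 HU voxel still
normalises to 1. Whether the shift precedes or follows clamping is a
genuinely open choice; it is configurable, with pre-clamp as the default.

Two training options deserve explanation because the desk experiments rely
on them:

* **Leaky ReLU (`"lrelu"`, slope 0.1).** After clamp/scale, air is exactly
  -1 and lung-like tissue about -0.87: a flat, strongly negative input
  region in which a substantial fraction of plain-ReLU units are inactive
  from initialisation onward, leaving the air/lung contrast without
  gradient flow. The leaky slope keeps those units trainable.
* **Class-balanced cross-entropy (`class_balance = TRUE`).** Voxel classes
  are weighted by inverse frequency within each patch's valid region
  (mean weight 1). With plain cross-entropy under heavy class imbalance,
  the argmax boundary of a low-contrast class sits below the decision
  threshold until logit magnitudes have grown large, which takes many more
  optimiser steps than a CPU-scale budget provides; balancing centres the
  decision boundary on the class boundary from early in training. The
  option defaults to off — plain cross-entropy — and is switched on by the
  desk experiments.

The centre-regression target is parameterised as the *offset* from the
voxel to its instance centre (in mm, divided by `centre_scale = 20` so
targets are O(1)). Offsets are translation-invariant, matching a fully
convolutional network; an absolute-coordinate mode is kept as an option.
The regression loss is a masked mean squared error over vertebra/rib
foreground voxels, weighted 1:1 against the cross-entropy by default
(`centre_weight`).

## Instance assembly

`cluster_instances()` groups the per-voxel predicted centres by
agglomerative single-linkage clustering cut at a millimetre threshold
(default: half the expected inter-vertebral centre-to-centre pitch).
Single linkage needs no preset cluster count, which matters because the
number of vertebrae and ribs varies between images. Clusters smaller than
`min_size` voxels (default 5) are discarded as noise. Point clouds larger
than `max_exact` (default 3000) are quantised to cells of a quarter of the
linkage threshold first; since the jitter of predicted centres is far below
the threshold in practice, this changes nothing in the experiments while
bounding the O(n^2) distance matrix.

`assign_indices()` sorts vertebra instances by decreasing z (the package
convention is +z toward the head) and assigns consecutive registry labels
from a declared starting entry. Anchoring the run (is the most cranial
instance C1 or Th1?) is heuristic by design — it cannot be resolved from a
cropped image — so the start is an explicit argument, and instance counts
beyond the available registry slots produce a warning and truncation. Ribs
take the level of the nearest vertebra instance and a side from the
centroid's position relative to the vertebral midline (+x = anatomical
left).

Postprocessing of every label keeps the largest connected component
(26-connectivity; ties broken deterministically toward the earliest voxel
in (z, y, x) scan order) and fills interior holes (background
6-connectivity). The composite is idempotent and produces a single
component without holes; both connectivities are configurable. `fuse()`
overlays instance labels on the semantic argmax (argmax ties break toward
the lower label index), then applies the per-label morphology in
increasing label order, letting hole filling claim only background voxels.

## Metrics

`confusion_counts()` computes exact per-label TP/FP/FN voxel counts;
voxels whose *reference* label is unannotated are excluded entirely, and
unannotated labels are not reported — the evaluation-side mirror of the
training mask. Dice, recall and precision follow their standard closed
forms; Dice is the harmonic mean of precision and recall, an exact identity
on integer counts that the tests verify by property. When both masks are
empty all three metrics default to 1 (agreement on absence), with
`empty_value = NA` available to mark them undefined instead — a convention
that must be explicit under sparse annotations.

Aggregation is provided in two clearly named modes, because a per-organ
average and a voxel-pooled metric answer different questions and published
per-organ tables are ambiguous about weighting: `"per_label_mean"`
averages the per-label metrics within each group; `"pooled"` sums the
counts first. Neither mode is claimed to reproduce any particular published
average. Foreground metrics binarise all labels against background and are
invariant to label renaming; `interobserver()` compares two readers (Dice
symmetric, recall and precision swapping under argument exchange).

## Quantification

`label_stats()` reports, per label: volume (voxel count x voxel volume,
exact), mean and maximum of the value volume, the number of 26-connected
components, and total uptake (sum x voxel volume, identically mean x
volume). SUV uses the body-weight variant — the clinical default —
with the injected dose decay-corrected to scan start:
`SUVbw = concentration[Bq/ml] * weight[g] / (dose[Bq] * 2^(-t / T_half))`.
A worked example: 10 kBq/ml with 100 MBq injected (no decay) in a 70 kg
patient gives SUV 7.0. One half-life of elapsed time doubles the factor. A
missing dose or weight produces a report without SUV scaling plus a
warning, never a hard failure. Stored PET values already decay-corrected
are supported via `decay_corrected = TRUE`.

## Imaging I/O and de-identification

NIfTI-1 is the interchange format (via RNifti); the affine stored is a
positive-diagonal sform carrying spacing and origin in the package's
internal axis convention, with no RAS/LPS reorientation. DICOM support is a
minimal explicit-VR little-endian codec written for the package: CT series
(one file per slice, HU encoded with rescale slope/intercept, slices
re-sorted by position on read), PET series (32-bit float pixel data so
round-trips are exact to float precision, plus the radiopharmaceutical
attributes SUV needs), and a segmentation-style label object — the
Segmentation SOP class with a SegmentSequence item (number + name) per
label and label indices as unsigned 16-bit pixel data. This is a pragmatic
label-map encoding rather than the full per-segment binary-packed
Segmentation IOD; the write/read round-trip reproduces the label array and
names exactly, which is the contract the rest of the package needs. CT
round-trips are bit-exact for integer HU (HU are quantised to integers on
write).

De-identification applies an attribute-action profile in the spirit of the
DICOM standard's basic confidentiality profile: names and IDs are replaced
with dummies, free-text identifying attributes removed, dates removed by
default (or shifted by a consistent per-session offset when
`retain_longitudinal` is set, preserving intervals between studies), and
UIDs remapped through a per-session injection so study/series linkage
survives while original UIDs disappear. Pixel data are untouched. Which
profile options the original platform applies is not published; the
conservative default here removes dates. The tests verify by byte-scan that
no profiled value survives anywhere in the output files, and that a second
pass within a session is a no-op.

## The phantom generator

`generate_phantom()` rasterises ellipsoids, boxes and tubes with known HU
statistics onto a configurable grid (later primitives overwrite earlier
ones at overlaps), adds per-primitive HU jitter and global Gaussian noise,
and records exact ground truth: label maps, per-instance voxel-centroid
centres (the regression target; stored centres agree with mask centroids
to within half a voxel by construction), and annotation sets.
`sparsify_annotation()` emulates per-study incomplete annotation by
Bernoulli thinning of the label set. `generate_pet()` adds a co-registered
activity volume with per-label uptake and optional noise.

The desk-scale study conditions are fixed in `desk_semantic_phantom()` /
`desk_spine_phantom()`: a 64^3 voxel, (2, 2, 3) mm CT with three organs —
lung-like (-700 HU), liver-like (60 HU), bone-like (700 HU), spanning
normalised contrasts from 0.125 to 0.94 — with 20 HU global noise and
seed-dependent moderate variation in organ position and size; and a
48 x 48 x 64 spine of 3–8 ellipsoidal vertebrae (36 x 30 x 15 mm, 9 mm
clear gap, so a 24 mm pitch, 1 mm z-jitter), optionally with rib tubes.
The grid and organ sizes were chosen once to make one CPU-core training
take minutes while keeping the anisotropic-voxel, multi-instance structure
of the real problem.

What the phantoms deliberately do **not** model: anatomical texture,
contrast phases, partial-volume boundaries, scanner artefacts, or
inter-organ contact geometry. Passing the desk experiments therefore
demonstrates that the pipeline's machinery — sampling, masking, loss,
optimisation, inference, clustering, numbering, metrics — is correct and
trainable, not that the reduced networks would reach any particular
accuracy on patient CT.

## The desk experiments

`desk_semantic_experiment()` trains the reduced semantic network on 20
seeded phantoms (16 train / 4 validation; 2400 Nadam steps of 3 patches of
14^3 voxels; learning rate 5e-3; every patch foreground-centred; class
balancing on)
and evaluates per-label Dice on the held-out studies; the experiment's
target is min per-label Dice >= 0.80, and it reaches ~0.97.
`desk_instance_experiment()` trains the instance network on 10 spine
phantoms (800 steps, same schedule) and reports the mean Euclidean
centre-prediction error over vertebra voxels on held-out studies (~2 mm,
against a 9 mm clear gap and 24 mm pitch) plus the instance counts
recovered by clustering. `instance_recovery_experiment()` exercises
clustering alone on exact and jittered centre fields from 50 phantoms;
noiseless recovery of the exact count and voxel partition is 100 %, and
with per-voxel centre jitter of 0.1 x gap it remains >= 95 %.

## Known limitations

* Training and exact tiled inference are restricted to unit-stride
  (single-resolution) stacks; the multi-resolution full-scale preset is
  buildable and verifiable but not trained here.
* The DICOM codec reads the dialect it writes (explicit VR little endian)
  and is not a general-purpose DICOM parser.
* Vertebra numbering is anchored heuristically by a declared starting
  vertebra; a global shift of the whole run (the classic off-by-one
  failure) is detectable only from wider anatomical context that a local
  model does not see.
* The interpolation in `resample_image()` is plain trilinear; no
  band-limiting is applied before downsampling.
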