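---
title: "Multi-organ segmentation of whole-body mouse scans: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-organ segmentation of whole-body mouse scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`moseg` implements an end-to-end pipeline for delineating multiple organs
in volumetric whole-body mouse scans (micro-CT or light-sheet microscopy
style data in NIfTI files), together with an annotation-uncertainty mode
that predicts where independent human annotators are likely to disagree,
the standard segmentation quality metrics, and an organ-volumetry
variability analysis. This vignette explains the model and the reasoning
behind every tunable choice; the README shows a worked example.

## The segmentation model

The backbone is a U-Net-style encoder–decoder operating on 2-d **coronal
slices** (fixed indices along axis 1 of the volume; see "Axis
conventions" below). Each *encoding unit* applies two 3×3 convolutions
(padding 1, stride 1), each followed by batch normalization and a ReLU;
units are separated by 2×2 max-pooling with stride 2, and the deepest
unit acts as the bottleneck. Feature channels double per level:
`base_channels * 2^(level-1)`, i.e. 32, 64, …, 1024 at the defaults of
six levels and 32 base channels. Each *decoding unit* bilinearly
upsamples the coarser feature map, concatenates the skip connection from
the encoder at the same level, and applies three such convolutions. A
final 1×1 convolution maps the first-level channels to the prediction
classes, and a **per-class sigmoid** yields probability maps. The
channels are independent — they do not sum to one — and mutual
exclusivity is imposed only at postprocessing. The kernel size of the
final convolution is not uniquely determined by the phrase "mapped the 32
feature channels to the number of prediction classes"; we implement it as
1×1, the minimal map consistent with that description.

Because pooling happens `levels - 1` times (the bottleneck does not
pool), input spatial dimensions must be divisible by `2^(levels-1)`;
prediction pads slices with zeros (the normalized background mean) and
crops the output back, so callers never see this constraint.

The network, its hand-derived backward pass, the Adam optimizer and the
plateau scheduler are implemented in the package itself, with the
convolution / pooling / bilinear-resampling kernels in compiled code
(`src/layers.cpp`). The backward pass is verified against central finite
differences in the test suite, which is the strongest correctness
guarantee such a component can have.

## Training

The loss is the **soft-Dice loss**

$$L = 1 - \frac{1}{C}\sum_{c=1}^{C}
\frac{2\sum_i p_{ic} t_{ic} + \epsilon}
     {\sum_i p_{ic} + \sum_i t_{ic} + \epsilon},
\qquad \epsilon = 10^{-5},$$

with sums over all pixels of a batch and equal class weights; the
smoothing constant is shared with the evaluation Dice. Optimization uses
Adam. Training sees only slices containing at least one organ voxel
(`filter_training_slices()`); inference sees every slice of the volume.
Training slices are augmented by a random in-plane rotation uniform in
±10° (image bilinear, masks nearest-neighbour, out-of-bounds filled with
0, the normalized background mean) followed by a random axis-aligned,
aspect-preserving crop with area uniform in [80 %, 100 %], resized back
to the original shape so batch shapes stay fixed.

Evaluation is **subject-level cross-validation**: leave-one-mouse-out,
with `k` equal to the number of mice. Splitting at the mouse level, never
the scan level, prevents information leaking between the repeat scans of
one animal; the training loop additionally asserts at run time that no
test-mouse slice enters a training or validation batch. Per
training/validation set an ensemble (default ten members, each with a
different validation mouse and seed) can be trained; member probability
maps are combined by a **voxel-wise median**, which is robust to a
corrupted or outlier member. When fewer non-test mice than ensemble
members exist, validation mice are recycled and members differ by seed
only.

After every epoch the mean soft-Dice on the validation mouse's slices is
computed; when it has not improved for five epochs the learning rate is
multiplied by 0.1 (the conventional plateau-scheduler factor; the
monitored quantity and factor are both configurable, as neither is
uniquely pinned down by the description "gradually reduced when the
performance on the validation set stagnated").

### Desk-scale study conditions

The package's own studies (tests and `scripts/acceptance.R`) run on
synthetic phantoms at deliberately small problem sizes chosen so the full
set of experiments completes on one CPU core: cohorts of 6 mice × 2
scans on a 64×64×96 grid at 240 µm/voxel, a 3-level, 8-base-channel
network, 12 epochs, batch size 8, one model per fold. At this scale the
default learning rate of 1e-3 (appropriate for full-size networks trained
for tens of thousands of steps) descends too slowly to converge within 12
epochs, so the studies use 1e-2; the one-slice overfit test demonstrates
clean convergence under that rate. These are the package's standing
choices for its own experiments, not tuned per run.

## Postprocessing

`binarize_softmax()` turns probability maps into a label volume. The
per-class sigmoids need an explicit background competitor for an arg-max
rule, so a synthetic background score `1 - max(anatomical probabilities)`
is appended, the scores pass through a per-voxel softmax, and each voxel
receives the arg-max class. Ties break toward the lowest class index with
background first — so a voxel whose every organ probability is ≤ 0.5 is
background, deterministically. A plain threshold-then-argmax rule
(`rule = "threshold"`) is available. The disagreement channel is excluded
from the softmax and returned unchanged as a heatmap. No filtering or
morphological cleanup is ever applied.

## Disagreement (annotation-uncertainty) mode

With `disagreement_head = TRUE` the targets come from
`make_disagreement_targets()`: each organ channel is the voxel-wise
**agreement** (intersection) of the two annotators, and one extra channel
is the union over organs of the XOR of their masks — exactly the voxels
the annotators label differently. Whether organ targets should be the
intersection or annotator 1's masks with an auxiliary disagreement class
is genuinely open; we default to the intersection (training the model to
"segment organs where both annotators agree") and expose
`organ_targets = "annotator1"` as the alternative. The predicted heatmap
is evaluated by binarizing at 50 % and scoring Dice against the true XOR
region; the tests additionally compare that score against a spatial
permutation null (random 3-d cyclic shifts of the binarized heatmap),
which preserves the heatmap's size and texture while destroying spatial
correspondence.

## Evaluation metrics

All metrics are computed on the reconstructed 3-d volume, per organ and
scan, in physical units (µm) derived from the voxel spacing.

* **Dice**: `(2·TP + ε) / (2·TP + FP + FN + ε)`, `ε = 1e-5`. The
  smoothing makes the score 1 when both masks are empty and well-defined
  when one is. Human-vs-human agreement reuses the same function (it is
  symmetric).
* **Percentile Hausdorff distance**: as printed in its source the
  formula nests a percentile around an already-scalar max–min expression,
  which is not well-formed; we implement the standard reading — the p-th
  percentile of the set of minimum distances from each reference-surface
  voxel to the predicted surface (matching the inner minimum over
  predicted-surface voxels). A symmetric variant pooling both directed
  distance sets is available (`symmetric = TRUE`). Surface voxels are
  mask voxels with at least one face-adjacent (6-connected) background
  neighbour, grid borders counting as background. Percentiles interpolate
  linearly between order statistics (R quantile type 7) so results are
  bit-stable.
* **Center-of-mass displacement**: Euclidean distance between
  voxel-center centroids.
* **Union-reference Dice**: a prediction voxel counts as correct if it
  matches at least one of two annotations: `TP = |pred ∧ (a1 ∨ a2)|`,
  `FP = |pred ∧ ¬(a1 ∨ a2)|`, `FN = |¬pred ∧ (a1 ∧ a2)|`.
* Metrics on empty masks are reported as missing values with a
  machine-readable reason, never as 0 or ∞ — empty predictions do occur
  (e.g. a completely missed organ) and silently coercing them would
  corrupt summaries.

## Organ volumetry and variability

Organ volume is voxel count × physical voxel volume. Three variability
decompositions summarize a cohort with repeat scans and two annotators:

* **intersubject** — standard deviation across mice of the per-mouse
  scan-mean volume (annotator 1);
* **interannotator** — mean over scans of the per-scan standard
  deviation across annotators;
* **intraannotator** — mean over mice of the standard deviation of
  annotator 1's volumes across that mouse's repeat scans.

As printed in their source, these formulas omit the `1/N` factor inside
the square root that a standard deviation requires, while their axis
labels call the quantity a "standard deviation relative to average
volume". We therefore implement **population standard deviations**
(divide by N under the root) as the default and provide
`normalized = FALSE` for the literal unnormalized root-sum-of-squares
form. Relative forms divide by the organ's grand mean volume (mean over
mice of annotator-1 scan means).

## The phantom generator

`phantom_spec()` / `build_cohort()` generate synthetic cohorts with the
statistical structure the pipeline assumes, so every stage is testable
without external data:

* **Organs are ellipsoids** with per-organ mean intensities plus Gaussian
  noise — the simplest shapes whose voxel counts and surfaces have exact
  brute-force oracles. The default four organs emulate a torso at
  240 µm/voxel: heart, liver and kidney at 3–6× the noise floor, and a
  *spleen analog* whose contrast (0.12 against noise sd 0.15) sits below
  the noise floor, emulating the organ that is hard even for human
  experts.
* **Posture jitter** between the repeat scans of one mouse is strictly
  rigid (random shift up to 3 voxels per axis plus in-plane rotation up
  to 5°), so true organ volumes are invariant across scans up to
  voxelization, making volumetry tests exact. Per-mouse anatomy varies by
  a single size factor (sd 5 %), giving intersubject volume variability
  of roughly the magnitude seen in real cohorts (~15 %).
* **Annotator 2** differs from the ground truth (annotator 1) by a
  systematic morphological boundary offset per organ — by default +2
  voxels on the spleen, the organ where human interpretation diverges
  most — plus random flips of boundary voxels (probability 0.1). This
  reproduces structured inter-annotator disagreement in a controllable
  way and guarantees, by construction, that interannotator variability
  exceeds intraannotator variability for the biased organ.
* **Metastases** are simulated as point coordinates sampled uniformly
  inside each organ (plus background points), so organ-allocation
  analyses have a known truth.

What the phantom does *not* emulate: imaging physics (beam hardening,
scatter, PSF), texture inside organs, deformable posture changes, contact
between organs, and anatomically realistic shapes. Passing tests on
phantoms therefore demonstrate that the pipeline's machinery — slicing,
training, reconstruction, metrics, variability accounting — is correct
and that the network can learn contrast- and shape-defined structures at
small scale; they do not certify segmentation quality on real scans.

## Axis conventions and numerical choices

* Axis 1 is dorsoventral (a coronal slice is one fixed index along it);
  axes 2 and 3 span the coronal plane. Voxel coordinates are 0-based;
  physical positions are `index × spacing` at voxel centers. NIfTI
  headers store spacing in mm; the package works in µm.
* Intensity normalization (subtract mean, divide by sd) is **per slice**
  by default — the natural reading for a slice-wise model and the choice
  that keeps inference streamable — with `normalize_scope = "volume"`
  available. The order is slice → normalize → resample. The sd guard
  `max(sd, 1e-6)` maps constant slices (common at phantom edges) to
  zeros.
* Images are resampled bilinearly, label masks by nearest neighbour,
  both under a half-pixel-center convention; the same bilinear kernel
  (with its exact adjoint) serves as the decoder's upsampler.
* Batch-normalization statistics are frozen at inference, so evaluation
  passes are bit-identical; all randomness (phantoms, weight init,
  shuffling, augmentation) flows through per-component seeds derived from
  one master seed, making cohorts and training runs bit-reproducible.
* Deliberate tie-breaks: arg-max ties go to the lowest class index
  (background first); metastasis points belong to the voxel containing
  them (floor of coordinates).

## Known limitations

* 2-d slice-wise modelling only; no 3-d convolutions.
* The disagreement heatmap of the desk-scale model is diffuse: it
  reliably marks the *region* of disagreement (it beats the spatial
  permutation null by an order of magnitude) but over-covers the thin
  XOR shell, so its absolute Dice is modest. Larger models and more
  training sharpen it.
* The CLI stores trained models as RDS files, which are R-version
  portable but not framework-interoperable.
* `index_cohort()` expects the manifest CSV schema described in its help
  page; DICOM and TIFF-stack ingestion are out of scope.
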