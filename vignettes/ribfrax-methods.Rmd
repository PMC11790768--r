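---
title: "Methods: patch-based rib-fracture classification on unfolded rib-cage images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based rib-fracture classification on unfolded rib-cage images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ribfrax)
```

## The task and the modelling assumptions

`ribfrax` classifies rib fractures on 2-D planar reformations of the rib
cage ("unfolded" images), in which all ribs appear as roughly horizontal
bright bands on a dark background. The pipeline makes three structural
assumptions:

* a fracture is a *local* event: a 99×99-px window centred on the fracture
  (in the 3×-upscaled frame, i.e. a 33-px neighbourhood at native
  resolution) contains the evidence needed to type it;
* multiple shifted windows of one fracture are *representations* of the
  same object, so they must never be separated across training and test
  data, and at test time they can be pooled into a single prediction;
* fracture types are distinguishable by fragment geometry: no displacement
  (a fracture line only), sideways offset (*ad latus*), longitudinal
  overlap (*cum contractione*), longitudinal gap (*cum distractione*).

## The synthetic study

Real unfolded-rib PMCT images are private clinical data, so the package is
developed and tested against a seeded generator (`simulation_params()`,
`generate_image()`, `generate_dataset()`). It emulates exactly the features
the pipeline's geometry depends on:

* near-horizontal bands (default 6 per 500×1000 image, 14 px thick,
  intensity 200 on background 20) with slight seeded sinusoidal curvature,
  so band position varies across patches;
* one of four motifs stamped at each fracture site, with a common size dial
  `motif_magnitude` (px): a 2-px dark transverse line (nondisplaced), a
  vertical offset of the right fragment (ad latus), a brighter/thickened
  overlap zone (cum contractione), a background-level gap
  (cum distractione);
* additive Gaussian pixel noise (`noise_sigma`, grayscale units) and 8-bit
  quantisation.

The generator does **not** emulate cortical texture, partial-volume
blur, unfolding artefacts, anatomical variation between ribs, subacute or
chronic fracture appearance, or inter-reader labelling noise. Passing the
end-to-end suite therefore demonstrates that the pipeline's machinery —
mining, grouping, training schedule, aggregation, scoring — is correct and
can recover a signal it is pointed at; it says nothing about classifier
accuracy on clinical images.

The default study conditions are fixed once: 16 positive and 4 negative
images, 5 fractures per positive image, `motif_magnitude = 14` and
`noise_sigma = 1` (a clearly separable rendering, chosen so that end-to-end
accuracy reflects pipeline correctness rather than the generator's
difficulty dial), yielding ≈ 1,040 fracture representations in 80 groups
plus the same number of balanced negatives (≈ 2,080 patches). The
motif magnitudes are free parameters of the simulation, not calibrated to
measured PMCT appearance — no public quantification of these offsets
exists.

## Coordinates and preprocessing

All coordinates are 1-based, `x` = column (left→right), `y` = row
(top→bottom), matching R's matrix convention; annotation CSVs use the same
convention. Cropping (default 500 rows × 1000 columns) is a pure window
copy. Upscaling uses pixel-area-relation resampling; at integer factors an
enlargement maps each source pixel onto an exact `factor × factor` block,
so the operation is replication, constant regions are preserved exactly,
and `factor = 1` is the identity. A source coordinate maps to the centre of
its block, `X = (x − left)·f + (f + 1)/2` — this keeps fracture centres
centred after upscaling; the inverse (`from_large_coords()`) recovers the
source pixel exactly.

## Patch mining

`augment_centers()` enumerates 4 directions × 4 steps of 10 px = 16
additional windows; 4 steps per direction is the unique solution giving 16
shifts at a 10-px step. With a maximum shift of 40 px against a 49-px half
window, the annotated centre remains inside every augmented patch. Manual
curation of shifted samples is replaced by a reproducible proxy: a shifted
window is kept iff it covers at least `curation_fraction` (default 0.5) of
the annotation's extent box. Negative windows tile from the top-left corner
at 25-px stride, keeping fully-inside windows only (6,669 on 1500×3000);
each negative is its own aggregation unit, since groups are only meaningful
for representations of one fracture. `balance_negatives()` draws a seeded
uniform subset matching the fracture-sample count.

## Partitioning

Splits operate on whole groups and are stratified by terminal class: within
each class, shuffled groups are moved to the test side until the class's
test sample mass reaches the target fraction, the last group always staying
on the train side so both sides retain every class. Because groups are
indivisible (up to 17 samples), the realised fraction can deviate from the
target; deviations beyond `split_tolerance` (default ±0.03) raise a
warning, not an error. A class with a single group cannot be stratified and
is reported as an error. K-fold assignment deals shuffled groups round-robin
per class, so per-class group counts per fold differ by at most one.

## Classifier and training schedule

The head is fixed: backbone features → dense(198, ReLU) → dense(198, ReLU)
→ dropout(0.5) → dense(C) emitting pre-softmax scores. Two backbones are
named. `small_convnet_test` — a 3×3 block-mean pool (99→33), one 5×5
convolution with 8 filters at stride 2 (ReLU), and a 5×5 mean pool to 72
features — is deliberately small enough to train in seconds on one CPU and
is the backbone behind every test and synthetic study in this package.
`residual50_pretrained` names the ImageNet-pretrained 50-layer residual
backbone intended for production-scale runs on real data; pretrained
weights cannot be distributed inside this source-only package, so
requesting it raises a configuration error rather than silently training a
randomly initialised deep network. Grayscale patches would be
channel-replicated for such a pretrained backbone; the test backbone
consumes single-channel input natively at 99×99.

The engine (forward/backward passes, Adam, dropout, the schedule) is
implemented in vectorised base R inside the package. Numerical choices:
He-normal seeded initialisation; softmax computed with row-max subtraction;
cross-entropy clamped at 1e-12; argmax ties broken toward the lowest class
index everywhere. Correctness of the hand-derived gradients is enforced by
a finite-difference test.

Training runs in two phases — frozen backbone at learning rate 1e-4, then
full fine-tuning at 8e-5, up to 100 epochs each — with batch 16,
categorical cross-entropy and Adam. Early stopping monitors validation
loss with patience 15 and restores the best-validation-loss weights
(stopping "when validation loss is minimal" implies best-weight
restoration, so the returned model attains the history's minimum).
Learning-rate-on-plateau uses patience 2; the reduction factor is a free
parameter, defaulting to 0.1, the framework-family convention. Validation
quality is tracked as macro-F1 over terminal classes (macro chosen because
the fracture classes are imbalanced; the averaging rule is configurable in
evaluation). Adam state is reset between phases, as when a model is
recompiled for fine-tuning; plateau reductions keep optimiser state. Epoch
shuffling and dropout masks derive from the run seed, so training is
bit-reproducible on CPU.

`select_hyperparameters()` scores a candidate by the mean over folds of its
best-epoch validation F1; ties break toward fewer mean epochs, then
candidate order; a candidate with any failed fold is disqualified.

## Aggregation

For a group with predicted labels ŷ₁..ŷₙ (0 = no fracture) and score matrix
logitᵢᶜ, the presence indicator is

Y = 0 if Σᵢ ŷᵢ = 0, else Y = 1.

The gate is defined by the label *sum*: a group is called fracture-free
only when **every** representation is predicted class 0, so the weakest
fracture signal in any single window is enough to flag the group. (The
alternative gate — calling no-fracture as soon as *one* representation is
negative — would invert this sensitivity rationale and is not what the sum
formula computes.) When Y = 1 the type is k = argmax over the fracture
classes of the per-class mean logit, (1/n) Σᵢ logitᵢᶜ. Class 0 is excluded
from this maximisation; otherwise k could contradict Y = 1. Degenerate
all-equal scores return the lowest fracture class by the global tie rule,
not an error. Aggregation averages the logits of all representations that
entered the test set for that fracture (i.e. the post-curation set).

## Evaluation

Three taxonomy levels restrict on the *true* terminal label and map labels
into level classes: high (everything; no-fracture vs fracture), mid (true
fractures; nondisplaced vs displaced), low (true displaced; three
subtypes). A prediction outside the level's classes (e.g. predicted
no-fracture for a true displaced fracture at mid level) is kept as an
explicit `out_of_level` confusion column: it counts in its true class's
recall denominator but is absorbed by no in-level class's precision.
Dropping such items would silently inflate scores. Mid/low metrics are
macro-averaged over in-level classes with nonzero support; zero-support
classes are flagged and excluded from the averages, and their rows in the
row-normalised confusion matrix are zero. Row normalisation is per true
class, so the diagonal of the relative matrix equals per-class recall — an
identity the test suite asserts.

Standard assessment scores each patch as one item; aggregated assessment
scores each group as one item. On fixtures where every fracture group
contains at least one correctly labelled patch, aggregated high-level
accuracy is bounded below by standard accuracy — the Y gate can only help.

## Problem sizes and runtime

The synthetic study sizes were chosen so a full pipeline run (simulate
through evaluate) completes in under two minutes on a single CPU: ~2,080
patches, a ~70/30 grouped split, fold 1 of the 5-fold partition as the
early-stopping validation set, and the test backbone. The acceptance
script repeats the aggregation-oracle comparison on 1,000 random groups
and the leakage audit over 100 seeded repartitions of a 200-group dataset.

## Known limitations

* The production-scale pretrained backbone is declared but not shipped;
  results in this package are test-backbone results on synthetic data.
* The synthetic generator's motif magnitudes are not calibrated against
  real PMCT appearance; separability is a dial, not a measurement.
* The curation proxy (extent-box overlap) approximates, but cannot
  reproduce, expert judgement about information loss in shifted samples.
* Metrics carry no uncertainty quantification (no bootstrap intervals).
* One fracture per rib band per image; overlapping or comminuted fracture
  patterns are out of scope.
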