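---
title: "Methods: modular femur segmentation in hip CT at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular femur segmentation in hip CT at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Preoperative planning for hip surgery needs the femur separated from the
pelvis in CT, slice by slice, including in diseased joints (osteoarthritis,
developmental dysplasia, femoral neck fracture, osteonecrosis of the femoral
head) where the joint space narrows, deforms or fills with osteophytes.
Manual segmentation takes tens of minutes per scan; a single monolithic
segmentation network struggles simultaneously with three different
subproblems — telling bone from soft tissue, telling femur from acetabulum
across the narrow joint space, and telling which axial slices contain femur
at all (most slices of a long scan do not).

`hipseg` implements a modular answer: three small 2D networks, each solving
one subproblem, trained independently and assembled at test time.

## The model

**Upward network (bone/soft-tissue separator).** A modified 2D U-Net:
encoder–decoder with exactly two 2×2 max-pooling stages and two up-sample
(transposed 2×2, stride 2) deconvolution stages, three 3×3 convolutions per
resolution block across the five blocks, skip concatenations, and a final
1×1 sigmoid projection. Counting only layers that carry trainable weights —
pooling does not participate in backpropagation and is excluded — this is
15 convolutions + 2 deconvolutions + 1 projection = **18 layers**. The input
is the slice windowed at level 40 / width 200 HU, which highlights all bone;
the outputs are a per-pixel bone probability map and a full-resolution bone
feature map fused into the main network.

**Main network (femur segmenter).** A stack of encoder–decoder
"hourglasses" (default two, adjustable via `stack_count`), each again with
two pooling and two deconvolution stages. All same-resolution block outputs
are densely concatenated across the whole stack, so every block receives
the network input plus every earlier feature map at its resolution; this
keeps gradients strong through the stack and reuses features with few
parameters. Each decoder carries its own 1×1 sigmoid head; both heads are
supervised (intermediate supervision) and the last head is the prediction.
The input is the slice windowed at level 500 / width 1000 HU (soft tissue
removed, bone preserved) concatenated with the fused bone feature map.

**Downward network (slice classifier).** Twelve 3×3 convolutions in six
blocks with 2×2 pooling after the first four, a global average pool, and
two fully connected layers ending in a sigmoid: **14 layers**. It scores
each bone-windowed slice with the confidence that it contains femur.

**Assembly.** At test time the classifier confidence multiplies the femur
probability map as a coefficient before the fixed 0.5 threshold, so slices
unlikely to contain femur have all positive responses suppressed. The
remaining bone (upward bone mask minus femur) is labelled as pelvis/other
bone. Per-slice masks are re-stacked in the original order into the 3D
segmentation. Morphological post-processing (keeping the largest
6-connected femur component) exists as an option but is off by default —
the classifier gating is the intended false-positive control, and the
accuracy targets are met without clean-up.

## Loss and training regime

All segmentation heads are trained with the combined loss

L = a · diceLoss + b · crossEntropy,

with soft Dice `1 − (2Σpt + ε)/(Σp + Σt + ε)`, ε = 1e−6, favouring overall
shape integrity, and mean pixel-wise binary cross-entropy preserving edge
pixels. `a` and `b` are hyper-parameters; the package defaults to
a = b = 1. The stacked decoders are supervised jointly with head weights
(0.5, 1): the final head carries full weight, the intermediate one half. A
positive-class weight in the cross-entropy term is available for class
rebalancing (default 1).

The three networks are trained **independently** and assembled afterwards.
During main-network training the *ground-truth* bone mask stands in for the
upward network's feature map (benchmark feeding), and only slices whose
ground-truth flag says they contain femur are fed; at test time the upward
network's prediction and the classifier's confidence replace both. Because
the ground-truth fusion input is a 1-channel mask, the fusion pathway is
1-channel, and the upward network's fused "feature map" is its bone
probability map — the design choice that makes benchmark feeding a drop-in
replacement. (The alternative reading — joint end-to-end training of all
three networks — is not implemented.)

Optimisation is Adam at learning rate 1e−3, batch size 16, with seeded
shuffling; on a single thread a fixed seed reproduces the loss trajectory
exactly. The clinical-scale regime (512×512 slices, 30,000 iterations, GPU
hours) is out of scope; all defaults target desk scale.

## Augmentation

Every slice is cut down the middle and the right half mirrored so it
appears to be a second "left" half: one 256×256 slice yields two 256×128
half-images (at the package's desk scale, 64×64 yields two 64×32). The same
cut is applied to the label slices, and it is applied at training *and* at
test time. The inverse at test time — un-mirror the right half-prediction
and concatenate — reconstructs the full slice exactly; concatenation of
halves is the chosen inverse (the recombination rule is otherwise
unconstrained).

## CT conventions

Stored intensities are unsigned 12-bit integers 0–4095 with the standard
CT rescale (slope 1, intercept −1024) as the package default; windowing
maps `[level − width/2, level + width/2]` linearly to [0, 1] with clamping.
The 200 HU bone threshold utility uses an inclusive comparison (`≥ 200`);
the threshold's strictness is a convention choice. Volumes are NIfTI with
per-axis spacing in mm; the third array axis is axial. Whether clinical
512×512 slices should be resized or cropped to the network input is an open
choice; `hipseg` resizes (bilinear for images, nearest-neighbour for
labels).

## Evaluation metrics

With AS the automatic and GT the manual voxel sets:

* DOC = 2|AS∩GT| / (|AS| + |GT|), on the full voxel sets.
* d(x, A) = min over y in A of the Euclidean distance scaled by the voxel
  spacing, in mm.
* Directed Hausdorff d_H(A, B) = max over x in A of d(x, B); HD is the
  maximum of the two directions.
* Mean surface distance: the symmetric average of all nearest-surface
  distances (the formula is a package choice; only the metric's name is
  fixed externally).

HD and MSD are computed on *surface* voxels (6-connectivity: a class voxel
with any face-adjacent voxel outside the class, the volume boundary
counting as outside), matching standard practice; a pixel-unit option
(`units = "px"`) is available since reported distances are sometimes in
pixels. An empty predicted structure yields DOC 0 with distances flagged
undefined (`NA`), never infinite. All distance metrics are exactly equal to
their O(|A||B|) brute-force definitions — the implementation is a blocked
evaluation of the same double minimisation, and the test suite checks
equality against independent double-loop references on random masks.

## The phantom generator

No clinical scans ship with the package; a procedural hip phantom makes
every module testable. The geometry is parametric-primitive, not
atlas-based: a femur (spherical head, neck and shaft cylinders), an
acetabular cup (hemispherical shell opening toward the head) plus an iliac
slab, inside an elliptical soft-tissue body surrounded by air. Intensities
are tissue means (air −1000, soft tissue 40, trabecular 300, cortical
1200 HU; cortical in a ~1.5 mm surface shell) plus Gaussian noise
(SD 30 HU), quantized to the stored 12-bit range. Defaults: 64×64×60
voxels at 1 mm isotropic — a reduced-scale stand-in for 512×512 scans with
200–600 slices of 1 mm thickness; full resolution is supported but not the
default. The femoral head radius defaults to 15% of the smallest volume
extent (9 mm at default scale). Each case additionally receives mild
seeded anatomical variability — femoral head position (±3–4% of the volume
extent, moving the whole femur), head radius (±10%), acetabular axis tilt
and iliac position — so that cases differ in geometry and not merely in
noise, and held-out phantoms genuinely test generalisation.

The five conditions mirror the diseased-hip categories: `OA` adds
osteophyte-like rim protrusions to both bones; `ONFH` collapses the
superior head with a crater; `FNF` inserts a 2 mm background gap through
the neck, splitting the femur into head and shaft components; `DDH`
translates the femur superolaterally, reducing cup coverage; `normal` is
the identity. Severity is a free parametric choice — the phantoms are not
calibrated to Crowe/ARCO/Garden stages, which no quantitative source pins
down. All conditions preserve the joint gap (default 2 mm) between femur
and pelvis, every phantom contains both femur-positive and a contiguous run
of femur-free axial slices (the classifier's negatives), and identical
spec + seed reproduce the volume bitwise.

What the phantoms do *not* emulate: anatomical shape variability, muscle
and tendon structure, metal implants (excluded from scope), scanner
artefacts, and partial-volume effects beyond interpolation. Passing the
phantom experiments therefore demonstrates that the architecture, losses,
training loop, assembly and metrics are implemented coherently — not that
the system reaches clinical accuracy on real scans.

## The desk-scale recovery experiment

The package's end-to-end check trains on 25 phantoms (64×64×60, seeds
1–25) and evaluates on 5 held-out phantoms (seeds 26–30). The two
segmentation networks train on every third axial slice (500 slices, 1000
half-images after augmentation) — femur geometry varies smoothly along the
axial axis, so neighbouring slices are largely redundant for a per-pixel
task. The slice classifier is much cheaper per slice and its task — is
there femur at this axial level? — is exactly a function of the slice
position relative to each case's (jittered) anatomy, so it trains on every
slice; thinning its training set would leave the femur-top boundary
undersampled. Channel width is `base_channels = 6` and the epoch budget
per stage is at most 10 (upward 4 — it converges within a few epochs on
this contrast; main 10; classifier 6), chosen so the whole experiment runs
on one CPU in minutes. The acceptance bar is a mean held-out femur DOC of
at least 0.85 with classifier gating emptying at least 95% of femur-free
slices.

## Numerical choices and degenerate inputs

* Network engine: convolutions are evaluated as compiled im2col gathers
  plus BLAS matrix products in double precision; the data gradient of a
  stride-1 same convolution reuses the forward path with the spatially
  flipped, channel-transposed kernel. Gradients of every layer type are
  verified against central finite differences in the test suite.
* Initialisation: He-scaled Gaussian weights, zero biases; build functions
  draw from the session RNG, and `train_stage` seeds it from its config.
* Max-pool ties route the gradient to the first maximal corner
  (deterministic tie-break).
* Cross-entropy probabilities are clamped to [1e−7, 1 − 1e−7].
* `quantize_to_stored` clamps to [0, 4095] after rounding; windowing
  requires finite HU input and errors otherwise.
* Empty datasets, femur-free datasets for the main stage, mismatched
  shapes/spacings, out-of-range confidences and thresholds all raise
  informative errors rather than propagating silently.

## Known limitations

* The channel widths of the clinical-scale architecture are not public in
  usable form; widths here are configurable (`base_channels`) and the
  verified facts are the layer counts and the pooling/deconvolution stage
  structure.
* Whether dense connections span one hourglass or the whole stack is
  ambiguous; `hipseg` concatenates across the whole stack.
* The classifier consumes the bone-windowed slice (the femur-windowed
  alternative is plausible but unimplemented).
* Training is plain Adam without schedules, search or early stopping; at
  desk scale this is sufficient and keeps runs reproducible.
* The engine is CPU-only and double-precision; it is written for clarity
  and testability at phantom scale, not for clinical-resolution throughput.
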