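# hipseg

Modular deep segmentation of the femur in hip CT, with a synthetic phantom
generator so the whole system trains and tests at desk scale without
clinical data.

## The problem

Separating the femur from the pelvis in CT is the step that gates
3D planning for hip surgery. It is hard for one monolithic model because it
is really three problems: separating bone from soft tissue, separating the
femoral head from the acetabulum across a joint space a few voxels wide
(which collapses or deforms in osteoarthritis, hip dysplasia, femoral neck
fracture and osteonecrosis), and deciding which axial slices contain femur
at all. `hipseg` implements a modular three-network design in which each
network solves one subproblem:

* an **upward network** — a modified 2D U-Net (two 2×2 pooling stages, two
  up-sample deconvolutions, three 3×3 convolutions per resolution block;
  18 parameterized layers) that separates bone from soft tissue on slices
  windowed at level 40 / width 200 HU and passes a fused bone feature map
  downstream;
* a **main network** — a densely-connected stacked-hourglass segmenter
  (two encoder–decoders, all same-resolution features concatenated across
  the stack, one supervised sigmoid head per decoder) that extracts the
  femur from slices windowed at level 500 / width 1000 HU;
* a **downward network** — a 14-layer slice classifier whose femur
  confidence multiplies the segmentation map, suppressing false positives
  on femur-free slices.

Each segmentation head trains with the combined loss
`L = a·diceLoss + b·crossEntropy` (defaults a = b = 1; intermediate
supervision with head weights 0.5 / 1.0). Every slice is augmented by
cutting it in the middle and mirroring the right half (one 256×256 slice →
two 256×128 half-images; at package desk scale, 64×64 → two 64×32), at
training and at test time. Accuracy is reported as Dice overlap
(DOC = 2|AS∩GT|/(|AS|+|GT|)), directed/symmetric Hausdorff distance and
mean surface distance in millimetres on 6-connected surface voxels.

The convolutional engine itself (im2col convolutions on BLAS, transposed
convolutions, max-pooling, dense layers, reverse-mode gradients, Adam) is
implemented natively in R with one compiled gather kernel; there is no
external deep-learning framework dependency.

## Worked example

Generate phantoms, train the three stages, assemble, segment a held-out
phantom and evaluate (about ten minutes on one CPU):

```r
library(hipseg)

# 25 training phantoms; the segmentation nets take every third axial slice,
# the (cheap) slice classifier takes every slice
seg_ds <- list(); cls_ds <- list()
for (i in 1:25) {
  ph <- generate_phantom(phantom_spec(seed = i))
  seg_ds <- c(seg_ds, make_slice_dataset(ph$ct, ph$labels,
                                         input_size = c(64, 64),
                                         slice_stride = 3))
  cls_ds <- c(cls_ds, make_slice_dataset(ph$ct, ph$labels,
                                         input_size = c(64, 64)))
}

cfg <- network_config(in_rows = 64, in_cols = 64, base_channels = 6)
up <- train_stage("upward", seg_ds, train_config(epochs = 4, seed = 101), cfg)
mn <- train_stage("main", seg_ds,
                  train_config(epochs = 10, seed = 102, stage = "main"), cfg)
cl <- train_stage("classifier", cls_ds,
                  train_config(epochs = 8, seed = 103, stage = "classifier"), cfg)
pipe <- assemble(up, mn, cl)
pipe

held <- generate_phantom(phantom_spec(seed = 30))   # unseen case
res <- segment_volume(held$ct, pipe)
res
evaluate_case(res$labels3d, held$labels)
round(res$per_slice_confidence[44:52], 2)           # femur-top boundary
```

```
<hs_pipeline> input 64x64; layers: upward 18, main 26, classifier 14
<segmentation_result> 60 slices (64 x 64), threshold 0.50, 4002 femur voxels
<metric_report> (mm)
  class 1: DOC 0.9430  HD 6.164  MSD 0.443
  class 2: DOC 0.9397  HD 37.014  MSD 0.620
[1] 0.99 0.01 0.01 0.10 0.03 0.00 0.00 0.00 0.00
```

Class 1 is the femur, class 2 the remaining bone (acetabulum + ilium). A
DOC near 1 means the predicted and true voxel sets almost coincide; MSD is
the average surface disagreement in mm (here under half a voxel) and HD the
worst single surface disagreement — the femur's 6 mm comes from a small
mislabelled patch near the joint space, and the larger class-2 value from a
stray blob of false pelvis, the kind of outlier HD is designed to expose.
The classifier confidences collapse from 0.99 to ~0 exactly where the femur
ends, which is what empties the femur-free slices after gating.

A command-line wrapper covering the same pipeline
(`make-phantoms` / `train` / `predict` / `evaluate`) is installed at:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hipseg.R", package = "hipseg"))')" \
    make-phantoms --n 5 --condition mixed --seed 1 --out phantoms/
```

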