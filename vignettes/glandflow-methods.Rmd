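---
title: "Methods: gland segmentation, classification and mucosa quantification"
author: "glandflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gland segmentation, classification and mucosa quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Histopathological staging of gastritis (the Sydney system) rests on the
morphology of gastric glands: gastric atrophy (GA) is the loss of glands in
the mucosa, and intestinal metaplasia (IM) — an advanced stage of atrophy —
replaces native glands with larger, goblet-cell-bearing intestinal-type
glands. Quantifying this on H&E whole-slide images requires four
ingredients, which map one-to-one to this package's modules:

1. **Gland instance segmentation** (`buildGaglNet`, `trainSeg`,
   `predictTiled`, `postprocess`): a two-branch convolutional network
   produces a 3-class map (background / gland lumen / gland edge) that is
   post-processed into individual gland objects.
2. **Gland classification** (`buildImglVtnet`, `trainCls`): segmented gland
   crops are scored normal vs IM by a backbone feature pyramid with a
   multi-scale deformable-attention encoder.
3. **Mucosa segmentation** (`kmeansSeed`, `buildEnergy`, `graphcutLabels`,
   `trainTissueUnet`, `segmentTissue`, `mucosaMaskFromGlands`): weakly
   supervised tissue/background labelling feeds a U-Net; the mucosa is the
   morphological closing of the gland mask intersected with the tissue.
4. **Biopsy features** (`slideFeatures`, `referenceRatio`, `groupCompare`):
   per-slide mean gland area, glands per mucosa area, and gland area
   fraction, compared across normal / GA / IM cohorts.

Everything is trainable and testable on synthetic phantoms
(`generateTile`, `generatePseudoWSI`) with exact ground truth, and scored
with object-level metrics (`objectDice`, `objectHausdorff`,
`f1Detection`).

# Segmentation model

The segmentation network runs two encoders in parallel. The *global*
branch is a four-stage residual encoder with a 7×7 stem (stride 2); stages
use strides 1, 2, 2 and a final stage with stride 1 and dilation 2, so the
deepest features keep 1/8 resolution while retaining a large receptive
field. The *local* branch is a VGG-style encoder with a 3×3 stem and three
pooling steps; its levels at 1/2, 1/4 and 1/8 resolution are brought back
to full resolution by stride-2 deconvolution chains (one head per level),
in the spirit of contour-aware multi-level fusion. All upsampled maps and
the full-resolution local features are concatenated and fused by a 1×1
convolution ahead of the 3-class head. Every convolution is followed by
batch normalization and ReLU.

Training minimizes the class-weighted negative log-likelihood

$$\mathcal{L} \;=\; L_2 \;-\; \sum_{p=1}^{N} w_p\, r_p \log t_p ,$$

with one-hot references $r_p$, softmax probabilities $t_p$ (clipped at
$10^{-7}$ before the log) and per-pixel weights $w_p$. The weighting rule
is not prescribed beyond "balance the classes", so we use batch inverse
class frequency, $w_p = N / (3\,\mathrm{count}(c_p))$, which equalizes the
weighted pixel mass of the classes present in a batch (`classWeights`).
The $L_2$ term is realized as optimizer weight decay (SGD, learning rate
0.005, weight decay 0.01, momentum 0.9), so `segLoss`'s `l2_coeff`
defaults to 0 to avoid double counting. The optimizer minimizes the
per-pixel mean of the same objective so that the learning rate is
independent of the patch size. Augmentation applies random 90° rotations,
flips and circular shifts on the fly.

Whole-slide inference uses overlap tiling: windows of `tile` pixels with
stride `tile - overlap`; each window keeps its central region (a margin of
`overlap/2`, except at image borders) and regions abut exactly. A
tile-sized image with zero overlap reproduces a direct forward pass.

Post-processing follows fill-holes / remove-small-areas: lumen-class
components are labelled (the edge class separates touching glands), holes
filled, components below `min_area` dropped, and each component reclaims
the surrounding epithelial band by growing over foreground pixels up to
`edge_thickness + 1` px, ties resolved to the nearest component. Instance
ids are assigned 1..K in raster order of centroids. Feeding one-hot
ground-truth labels through this path reconstructs the ground-truth
instances up to id permutation, which the tests assert.

# Classification model

Gland crops are isotropically resized so the longer side matches the input
size and zero-padded symmetrically (224 px at full scale; the desk-scale
experiments use 96 px inputs). The backbone is the same residual 4-stage
encoder; stages at 1/4 and 1/8 resolution form a three-level pyramid. The
two coarse maps are upsampled by deconvolution, the fine map is embedded
by a 1×1 convolution, and the three aligned maps are concatenated and
group-normalized (one group per level). A fused 1×1 projection provides
the query map.

Each encoder layer applies multi-scale deformable attention (MSDAM): for
query $q$ at reference point $r$ (the grid-cell centres of the fused map),

$$\mathrm{MSDAM}(q, r) = \sum_{m=1}^{M} W_m \Big[ \sum_{l=1}^{L}
\sum_{k=1}^{K} A_{mlk}(q)\, F_l\big(\phi_l(r) + \Delta p_{mlk}(q)\big)
\Big],$$

where offsets $\Delta p$ and attention logits are linear in the query, the
weights $A$ are softmax-normalized over the $L \times K$ slots of each
head, and sampling is bilinear with zero padding outside the maps. Queries
are the fused features plus a fixed sinusoidal position encoding and a
learned scale embedding. The module output is added residually and
followed by a two-layer feed-forward network; average pooling and a fully
connected sigmoid head produce the IM score. The vectorized implementation
is verified against a per-query/per-point loop oracle to $10^{-5}$.

Training uses the focal loss
$FL = w_{\mathrm{focal}}\cdot \mathrm{BCE}(p, s)$ with
$w_{\mathrm{focal}} = (1-s)^\gamma$ for $p=1$ and $s^\gamma$ for $p=0$,
$\gamma = 2$. We read the cross-entropy factor with the standard negative
sign so the loss is non-negative and minimization is well-posed; with
$\gamma = 0$ it reduces exactly to binary cross-entropy. The optimizer is
Adam; an optional mean-teacher scheme maintains an exponential moving
average of the student (decay 0.99) and penalizes the squared score
difference on augmented unlabeled crops, ramping the consistency weight
linearly over the first 20% of steps. Per-batch aggregation is the mean.

# Weakly supervised mucosa segmentation

Tissue/background labels are produced without manual annotation. k-means
(k = 3 by default: background, stroma-like, epithelium-like colours)
clusters per-pixel RGB; the brightest centroid becomes background and the
rest tissue. Pixel confidence is the margin between the best and
second-best centroid distances; the lowest decile is left unlabeled and
seeds above the 80th percentile are hard-clamped. The binary labelling
then minimizes

$$E = \sum_{p \in V} C_p(x_p) + \sum_{(p,q) \in E} S_{p,q}(x_p, x_q),$$

with colour-consistency unaries $C_p(l) = \lVert I_p - c_l \rVert^2$ and
contrast-sensitive Potts pairwise costs
$S_{p,q} = \lambda \exp(-\beta \lVert I_p - I_q\rVert^2)$ on the
4-neighbour grid ($\lambda = 10$;
$\beta = 1/(2\,\overline{\lVert I_p - I_q \rVert^2})$ auto-scaled). This
energy is submodular, so an s–t minimum cut solves it *exactly*; the
implementation is checked against exhaustive enumeration on random 3×3
problems, and the returned energy never exceeds the seed labelling's. The
cut labels train a standard U-Net (depth 3, channels 64–128–256–512 scaled
by `width_scale`, 296-px patches and batch 40 at full scale) with pixel
binary cross-entropy and Adam; inference is overlap-tiled, thresholded at
0.5, then small components are removed and small holes filled.

The mucosa itself is `close(glands) ∩ tissue`: dilation merges
neighbouring glands into the glandular layer, erosion restores the outer
boundary, and the intersection guarantees $M \subseteq T$. The paper-level
default radii are 25/25 px; the desk-scale phantom experiments use
dilation 12 / erosion 8 px — the 4-px difference restores the thin
lamina-propria margin at the band surface that pure closing clips at this
scale. Closing is extensive and idempotent, which the tests assert.

# Object-level evaluation

Detection: a segmented object is a true positive iff it overlaps more than
50% of some ground-truth object's area (the gland-challenge convention);
candidates are matched greedily by descending overlap, ties to the smaller
segment id, each object at most once; precision, recall and F1 follow.
Object Dice weights each object's best-overlap Dice by its share of total
area, in both directions, and averages the two sums. Object Hausdorff uses
the same weighting with the symmetric Hausdorff distance on 0-based pixel
centres (Euclidean); an object with no overlapping counterpart is paired
with the nearest-centroid object on the other side. Conventions for
degenerate inputs: both masks empty gives Dice 1 and Hausdorff 0;
detection scores on empty problems return 0 with a warning. All three
metrics are verified to agree exactly with brute-force oracles on random
small instance masks.

# Biopsy features and statistics

Per slide: mean gland area (px²), gland count divided by mucosa area, and
total gland area divided by mucosa area. "Average area that glands cover"
is read as the per-gland mean within each slide (the reading consistent
with per-WSI box plots); IM-classified glands additionally get their own
mean area. Mean areas are expressed relative to the normal group's grand
mean (`referenceRatio`). Group differences use two-sided Mann–Whitney U
tests with Benjamini–Hochberg correction over the three group pairs —
chosen over t-tests for robustness at cohort sizes of 10–45 slides — with
Welch t available as an option.

# The phantom generator

`generateTile` renders an H&E-like tile with exact ground truth: a wavy
tissue band on a bright background, a mucosa band inside it, and
non-overlapping perturbed-ellipse gland rings (low-frequency radial
harmonics on an ellipse) whose epithelial edge band encloses a lumen. IM
glands are enlarged by `imScaleFactor` (default 1.5, so IM areas scale by
≈2.25) and receive 4–8 white goblet-like vacuoles. The palette is fixed:
purple epithelium, pink stroma, near-white background — and a faint
mucinous pink tint in the lumen. The tint is deliberate: lumens belong to
the tissue and mucosa ground truth (gland pixels are defined to lie inside
both), carry secretions in real H&E, and a purely chromatic seeding stage
can only assign them to tissue if they are chromatically distinct from the
background. Gaussian noise (sd 0.02) is added throughout.

Two placement modes exist. `"random"` rejection-samples centres inside the
mucosa band with a 2-px clearance and errors out explicitly if packing is
infeasible. `"rows"` places glands in one or two jittered regular rows —
the arrangement of real foveolae — and is used whenever gland-dense mucosa
matters (the mucosa-reconstruction experiments and the cohort generator),
since random packing cannot reach realistic area fractions of ~0.3. The
ground-truth mucosa is the gland-bearing layer: the tissue rows spanned by
the glands plus a 3-px lamina-propria margin (the placement band when a
tile has no glands). Ground-truth gland areas in `glandTable` are pixel
counts from the emitted instance mask.

What the phantoms do *not* emulate: nuclei, stain variation, mucosal
folds, touching glands with shared epithelium, tissue tears. Passing the
recovery tests therefore demonstrates that the implementations learn and
measure what they claim on chromatically clean, geometrically idealized
data — not clinical performance. Optional artifacts (pen stroke, blur
patch, background debris) perturb only the rendered image, never the
ground truth, and exist for robustness tests of tissue cleanup.

# Desk-scale study conditions

All experiments in the tests and the acceptance script run on one CPU
with width-scaled models; these sizes are the package's chosen study
conditions:

* segmentation recovery: 80-px tiles, 3 glands of radius 5–8 px, 20
  training / 5 held-out tiles, 1/8-width model with one residual block per
  stage, 30 epochs;
* classification recovery: 128-px tiles with 4 glands at IM fraction 0.5,
  100 training / 40 held-out crops at 96-px input, 1/16-width backbone,
  embed dim 16, 2 heads, 2 points, 1 encoder layer, 12 epochs;
* mucosa recovery: 10 gland-dense 128-px phantoms (16 glands of radius
  4–6 px in rows), k = 3 seeding, exact graph cut, 1/16-width U-Net with
  96-px patches, 16 epochs of 20 patches;
* cohort: 10 slides per group; normal = 16 glands, GA = 10, IM = 5 with
  IM fraction 1 (fewer, larger glands — atrophy accompanies IM).

# Numerical choices and degenerate inputs

* Softmax defines the per-pixel class probabilities; probabilities are
  clipped at $10^{-7}$ before logs; non-finite losses abort training with
  a diagnostic rather than propagating.
* Normalization after every convolution uses the sample's own spatial
  statistics per channel in both training and inference (instance-norm
  semantics — with single-sample batches the batch statistics are the
  sample's own, and reusing them at inference keeps the two modes
  identical); running moments are tracked as model state.
* The training engine is a small reverse-mode autodiff tape over dense
  arrays with C++ im2col/col2im convolution lowering; every operator's
  gradient is verified against central finite differences in the tests.
* He initialization throughout; the classifier head starts at zero so an
  untrained model scores exactly 0.5; MSDAM attention weights start near
  uniform and offsets near zero.
* Coordinates are row-major, 0-based, origin top-left; tile windows are
  half-open. Distances use pixel centres.
* `graphcutLabels` rejects negative pairwise costs (non-submodular) and
  non-finite unaries; hard seed clamps use a large finite cost (1e6).
* Determinism: every entry point takes a seed; phantom generation consumes
  RNG in a fixed order, so identical spec + seed is bit-identical, and the
  workflow writes byte-identical CSVs under a fixed seed.

# Known limitations

* The networks are desk-scale analogues: topology is faithful (two
  branches, dilated final stage, pyramid + deformable attention, U-Net
  with stated channel layout) but widths, depths and input sizes are
  reduced for CPU training; headline numbers from GPU-scale training on
  real cohorts are out of reach by design.
* `pretrained_init` is a declared switch but no pretrained weight archive
  ships with the package; only He initialization is available.
* The graph cut runs at the working resolution of the input tile; very
  large slides should be processed at a downsampled working resolution.
* Mean-teacher training helps only when genuinely unlabeled crops are
  supplied; with none it silently reduces to supervised training.
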