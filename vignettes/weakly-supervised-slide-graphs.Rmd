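---
title: "Weakly supervised graph-transformer classification of whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised graph-transformer classification of whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Histology slides are scanned as gigapixel pyramidal images, but diagnostic
labels are usually available only at the slide level — "this biopsy contains
a basal cell carcinoma of subtype II" — with no pixel or patch annotations.
`wsigt` implements a weakly supervised pipeline for exactly this setting:

1. **Tiling** — each slide is cut into non-overlapping patches at a working
   magnification (10X by default), and patches with too little tissue are
   discarded.
2. **Contrastive embedding** — a self-supervised encoder (SimCLR-style:
   two augmented views of the same patch form a positive pair under the
   NT-Xent loss) maps each surviving patch to a 512-dimensional
   L2-normalized feature vector. The encoder can be pretrained on a large
   unlabeled corpus and is *frozen* for all downstream training.
3. **Spatial graphs** — patches become nodes; edges connect patches that
   touch by an edge or a corner on the patch grid (at most 8 neighbours).
   Disjoint tissue pieces yield separate connected components.
4. **Graph-transformer head** — per component: grid max-pooling for
   dimensionality reduction, one graph-convolution (GCN) layer reducing
   node features to 128 dimensions, then a six-block pre-norm transformer
   over the concatenated node tokens of all components plus one learned
   slide-level aggregation token, ending in a softmax over task classes.
5. **Protocol** — a fixed stratified held-out test fraction, stratified
   k-fold cross-validation over the remainder (each fold's validation set
   drives early stopping), Adam fine-tuning of GCN + transformer with the
   encoder frozen, and fold-ensemble inference by softmax averaging.
6. **Evaluation** — confusion matrices, per-class one-vs-rest sensitivity
   and specificity, balanced accuracy (macro recall), threshold-sweep
   ROC/AUC, and fold-mean aggregation.

Because every neural component is implemented in the package itself (plain
matrix arithmetic with analytic backpropagation), the full pipeline runs on
one CPU and every gradient is pinned by finite-difference tests.

## Label schemes

The base labels are `no-tumor` and four tumor growth patterns of
increasing aggressiveness: `Ia` (nodular), `Ib` (superficial), `II`
(medium) and `III` (high). Three tasks reuse the same cohort:

* task 1: no-tumor vs tumor (2 classes);
* task 2: no-tumor vs low-risk (`Ia`, `Ib`) vs high-risk (`II`, `III`);
* task 3: all five base classes.

`taskScheme()` and `remapLabels()` implement the mappings; they are total
(every base label maps) and tested against the grading conventions above.

## Model and numerical choices

**Tissue detector.** A pixel is tissue when its HSV saturation is at least
0.07 *and* its value is at most 0.95 — saturated, non-bright pixels are
stained tissue, near-white pixels are glass. An Otsu threshold on
saturation is available as an option. The patch filter keeps patches with
tissue fraction `>= 0.15`; the boundary value 0.15 itself is kept (the
discard rule is a strict inequality).

**Patch geometry.** Patch side is configurable (224 px is a common choice
at 10X; the synthetic studies use 32 px so that whole cohorts fit in CPU
minutes). Grid coordinates are 0-based; level-0 origins use half-open
pixel boxes. Residual downscaling between pyramid levels uses exact area
averaging (anti-aliased and deterministic).

**Encoder.** A residual convolutional backbone: per stage one 3x3
convolution + ReLU + 2x average pooling followed by a two-convolution
residual block; the default CPU-scale variant has two stages (8 and 16
channels) on 32 px inputs, and a deeper 18-layer-class variant is
configurable. Two implementation details matter on small corpora and are
worth stating plainly:

* *Texture pooling.* The final feature map is summarized by the
  per-channel spatial mean **and standard deviation**. Blob-like textures
  (the discriminative signal in stained tissue and in the synthetic
  slides) differ mainly in spatial variance; mean-only pooling discards
  it.
* *Batch normalization at the pooled layer.* Without it, the pooled
  descriptors of all patches share a dominant direction, cosine
  similarities start near 1, and the contrastive gradient vanishes (the
  classic collapse saddle). Training uses batch statistics; inference
  uses running statistics, so a patch's embedding never depends on the
  other patches in its batch.

Exported features are the L2-normalized backbone outputs (the projection
head is used only inside the NT-Xent loss, following standard contrastive
practice); "512 normalized values" is read as unit L2 norm.

**NT-Xent.** Cosine similarity, temperature `tau = 0.5` by default, the
denominator runs over all `2N - 1` non-self candidates, and the loss is
averaged over all `2N` anchors. Augmentation defaults follow the standard
contrastive recipe: random area crop (scale 0.2–1.0) with resize, color
distortion of strength 0.5, Gaussian blur with sigma drawn from 0.1–2.0
pixels.

**GCN.** One layer, `H' = relu(D^(-1/2)(A + I)D^(-1/2) H W + b)`, output
width 128 by default. Depth one is the minimal reading of "a GCN block";
the symmetric normalization with self-loops is the standard formulation.

**Pooling.** "Max-pooling that preserves positional embeddings" is
implemented as spatial block max over the patch grid (factor 2 by
default): a pooled node exists wherever a block holds at least one node,
its feature is the element-wise maximum over members, and its coordinate
is the block coordinate — spatial layout survives pooling, which is what
the positional encoding consumes.

**Transformer.** Six pre-norm blocks, 8 heads, MLP width 256 (all
configurable; head count must divide the token width). Positional
information is injected as learned embeddings of the binned
`(grid_row, grid_col)` coordinates, added to the tokens; component
identity is *not* encoded, which makes the slide prediction invariant to
the order in which components are passed (verified by permutation tests).
All components contribute tokens to a single sequence with one shared
learned aggregation token, whose final-layer output feeds the
classification MLP and softmax. The "one positive patch makes the slide
positive" reading of weak supervision is treated as label semantics, not
as an explicit patch-level max rule; the aggregation token learns the
slide-level decision.

**Training protocol.** Adam, batch = one slide, learning rate 1e-4 by
default (the CPU-scale synthetic studies pass 3e-3 explicitly — small toy
graphs tolerate and benefit from the larger step). Early stopping
monitors validation accuracy with patience 10; the returned checkpoint is
the epoch with maximum validation accuracy, earliest on ties. The
encoder is never updated ("frozen"); `finetune()` accepts the encoder
object and asserts byte-identity before returning it. A fixed stratified
15% test split is reserved first, then k-fold cross-validation runs over
the remaining 85% with fold i as validation set of member i — this is the
package's reconciliation of a fixed 70/15/15 split with fivefold
cross-validation, two protocol statements that do not uniquely determine
each other. No resampling or class weighting is applied anywhere.

**Ensembling.** The fold ensemble averages the members' softmax vectors
arithmetically; the hard label is the argmax with lowest-index tie-break.
Majority voting was considered and rejected as the default because softmax
averaging preserves the probability scale used by the ROC sweep.

**Evaluation conventions.** Sensitivity/specificity and ROC are
one-vs-rest in multiclass tasks (the only convention under which
per-class specificity is well defined). The ROC sweep uses every distinct
score as a threshold plus endpoints; trapezoid integration makes the AUC
equal to the Mann–Whitney pair-count statistic with ties at half credit
(oracle-tested to 1e-12). Fold aggregation averages every scalar metric
and *sums* confusion matrices (so aggregated matrices hold integer
counts). Note one consequence: a fold-mean balanced accuracy generally
differs from the balanced accuracy recomputed from the summed matrix, and
also from the mean of the per-class sensitivities — metric-level
averaging is applied deliberately and documented rather than resolved.

## The synthetic-data generator

`generateToySlide()` emulates the aspects of real slides the pipeline
actually consumes: a bright background (gray level 245/255 with truncated
Gaussian noise, sd 3/255), one or more rectangular tissue pieces that are
pairwise non-adjacent at patch-grid resolution (Chebyshev distance >= 2,
so disjoint pieces stay disjoint components), pixel-jittered piece
boundaries so that boundary cells have partial tissue coverage and the
15% filter is exercised non-trivially, an eosin-like pink tissue base,
and blob textures whose density and radius increase along the ordinal
severity scale: sparse small blobs for `no-tumor` (density 0.02, radius
1.2 px) rising to dense large blobs for `III` (0.45, 3.5 px). For tumor
slides the class texture is planted in 60% of the well-covered tissue
cells by default; labels are only ever emitted at slide level, and the
per-cell ground truth goes to a separate structure that training code
never sees. The colour bands are chosen so the HSV tissue detector
classifies exactly the planted mask — tissue pixels stay inside the
saturation/value band, background noise stays outside — which is what
makes brute-force mask counting an exact oracle for the tiler.

What the generator does **not** emulate: stain variability, nuclei and
glandular morphology, pen marks, blur and scanning artifacts, pyramidal
containers (toy slides are single-level images with a declared
magnification). Passing tests therefore demonstrate the correctness of
the machinery and the recoverability of planted signal, not clinical
performance on real slides.

The "excision-like" pretraining corpus (`generatePretrainCorpus()`) uses
larger slides (12x12 patch cells, 6 pieces) covering all five texture
classes, so pretrained features transfer to the cohorts by construction —
the synthetic analogue of pretraining on a large excision archive before
fine-tuning on small biopsy cohorts.

## Problem sizes of the shipped studies

The packaged studies are sized for interactive CPU runs. The test
suite's end-to-end study pretrains on 8 corpus slides (~1,000 patches
of 32 px) for 200 Adam steps at batch 8; the reproduction script uses a
somewhat larger recipe (12 corpus slides, 300 steps, batch 16), because
contrastive learning with very few negatives per batch is noisy — with
batch 8 the learned features separate the planted textures for some
initializations and not others, and the larger batch makes the learned
representation reliable across seeds. The cross-validated cohort holds
60 slides (30 no-tumor, 8 Ia, 8 Ib, 7 II, 7 III) with a 15% held-out
test split and fivefold cross-validation over the rest; the
transfer-learning ablation repeats a 40-slide cohort (20 training
slides after splits) over several seeds, comparing the
excision-pretrained frozen encoder against an encoder contrastively
trained on the target cohort's training slides only, with an otherwise
identical protocol. The ablation is asserted
directionally (pretrained mean balanced accuracy at or above
from-scratch), mirroring how such comparisons are reported; with 20
training slides both arms sit far below the large-cohort regime, which
is precisely the regime the comparison is about.

## Known limitations

* The encoder's CPU-scale default is far smaller than an 18-layer
  backbone; the deep variant exists but is impractical without
  vectorized convolution hardware.
* Single working magnification per run; no multi-scale fusion.
* No stain normalization or artifact handling.
* Early stopping on small validation sets (10 slides) is noisy; the
  best-epoch rule (earliest maximum of validation accuracy) can select
  an early checkpoint when validation accuracy saturates before the
  training loss does.
* `runCV()` evaluates every fold member on the same fixed held-out test
  set; per-fold reports are therefore correlated, and the fold-mean is
  not an independent-replicate mean.
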