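---
title: "Progressive screening of cytology slides: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive screening of cytology slides: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(cytoscreen)
```

## The screening problem

Cervical cytology screening asks a reader to find a handful of abnormal
squamous cells — enlarged, hyperchromatic nuclei, sometimes with a
perinuclear halo (koilocytes) — scattered among tens of thousands of normal
cells on a giga-pixel whole-slide image (WSI), and then to call the whole
slide positive or negative. Two properties make this hard for naive
patch classifiers: the lesion signal is extremely sparse and small relative
to the slide, and slides from different laboratories and scanners differ
systematically in staining and imaging style.

`cytoscreen` implements a progressive, coarse-to-fine architecture for this
problem:

1. **LR stage.** The slide, normalised to the 0.243 µm/px reference level,
   is divided into overlapping 512 px tiles sampled at 0.486 µm/px
   ("redundant division": default 25 % overlap so no cell is split by every
   covering tile). A low-resolution model emits, per tile, a lesion
   probability and a location heatmap registered at 1/8 of the tile.
2. **Gate.** Only tiles with probability strictly above 0.5 proceed. Their
   heatmaps are binarised (absolute threshold 0.5), cleaned by a 3×3
   closing then opening, reduced to 8-connected components, area-filtered,
   and each component centroid becomes an HR crop centre (at most 10 per
   tile, largest components first).
3. **HR stage.** 256 px crops at 0.243 µm/px (a ~62 µm field, one cell
   neighbourhood) are re-scored by a high-resolution model that also
   exposes its penultimate activations as an F-dimensional feature vector.
4. **Ranking.** Candidates from all tiles are pooled, duplicates from the
   overlapping tiling suppressed greedily within 64 px (~15.6 µm,
   below typical cell spacing), and sorted by HR probability with a fully
   deterministic tie-break (LR probability, then y, then x). The top 10
   are what a cytopathologist would review.
5. **Slide score.** The rank-ordered top-k feature matrices (k = 10, 20,
   30, zero-padded when a slide yields fewer candidates) feed six recurrent
   members — two per k, differing only by seed — each a single-hidden-layer
   tanh RNN reading rank 1 first, with the positivity read from the
   time-averaged hidden state (padded sequences end in long identical pad
   runs, where a final-state readout is bistable; the mean accumulates each
   real candidate's evidence instead). The slide score is the unweighted
   mean of the six probabilities, thresholded strictly at 0.5.

## Desk-scale backbones

At clinical scale the two cascade models are ResNet50 variants (2,048-dim
features; the LR model carries a dilated-convolution segmentation branch).
Those architecture contracts are retained as `resnet50LrSpec()` /
`resnet50HrSpec()`. The trainable desk-scale backbone (`deskLrSpec()`,
`deskHrSpec()`) is deliberately small so that the full system — generator,
cascade, ranking, ensemble, evaluation — runs end to end on one CPU in
minutes: a fixed multi-scale blob-response filter bank (smoothed darkness
= 1 − V of HSV, two difference-of-Gaussian bands at the normal- and
lesion-nucleus scales, smoothed saturation) computed at half resolution,
feeding trainable heads:

* LR classification head: logistic regression on pooled tile statistics
  (per-map mean, max, top-5 % mean of the per-cell features);
* LR heatmap head: per-heatmap-cell logistic regression, supervised by
  disks of radius 2 heatmap cells around planted lesion centres
  (class-weighted binary cross-entropy);
* HR model: a one-hidden-layer tanh MLP on centre/annulus/whole-crop map
  statistics; the hidden activations (default F = 64) are the candidate
  features, mirroring the penultimate-layer contract.

All heads and the RNN members train with Adam at initial learning rate
10⁻³ and step decay. The decay schedule defaults to ×0.5 every 20 epochs:
with these head sizes a ×0.1-every-10 schedule freezes the optimiser long
before the boundary settles. RNN backpropagation through time clips the
global gradient norm at 5 — over 20–30 steps a vanilla tanh cell otherwise
explodes for some initialisations. Everything is configurable via
`optimConfig()`.

What the desk backbone deliberately does *not* test: learned convolutional
features, ImageNet transfer, and clinical-scale accuracy. What it preserves
and what the tests exercise: the two-head contracts, the 0.5 cascade gate,
heatmap-to-proposal geometry, ranking and padding semantics, the ensemble,
and the three training strategies.

## The three training strategies

* **Designed enhancement** (`augmentConfig()`): hue ±15°, saturation,
  value and contrast ×[0.8, 1.2], flips, shifts ≤ 32 px, blur/sharpen with
  probability 0.2 each — hard caps chosen so cell identity is preserved.
  Every draw is materialised as an explicit parameter record
  (`sampleAugmentParams()`), replayable bit-exactly; geometric parameters
  co-transform annotation coordinates, photometric ones never touch them.
* **Balanced epochs** (`balancedEpoch()`): every (dataset group × category)
  cell contributes exactly the same quota per epoch, resampling small
  cells with replacement.
* **Hard-sample mining** (`mineHard()`, `mixHard()`): after round one, the
  exactly-misclassified records are mixed back at a configured proportion —
  small (0.1) for the recall-oriented LR model, large (0.5) for the
  precision-oriented HR model.

For the RNN members, sequence augmentation is (a) random rearrangement of
the rank order per epoch and (b) multiplicative feature jitter (σ = 0.05)
standing in for photometric re-extraction of the crop features; recomputing
features through the image pipeline inside RNN training would couple the
stages without changing what the augmentation teaches (tolerance to rank
and appearance perturbations). A trained member's output changes by well
under 0.1 mean absolute under test-time permutation of its input rows.

## The synthetic cohort: what it emulates and what it does not

Clinical WSIs are private; the generator (`generateCohort()`) reproduces
the *structural* properties the system's logic depends on:

* sparse, small lesion cells among abundant normal cells — lesion nuclei
  occupy well under 1 % of slide area under the defaults;
* a morphology margin carrying the recognition cues: lesion nucleus radius
  ×1.8–2.5 and darkness +0.3 over normal, optional perinuclear halo
  (`defaultMorphology()`);
* multi-centre style diversity: named styles differing in hue, saturation
  scale, value scale, background colour, noise and defocus
  (`styleLibrary()`), so value-channel histograms separate by style;
* exact point ground truth (0-based centre coordinates at the reference
  level) and a slide-wise 8:1:1 train/val/test split.

Default desk conditions: 40 + 40 slides of 2048² px at 0.243 µm/px, 180
normal cells per slide, 3–15 lesions per positive slide, two training
styles. Lesion density per positive slide is not a clinically asserted
value; it is an exposed parameter.

The generator does **not** attempt photorealistic cytology: no overlapping
cell clusters with realistic chromatin texture, no inflammation, debris or
mucus, no scanner optics. Consequently, passing the end-to-end tests shows
that the *system* — cascade, gating, ranking, aggregation, training
strategies — works as specified on data with the right structure; it does
not certify clinical accuracy, and the printed clinical numbers of the
original study are out of reach by construction.

## The ablation harness

The strategy ablation trains the HR model twice on single-style crops —
with enhancement + mining versus with neither — and compares AUC on crops
from *unseen* styles. Two design points matter, both found empirically:

* Under the study morphology the crop task is separable under any training
  regime (both arms reach AUC 1.0), so the harness uses
  `confusableMorphology()` — borderline, ASC-US-like lesions (radius
  ×1.35–1.9, darkness +0.12) whose recognition genuinely depends on the
  training regime.
* A *single* unseen style mostly shifts features globally, and ranking
  metrics are nearly invariant to global shifts for near-linear heads. The
  multi-centre effect appears when the unseen test set mixes two new styles
  (E and F, darker and brighter than training): an intensity-sensitive
  baseline interleaves their score scales, while the enhancement-trained
  model ranks by style-robust cues. The comparison is directional only.

## Numerical and policy choices

* Coordinates: 0-based pixels, x right, y down, half-open tile extents;
  all candidate coordinates at the 0.243 µm/px reference level. Tile grids
  clamp the last row/column inward (constant tile shape); out-of-bounds
  reads pad with glass white (255, 255, 255).
* Strict `>` at every decision threshold (LR gate, slide call); a score
  exactly at threshold is negative.
* Duplicate suppression, tie-breaks, padding: deterministic as described
  above; negative slides with zero candidates yield all-pad sequences with
  a defined score.
* `specAtFullSens()` returns the largest threshold keeping sensitivity
  exactly 1.0; its specificity depends on the lowest-scoring positive.
* Top-k TPR matches recommendations to truth points greedily in rank
  order, one-to-one, within 15 µm (~ one cell diameter) — an operational
  stand-in for cytopathologist confirmation, not a claim from the study.
* Histograms bin scores in [0, 1] with width 0.05, last bin closed.
* All randomness flows through explicit integer seeds (`withSeed`
  discipline); rendering, augmentation, sampling, training and screening
  are bit-reproducible for a fixed seed, and replicas differ only by seed.

## Problem sizes used by the tests and the acceptance script

The end-to-end study runs 40 + 40 slides at 2048² px (two styles, seeded),
trains all stages, and evaluates the 10-slide held-out split; module tests
use a 16-slide 1024² cohort and closed-form fixtures. The ablation uses
30 small slides at 1024². These sizes are the package's desk-scale choices:
large enough that the cascade, mining and ensemble have something real to
do, small enough for interactive runs.

## Known limitations

* The desk backbone's fixed filter bank cannot represent texture or shape
  cues beyond blob scale and darkness; it is a vehicle for the system, not
  a cytology model.
* Zero-feature padding makes "no candidates" informative to the RNN; the
  alternative (repeat-last) is not implemented.
* Ensemble members train on identical folds with different seeds;
  fold-resampled members are not implemented.
* Bootstrap confidence intervals for the screening metrics are left to the
  user; no reader-study statistics are provided.
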