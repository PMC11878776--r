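---
title: "Hierarchical multi-scale weakly supervised slide classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multi-scale weakly supervised slide classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Endometrial cancer is stratified into four molecular subtypes — MMRd,
NSMP, p53abn and POLE mut — that guide prognosis and adjuvant therapy
but normally require sequencing to determine. `hiwsi` implements a
pipeline that predicts these subtypes directly from H&E whole-slide
images (WSIs), treating the task as weakly supervised patch
classification followed by soft-voting aggregation:

1. **Tile extraction.** The slide is scanned on a non-overlapping
   1024-px grid at native resolution (0.549 µm/px, so each tile spans a
   562-micron tissue window). A tile is kept only if (a) it survives
   the RGB median background filter — rejected when all three channel
   medians exceed 200 (bright background) or fall below 100 (dark
   artifact) — and (b) strictly more than 50 % of its area lies inside
   the tumor mask. Masks are consumed as inputs; tumor segmentation is
   out of scope.
2. **Three-scale hierarchy.** Each accepted tile yields three 224-px
   views: `P_l`, the whole tile area-averaged down (effective
   2.51 µm/px — macroscopic architecture); `P_m`, the exact center
   512-px crop downsampled (1.255 µm/px — an intermediate field of
   view); and `P_s`, one 256-px quadrant of the center crop downsampled
   (0.627 µm/px — near-native cytologic detail). The quadrant is chosen
   by *selective sampling*: the four quadrants are scanned in the fixed
   order top-left, top-right, bottom-left, bottom-right, and the first
   one passing the color criterion is kept; if none passes, the whole
   tile is discarded so that every retained sample carries all three
   scales.
3. **Model.** Three parameter-independent encoder branches (one per
   scale) produce embeddings that are concatenated and fed to a fusion
   head `Linear → GELU → Dropout(0.25) → Linear`, yielding four logits
   per patch triple. Branches can be partially frozen: the embedding
   layer plus the first `floor(n_blocks × freeze_ratio)` blocks are
   non-trainable (at the reference configuration, 60 % of a 24-block
   encoder is 14 blocks).
4. **Training.** Every patch inherits its slide's subtype label (weak
   supervision). Class imbalance is addressed at the patch level by
   subsampling MMRd patches to 70 % and NSMP patches to 50 %, applied
   to training folds only. Optimization is cross-entropy with AdamW;
   the reference configuration uses learning rate 2e-4, batch size 12,
   dropout 0.25 and 20 000 iterations.
5. **Aggregation and evaluation.** The slide-level probability of
   subtype *j* is the mean over its *N* patches of the per-patch
   softmax probabilities, `P_j = (1/N) Σ_i softmax(z_i)_j`. Evaluation
   is patient-grouped, subtype-stratified five-fold cross-validation
   with class-wise and macro AUROC (Mann–Whitney form, ties counted
   half), across-fold normal-approximation 95 % CIs, threshold metrics
   and interpolated mean ROC curves.

## Backbones

The encoder contract is deliberately small: any callable mapping a
224 × 224 × 3 image to a fixed-length vector can be registered
(`register_backbone()`). The shipped `"tiny"` backbone is designed to
train on one CPU: a deterministic feature stem computes, on a 4 × 4
grid of 56-px cells, the per-channel cell means (low-frequency
arrangement) and per-cell gray standard deviations (local contrast),
giving 64 features; on top of it sit a trainable embedding
(`Linear(64 → 32)`) and four residual blocks
`h ← h + W2 tanh(W1 h + b1) + b2`. The residual form keeps randomly
initialized frozen blocks near the identity, so partial freezing never
destroys information — the property that makes the freeze-ratio
ablation meaningful for an untrained backbone. Large pretrained
foundation-model encoders fit the same registry contract but are not
shipped: no weights are bundled, and nothing in the package or its
tests requires them.

## The synthetic cohort: what it emulates and what it does not

Real WSIs with molecular labels cannot be redistributed, so the package
ships a deterministic generator whose output has exactly the
statistical structure the pipeline relies on:

* **Geometry**: square slides (a multiple of 1024 px), a bright
  background strip (all channels > 230, so its tiles fail the median
  filter), tissue below it, and a contiguous tumor region covering a
  controllable fraction of the tissue (mask granularity one pixel
  column, so coverage is exact to ±0.05 and a zero coverage yields an
  empty mask).
* **Patient structure**: a configurable fraction of patients
  contributes two slides; with `m` slides per class and target fraction
  `p`, `round(p·m/(1+p))` patients receive two slides after a seeded
  within-class shuffle.
* **Multi-scale class signal.** The four classes are split into a
  *coarse pair* and a *fine pair*. The coarse pair differs only in the
  spatial arrangement of 512-px constant-intensity cells (amplitude
  ±20): a checkerboard with random per-slide phase versus independent
  random cells. Because cells are aligned to the absolute 512-px grid,
  every 256-px quadrant of a tile's center crop lies inside a single
  cell, so the quadrant view sees a constant offset whose marginal
  distribution is identical for both classes — only a view wide enough
  to contain several cells can tell them apart. The fine pair differs
  only in single-pixel, zero-mean ±18 speckle, which the 1024 → 224
  area averaging attenuates by a factor ≈ 4.6 into the texture floor
  but which the near-native quadrant path preserves. All tissue
  additionally carries a shared 8-px block micro-texture whose
  amplitude is drawn per tile from U(8, 16); its between-tile
  variability masks the residual speckle leakage at the coarse scale.
  Gaussian pixel noise (sd 6) covers everything.
* **Intensity calibration**: tissue base (175, 140, 165) keeps every
  channel median inside the accepted (100, 200) band under all signal
  components; background 245 (clipped to ≥ 231) keeps background
  medians above 200.

Per-slide seeds are derived as `seed XOR hash(slide_id)` with a
31-bit polynomial string hash, so any slide can be regenerated in
isolation and regeneration of a cohort is byte-identical.

What the generator does **not** emulate: H&E stain statistics and
texture, nuclear morphology, scanner artifacts, annotation noise in
tumor masks, or any biological association between morphology and
subtype. Passing tests on this substrate therefore demonstrates that
the pipeline's machinery — filtering, geometry, freezing, training,
aggregation, grouping, metrics — behaves as specified, and that the
three-scale fusion can integrate signal that no single scale carries
alone; it does not certify clinical performance.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `median_low`, `median_high` | 100, 200 | intensity | background-filter bounds |
| `tumor_min_fraction` | 0.5 (strict >) | fraction | majority-tumor rule |
| `tile_px` / `stride_px` | 1024 / 1024 | px | non-overlapping native tiles |
| `target_px` | 224 | px | encoder input size |
| `freeze_ratio` | 0.6 | fraction | reference freezing configuration |
| `dropout` | 0.25 | fraction | fusion-head regularization |
| `lr`, `batch_size`, `iterations` | 2e-4, 12, 20 000 | — | reference training configuration |
| `balance_rates` | MMRd 0.70, NSMP 0.50 | fraction | patch-level class balancing |
| `k`, CI method | 5, normal-over-folds | — | evaluation protocol |

The **desk profile** (`desk_profile()`) adapts the training
configuration to the shipped tiny backbone trained from random
initialization on cohorts of tens of slides: learning rate 3e-3 and
1000 iterations (chosen for stable convergence of the small model; a
large pretrained encoder fine-tuned at 2e-4 for 20 000 iterations is
the reference configuration, kept as the defaults of
`train_config()`).

## Numerical and design choices

* **Background-filter quantifier.** The median rule is applied with an
  *all-channels* quantifier by default: a tile is rejected only when
  all three channel medians violate the same bound. This discards
  uniform white/black regions without dropping eosin-dominant tissue
  in which a single channel alone is bright; the stricter
  *any-channel* variant is a config switch.
* **Coordinates** are 0-based, half-open, level-0 pixels; the grid
  scan is row-major (y outer, x inner). Fixed for determinism.
* **Downsampling** is exact separable box averaging (`box_weights()`):
  each output pixel is the overlap-weighted mean of the source pixels
  it covers, rows of the weight matrix sum to one, and constant images
  are fixed points. No interpolation-kernel choice is left open.
* **Selective-sampling color criterion** reuses the background-filter
  thresholds — the only intensity bounds defined anywhere in the
  preprocessing — and the quadrant scan order is pinned to row-major.
* **Tumor fraction** is computed on the mask's own grid by flooring
  the box coordinates at the stated integer downsample factor; masks
  are never interpolated.
* **Freezing at ratio 0** leaves the embedding trainable too: a 0 %
  freezing configuration means a fully trainable model.
* **Balancing scope**: only the quantified patch-level rates (70 %/
  50 %) are applied, on training folds only; slide-level
  undersampling is deliberately not performed.
* **Batch sampling** reshuffles the balanced patch set every
  epoch-equivalent and consumes it in fixed-size chunks; AdamW uses
  the conventional decay 0.01 (recorded in the run config since the
  reference runs do not state one).
* **CV grouping**: slides of one patient never straddle the
  train/test boundary; stratification by subtype is secondary to
  grouping. Argmax ties in hard calls go to the lowest class index.
* **CIs** are normal-approximation across folds
  (`mean ± 1.96 sd/√k`, clipped to [0, 1]); a percentile bootstrap
  over slides is available (`bootstrap_ci()`) since the choice between
  the two conventions is not fixed by the protocol.
* **Undefined metric cells** (zero denominators in one-vs-rest
  confusion ratios) are reported as `NA` and excluded from macro
  averages with a warning, never silently coerced to 0.
* **Mean ROC curves** interpolate each fold's step curve linearly onto
  a fixed FPR grid (step 0.01) with endpoints pinned at (0,0) and
  (1,1); this affects plots only, never AUROC values.

## Problem sizes used by the tests and the acceptance script

The study cohort used for the end-to-end checks is 40 slides (10 per
class) of 2048 px at 0.549 µm/px, tumor coverage 0.85, 30 % two-slide
patients — about 80 patch triples — evaluated with patient-grouped
five-fold cross-validation under the desk profile. These sizes were
chosen so that a full run (generation, tiling, hierarchy, four
cross-validated model variants) completes in minutes on a single CPU
while keeping at least two test slides per class in every fold.

## Known limitations

* The tiny backbone's fixed statistical stem cannot represent
  morphology beyond local first- and second-order intensity structure;
  it is an instrument for validating the pipeline, not a pathology
  feature extractor.
* Pyramidal/vendor WSI formats are not parsed; slides are single-level
  TIFF/PNG rasters with resolution carried in the manifest.
* The weak-supervision assumption (every tumor patch carries the
  slide's subtype signal) is taken as given; no patch-level label
  cleaning is attempted.
* Training is single-threaded CPU; there is no learning-rate schedule,
  early stopping or augmentation, none being part of the reference
  procedure.
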