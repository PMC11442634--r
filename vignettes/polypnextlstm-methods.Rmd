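---
title: "PolypNextLSTM: model, metrics and verification strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PolypNextLSTM: model, metrics and verification strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Colonoscopy video gives a segmentation model something single frames
cannot: the same polyp seen across consecutive frames, under motion,
specular highlights and partial occlusion. PolypNextLSTM exploits that
redundancy with a deliberately lean design. A clip batch of shape
$B \times F \times 3 \times H \times W$ (batch, frames, RGB channels,
height, width) is processed in three parts:

1. **Pruned ConvNext-Tiny encoder.** The original four-stage
   ConvNext-Tiny carries $(3, 3, 9, 3)$ blocks at widths
   $(96, 192, 384, 768)$. Dropping the fourth stage and all
   classification layers leaves three stages of $(3, 3, 9)$ blocks at
   widths $(96, 192, 384)$ and cuts the trainable parameters from
   27.82 million to 12.35 million. Each ConvNext block is a residual
   unit: depthwise $7\times7$ convolution (padding 3), channels-first
   layer normalization, $1\times1$ expansion to $4C$, GELU, $1\times1$
   projection back to $C$, a learnable per-channel scale, then the
   skip addition. A $4\times4$ stride-4 patch embedding begins the
   encoder; between stages a layer-norm + $2\times2$ stride-2
   convolution halves resolution and doubles width. The encoder runs
   on the flattened $B\cdot F$ batch, so frames are encoded
   independently.
2. **Bidirectional ConvLSTM bottleneck.** At $1/16$ resolution, one
   ConvLSTM cell (input 384, hidden 192, $3\times3$ kernel, zero
   padding 1, all four gates from a single convolution over the
   concatenated input and hidden state, no peepholes) scans the frames
   first-to-last and a second independent cell scans last-to-first.
   Concatenating the two 192-channel hidden states per frame restores
   384 channels. This is the only module that sees the temporal axis,
   and it adds parameters independent of $F$.
3. **UNet-style decoder.** Transposed $2\times2$ stride-2 convolutions
   upsample $384\to192\to96$, each followed by concatenation with the
   matching encoder skip ($1/8$ and $1/4$) and a DoubleConv (two
   $3\times3$ conv + batch norm + ReLU, the first conv halving
   channels). A skip-free tail $96\to48\to24$ restores full resolution
   and a $1\times1$ convolution produces one pre-sigmoid logit map per
   frame ("many-to-many": $F$ masks for $F$ frames).

### The decoder width progression

Published figures fix the decoder's end ("from 24 to 1") but not the
full progression. We adopt
$384\to192(+\text{skip})\to96(+\text{skip})\to48\to24\to1$, with no
DoubleConv between the last two upsamples. This is the unique simple
progression whose closed-form parameter sum (about 1.64 M) makes
encoder + fusion + decoder round to the published 21.95 M total
(12.35 M + 7.96 M + 1.64 M); any added tail DoubleConv or different
widths breaks that budget. The package treats the total as a testable
claim: `verify_params()` checks all three counts against an
independent closed-form summation in the test suite.

## Training objective and metrics

The loss is an equally weighted sum of Dice loss and binary
cross-entropy,

$$\mathcal{L} = \underbrace{1 - \frac{2\sum_i p_i t_i + s}
{\sum_i p_i + \sum_i t_i + s}}_{\text{per frame, then averaged}}
\; + \; \operatorname{mean}_i\,\mathrm{BCE}(p_i, t_i),$$

with smoothing $s = 1$ (a standard choice; the published description
fixes neither $s$ nor the term weights). The smoothing cancels for a
perfect 0/1 prediction, so the loss is zero exactly at the target. The
BCE term is evaluated from logits in the numerically stable form.

Evaluation uses four metrics on binarized (threshold 0.5) predictions:

* **Dice** $2|P\cap G|/(|P|+|G|)$ and **IoU** $|P\cap G|/|P\cup G|$,
  both defined as 1 when both masks are empty. The identity
  $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ is enforced as a
  property test.
* **HD95**: boundary pixels are mask pixels with a 4-neighbour outside
  the mask or touching the image edge; the statistic is the maximum of
  the two directed 95th-percentile (linear interpolation) Euclidean
  boundary distances, computed with an exact distance transform and
  cross-checked against brute-force pairwise distances in the tests.
  Conventions for degenerate cases: both masks empty gives 0; exactly
  one empty returns the image diagonal as a finite sentinel, flagged
  on the value. Distances are in pixels at the evaluation resolution.
* **Recall** $TP/(TP+FN)$, 1 for empty ground truth.

Clip-level scores are means of per-frame scores; the test-set
aggregate is the unweighted mean over clips; mean Dice is additionally
stratified by the clips' visual attributes (each clip counts toward
every attribute it carries).

## Data pipeline

The reader expects SUN-SEG-style trees: one directory per clip with
`Frame/` and `GT/` images and an `attributes.csv` holding
semicolon-separated attribute ids. Rules implemented:

* **First clip per polyp**: training sets keep only the
  lexicographically first clip of each polyp case.
* **Windowing**: clips are cut into windows of $F = 5$ consecutive
  frames, stride $F$ by default; when the length is not divisible, a
  final window anchored at the clip end (overlapping its predecessor)
  covers the remainder, so every frame of every clip at least $F$
  frames long is covered. A 12-frame clip yields starts $\{0, 5, 7\}$.
  Whether training should instead sample overlapping windows is not
  specified anywhere we could verify; the stride is configurable.
* **Loading**: frames resize bilinearly to $256\times256$; masks use
  nearest-neighbour and re-binarize, which keeps the foreground
  fraction stable to within about two percentage points on smooth
  blobs. Intensity normalization is plain $[0,1]$ scaling by default,
  or the fixed ImageNet channel means/sds when a pretrained backbone
  convention is wanted.
* **Augmentation**: one random draw of (rotation, horizontal flip,
  vertical flip, centre-crop scale) per window, applied identically to
  all $F$ frames and masks. Magnitudes — rotation $\pm20^\circ$, crop
  scale 0.8–1.0 with resize back — are package defaults (configurable);
  the published description states the transform types but not their
  ranges.
* **Folds**: 5-fold cross-validation splits at clip level,
  deterministic under the seed.

Pretrained encoder weights are supported only as an opt-in flag; no
weights are downloaded and random initialization (truncated normal,
sd 0.02 in the encoder; He initialization in ConvLSTM and decoder;
layer-scale $10^{-6}$) is the default, so every test runs offline.

## Synthetic clips and attribute rules

The generator renders a soft-edged bright ellipse moving over a
smooth, reddish textured background, with optional occlusion bands and
colour-fringe ghosting; the ground truth is the hard ellipse interior.
It emulates exactly what the pipeline and the numeric attribute rules
need — object geometry, motion, scale change, artifacts — and nothing
about real mucosa: passing tests demonstrate correctness of the
machinery, not clinical performance.

The four numeric attribute rules are implemented at their printed
thresholds: **FM** if mean consecutive-frame centroid displacement
exceeds 20 px; **SO** if mean object/image area ratio is below 0.05;
**LO** if mean bounding-box/image ratio exceeds 0.15; **SV** if the
minimum pairwise bounding-box area ratio is below 0.5. The SV wording
("average area ratio among any pair") is ambiguous; the min-over-pairs
reading is adopted, since a single large scale change is what the tag
is meant to capture. Empty frames are excluded from the means; OCC,
GH and OV on generated clips are construction flags, and the
qualitative SI/IB/HO tags are out of the generator's scope.

## Numerical and implementation choices

The network runs on a small reverse-mode autodiff engine written for
this package: 4-D feature maps `(H, W, C, N)`, compiled im2col+GEMM
convolutions, depthwise and transposed-convolution kernels, and a tape
of vector-Jacobian closures. Gradients of every layer family are
tested against central finite differences. Batch norm uses
training-mode batch statistics with momentum-0.1 running estimates for
evaluation; layer norm normalizes over channels at each position
(ConvNext convention); initial ConvLSTM states are zeros. Training
uses Adam (default betas, $\epsilon=10^{-8}$) at a constant learning
rate of $10^{-4}$ — only the initial rate is published, so no schedule
is applied. Checkpoints are selected by validation Dice, evaluated on
each fold's held-out clips; a single checkpoint (not a fold ensemble)
is used at evaluation time.

Determinism: all randomness flows through R's RNG from a single seed
(weight init, shuffling, augmentation, fold splits), and the compiled
kernels are deterministic, so same-seed runs are bit-identical on the
same platform.

## Problem sizes used in the tests

Full-scale training (51 clips, 100 epochs, 256×256, GPU) is out of
scope by design; the suite verifies every claim that does not require
the SUN-SEG data. Parameter counts are exact and desk-scale. Shape
and symmetry properties run at 256×256 (single clip) and smaller.
The learning smoke test trains on one synthetic 5-frame clip at
64×64 — large enough for a realistic blob and the full /16 temporal
bottleneck, small enough for CPU — and must reach training Dice 0.95
within 300 Adam steps; it stops at the first validation point past
the target. Synthetic benchmark trees for pipeline tests use 32–64 px
frames; attribute-rule tests render at 256×256, where the printed
pixel thresholds have their natural scale.

## Known limitations

* No photorealistic simulation; domain transfer to real colonoscopy
  is untested here by construction.
* Pretrained ConvNext weights are not bundled; reproducing the
  published benchmark numbers additionally requires SUN-SEG and GPU
  training.
* HD95 resolution (evaluation pixels vs original resolution) is an
  interpretation; evaluation-resolution pixels are used.
* The published abstract and its benchmark table disagree slightly on
  one headline Dice value (0.7898 vs 0.7838 on the hard unseen set);
  nothing in this package depends on either number.
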