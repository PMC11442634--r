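# polypnextlstm

An R implementation of **PolypNextLSTM**, a lightweight network for
segmenting polyps in colonoscopy *video*. Single-frame segmentation
models ignore the strongest cue a video gives — the same polyp seen
across consecutive frames — while most video models pay for temporal
modelling with large parameter counts. PolypNextLSTM keeps the model
lean by combining:

* a **pruned ConvNext-Tiny encoder**: the original (3, 3, 9, 3)-block,
  four-stage backbone is cut to three stages of (3, 3, 9) ConvNext
  blocks at widths (96, 192, 384), dropping the trainable parameters
  from 27.82 M to 12.35 M;
* a **bidirectional ConvLSTM bottleneck**: one cell (input 384, hidden
  192, 3×3 kernels) scans the F frames forward, an independent cell
  scans them backward, and their hidden states are concatenated per
  frame — the only module that sees the temporal axis;
* a **UNet-style decoder** with skip connections at 1/4 and 1/8
  resolution (384→192→96→48→24→1), producing one mask per input frame
  ("many-to-many").

The full model has 21.95 M trainable parameters. Input clips are
arrays of shape B × F × 3 × H × W; encoder and decoder run on the
flattened B·F frame batch. Training minimizes Dice loss + binary
cross-entropy with Adam at learning rate 1e-4; evaluation reports
Dice, IoU, 95th-percentile Hausdorff distance (HD95) and recall, with
mean Dice stratified by per-clip visual attributes (fast motion,
small/large object, scale variation, occlusion, ...), whose numeric
definitions (20 px, 0.05, 0.15, 0.5 thresholds) are implemented as
checkable labelling rules.

Because the SUN-SEG dataset cannot be redistributed, the package
includes a synthetic clip generator (moving, deformable bright blobs
over textured backgrounds, with ground-truth masks and derived
attribute labels) so the entire pipeline — data loading, windowing,
augmentation, training, metrics — is testable offline on CPU. The
network runs on a small reverse-mode autodiff engine with compiled
(RcppArmadillo) convolution kernels; no deep-learning framework is
required.

## Worked example

```r
library(polypnextlstm)

# The pruning claim, verified by construction
verify_params()
#>           component parameters millions target pass
#> 1  reduced_backbone   12348000    12.35  12.35 TRUE
#> 2 unpruned_backbone   27818592    27.82  27.82 TRUE
#> 3        full_model   21950113    21.95  21.95 TRUE

# A synthetic clip: a blob moving ~25 px per frame, covering ~1% of the
# image, is labelled fast-motion (FM) and small-object (SO)
spec <- synth_clip_spec(n_frames = 8, image_size = c(256, 256),
                        velocity = c(18, 18), seed = 7)
clip <- render_clip(spec)
label_attributes(clip$masks)
#> [1] "FM" "SO"

# A 4-clip synthetic dataset, evaluated with an untrained model
dir <- tempfile()
make_benchmark_suite(dir, n_clips = 4, seed = 1,
                     image_size = c(64, 64), n_frames = 6)
recs <- scan_dataset(dir)
cfg <- train_config(frames = 5, image_size = c(64, 64))
model <- build_polypnextlstm(model_config(seed = 1))
evaluate_model(model, recs, cfg)
#> Metric report over 4 clip(s)
#>   mean dice 0.0958  iou 0.0527  hd95 34.69  recall 0.4811
#>   mean dice by attribute:
#>     SO   0.0456
#>     LO   0.2466
```

The untrained model scores near zero, as it should; `train_model()`
with a `train_config()` runs the seeded Adam/Dice+BCE loop with
5-fold clip-level cross-validation, per-epoch JSONL logs and
best-validation-Dice checkpointing. On a single synthetic clip the
model overfits to Dice > 0.95 within a few hundred steps (the test
suite enforces this as a learning smoke test).

A command-line front end in `inst/cli/polypnextlstm.R` wraps the same
functions (`synth`, `train`, `evaluate`, `predict`, `params`
subcommands).

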