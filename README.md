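# wunet

Binary segmentation of liver vessels in intraoperative ultrasound (IOUS)
video frames, built for surgical-guidance research: real-time IOUS shows
the hepatic vasculature during liver resection, but anechoic lumina,
multiplicative speckle, acoustic shadows and probe motion make the video
hard to read.  `wunet` implements a complete, reproducible pipeline —
frame quality filtering, patient-level dataset splits, a saliency-prior
("weight map") estimator, a two-input attention U-Net, per-vessel
training, and the standard pixel-wise metric suite — together with a
seeded speckle-phantom generator that replaces the (non-distributable)
clinical recordings in every test.

## The model in brief

The network is a U-Net whose encoder (five 3x3 stages with filters
32, 32, 64, 64, 128) is fused at four scales with a max-pooled pyramid
`w_l` of a per-pixel saliency prior `W ∈ [0,1]^{256×256}`.  At level
`l`, a *weighted block* projects the encoder features to the attention
width, max-pools them to `Q_l`, lifts `w_l` with a 1x1 convolution +
ReLU, adds the two element-wise, refines with 3x3 and 1x1 convolutions,
and squashes to per-pixel gate coefficients `X = ∂_y ∈ [0,1]`; the
gated skip

    O_l = X ∗ Q_l        (side 256/2^l, 128 channels)

feeds a symmetric decoder that ends in a 1x1 convolution + sigmoid
probability map at the input resolution.  Training follows a fixed
recipe: Adam, learning rate 0.001, batch size 16, no augmentation, one
binary model per vessel (IVC, hepatic veins, portal branches), strict
patient-level isolation between partitions.  The saliency prior is
estimated by a bound-constrained quadratic program over SLIC
superpixels (foreground likelihood + centroid-distance discount +
zero-saliency cost + graph-Laplacian smoothness), or loaded from
precomputed files.  Evaluation reports Dice, IoU, recall, precision,
accuracy and rank-based AUC-ROC as mean ± SD per vessel.  The methods
vignette (`vignettes/weighted-attention-unet.Rmd`) documents every
design decision and the phantom generator's scope.

## Worked example

Simulate a small phantom cohort, train one vessel model end to end, and
evaluate on held-out patients (one command; ~1 minute on a laptop CPU):

```r
library(wunet)
cfg <- run_config(seed = 19, preset = "easy", n_patients = 6,
                  clips_per_patient = 1,
                  phantom = phantom_preset("easy", image_side = 64,
                                           frames_per_clip = 10, seed = 19),
                  model = model_config(input_side = 64,
                                       encoder_filters = c(8, 8, 8, 8, 16),
                                       attention_channels = 8,
                                       decoder_filters = c(8, 8, 8, 8),
                                       head_channels = 8),
                  train = train_config(epochs = 12, seed = 19))
res <- run_end2end("run1", cfg)
res$metrics[, c("vessel", "n_frames", "dice_mean", "dice_sd", "iou_mean")]
```

```
  vessel n_frames dice_mean    dice_sd  iou_mean
1    IVC       10 0.9215138 0.01475863 0.8547606
```

The row reports the per-frame mean ± SD over the two held-out test
patients: a mean Dice of 0.92 means the predicted vessel masks
overlap the ground truth almost completely at this (easy-phantom)
difficulty; IoU relates to it exactly by Dice = 2·IoU/(1+IoU).  The run
directory gets the resolved YAML config, seed, patient split, quality
report, training history, checkpoint and `metrics.csv`, so the run can
be reproduced bit for bit.

The same pipeline is scriptable from a shell through the thin CLI
wrapper (`exec/wunet` once installed, or `Rscript exec/wunet`):

```sh
wunet simulate --out data --patients 22 --preset hard --seed 7
wunet preprocess --data data --out prep --seed 7
wunet end2end --out run2 --preset easy --seed 7
```

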