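# agrinet

Pixel-level identification of winter wheat and winter canola in 10-band
multispectral satellite imagery, with a lightweight attention-based
encoder-decoder network implemented natively in R.

Winter wheat and winter canola share a planting cycle and dominate winter
cropping across the middle and lower Yangtze basin; mapping them from
Sentinel-2 imagery is a three-class semantic segmentation problem
(background / canola / wheat) under a hard efficiency constraint — the model
must be small enough for low-end agricultural hardware. This package is for
remote-sensing and agricultural-informatics researchers who want a fully
inspectable, dependency-light reference implementation of that pipeline:
every layer, gradient and metric is ordinary R code backed by BLAS, checked
against independent oracles.

## What is inside

* **Preprocessing** (`select_bands`, `resample_to_10m`, `fuse`,
  `linear_stretch`, `harmonize`, `preprocess_scene`): screen the 60 m
  Sentinel-2 bands (B1/B9/B10), bilinearly resample the 20 m bands to 10 m,
  fuse to a fixed-order 10-channel stack, and harmonize scenes by the
  percentage linear stretch
  `result = (DN - min_in)/(max_in - min_in) * (max_out - min_out) + min_out`.
* **Dataset construction** (`tile_scene`, `filter_coverage`, `split_tiles`,
  `augment_tile`): 512x512 tiling, removal of tiles with crop coverage
  below 30 %, seeded 7:3 train/validation splits, and label-safe
  augmentation (90-degree rotations, mirrorings, additive Gaussian noise on
  the image only).
* **The network** (`network_config`, `agrinet_model`, `agrinet_forward`,
  `predict`): a ShuffleNet v2 encoder (channel split, depthwise
  convolutions, channel shuffle; truncated after Stage3 at output stride
  16) feeding atrous spatial pyramid pooling (dilations 6/12/18), a
  convolutional block attention module
  `M_c(F) = sigma(MLP(AvgPool F) + MLP(MaxPool F))`,
  `M_s(F) = sigma(f7x7[AvgPool F; MaxPool F])`, and a skip-fusion decoder
  ending in a stride-2 transpose convolution. Forward and backward passes
  are hand-derived and finite-difference checked.
* **Training** (`train_config`, `train_agrinet`): per-pixel multi-class
  cross-entropy (`-sum_i y_i log yhat_i`, pixel mean), Adam, polynomial
  learning-rate decay `lr = base_lr (1 - epoch/max_epoch)^0.9`, on-the-fly
  augmentation, best-validation-mIoU model selection, bitwise-reproducible
  histories under a seed.
* **Evaluation** (`confusion_matrix`, `miou`, `overall_accuracy`, `recall`,
  `evaluate_agrinet`): mIoU = mean_i |P_i ∩ G_i| / |P_i ∪ G_i|, OA =
  trace/sum, macro recall = mean_i TP_i/(TP_i + FN_i), aggregated over the
  split's pooled confusion matrix.
* **Complexity profiling** (`complexity_profile`, `count_params`,
  `count_flops`, `compare_configs`): per-convolution accounting
  `params = K^2 C_in C_out`, `FLOPs = K^2 C_in H_out W_out C_out`
  (depthwise layers use `C_in/groups`), traced symbolically at any input
  size.
* **Synthetic fixtures** (`fixture_spec`, `generate_scene`,
  `generate_ds_like`): deterministic scenes of rectangular crop fields
  separated by thin background roads, with class-specific 10-band
  signatures plus Gaussian noise — the whole pipeline is testable without
  any satellite downloads.
* **CLI** (`inst/cli/agrinet.R`): `preprocess`, `build-dataset`,
  `make-fixtures`, `train`, `evaluate`, `predict`, `profile` subcommands
  over the same functions.

## Worked example

Profile the default network (10 input channels, 3 classes, CBAM on) at
512x512:

```r
library(agrinet)
complexity_profile(network_config(), 512)
#> Complexity report (full, input 512x512)
#>   parameters: 3,887,186 (3.89 M), + 11,940 itemized bias/BN
#>   FLOPs: 47,490,807,808 (47.49 GFLOPs)
#>   heaviest layers (FLOPs):
#>     refine2                  24.348 G
#>     refine1                  19.365 G
#>     head.tconv                1.082 G
#>     aspp.atrous_d6            0.547 G
#>     aspp.atrous_d12           0.547 G
```

3.89 M parameters and ~47.5 GFLOPs: the headline totals count one
multiply-accumulate per kernel tap over a symbolic trace of the forward
pass; the 11,940 bias/batch-norm parameters that the convention omits are
itemized separately, and headline + itemized equals the exact tally of
every stored weight array. Removing the attention module
(`network_config(use_cbam = FALSE)`) drops 8,290 weights to 3.88 M — the
gates are almost free, which is the point of CBAM.

Train a width-reduced configuration on easy synthetic fields (40 tiles of
64x64, distinct class signatures) and evaluate it:

```r
spec <- fixture_spec(scene_hw = 64, n_fields = 9, seed = 11)
ds   <- generate_ds_like(spec, 40, coverage_threshold = 0.30)
cfg  <- network_config(stage_out_channels = c(8L, 16L, 32L),
                       stage_repeats = c(2L, 2L),
                       aspp_dilations = c(1L, 2L, 3L),
                       aspp_out_channels = 32L, cbam_reduction = 8L,
                       skip_reduce_channels_low = 8L,
                       skip_reduce_channels_mid = 8L,
                       decoder_refine_channels = c(32L, 16L), seed = 7)
fit <- train_agrinet(agrinet_model(cfg), ds$tiles, NULL,
                     train_config(max_epoch = 30, seed = 5))
print(fit)
#> Trained crop-segmentation network
#>   30 epochs; best validation mIoU 0.9873 at epoch 30
#>   final train loss 0.1041; validation OA 0.9936, recall 0.9936

ev <- evaluate_agrinet(fit, ds$tiles, fit$manifest$val_ids)
round(c(miou = ev$miou, oa = ev$oa, recall = ev$recall), 3)
#>  miou     oa recall
#> 0.987  0.994  0.994
```

A validation mIoU of ~0.99 on noiseless-ish synthetic fields says the
optimizer, gradients and metrics work — it is an upper bound scenario, not
a claim about real scenes (see the methods vignette,
`vignettes/crop-identification.Rmd`, for what the fixtures do and do not
emulate). `predict(fit, tile$image)` returns a `{0,1,2}` label matrix.

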