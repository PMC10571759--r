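# akuseg

Semantic segmentation of actinic keratosis (AK) in wide-field clinical
photographs. AK lesions are precancerous keratinocyte lesions of
sun-damaged skin: low-contrast pink/red/brown patches with fuzzy
boundaries, scattered across a cancerization field that also contains
visually dominant confusers (hairs, seborrheic keratoses, solar
lentigines). `akuseg` is for researchers who need a complete,
dependency-light, testable implementation of a recurrent-skip U-Net
pipeline for this problem: training on lesion-box crops, tiled
inference over whole photographs, and region-tolerant evaluation.

## What is inside

**Model.** A U-Net whose encoder follows the first four VGG16 blocks
(widths F, 2F, 4F, 8F) and whose skip connections are fused by a
convolutional LSTM instead of plain concatenation: the concatenated map
X^l is split into an n x m patch grid and the recurrence

    i_t = sigma(W_xi * P_t + W_hi * H_{t-1} + W_ci . c_{t-1} + b_i)
    f_t = sigma(W_xf * P_t + W_hf * H_{t-1} + W_cf . c_{t-1} + b_f)
    c_t = f_t . c_{t-1} + i_t . tanh(W_xc * P_t + W_hc * H_{t-1} + b_c)
    o_t = sigma(W_xo * P_t + W_ho * H_{t-1} + W_co . c_t + b_o)
    H_t = o_t . tanh(c_t)

walks the patches in raster order (`*` = same-padded convolution, `.` =
Hadamard product; the output gate peeks at the new cell state). The
reassembled hidden maps feed a batch-normalized decoder ending in a
sigmoid 1x1 head. `skip_fusion = "concat"` instantiates the plain
U-Net baseline. The network, backpropagation (including BPTT through
the fused skips) and AdamW are implemented natively in R over BLAS
matrix products, and every gradient is finite-difference-verified in
the test suite.

**Metrics.** Dice and IoU, plus the region-tolerant family for roughly
annotated lesions: a ground-truth region counts as detected (TPC) from
a single intersecting pixel, aRec = TPC/N, aPrec = true-positive area /
total predicted-positive area, and aF1 their harmonic mean.

**Pipeline.** Lesion-centered boxes with translation augmentation and
two-stage 0.5x rescaling (512-px boxes at half scale, 256-px network
crops, ~5 px/mm); patient-level splits with leakage asserted;
zero-pad / tile / aggregate wide-field inference; a seeded synthetic
generator of skin-like scenes with exact ground truth so everything is
testable offline.

## Worked example

Train the small recovery configuration on synthetic data and evaluate
on held-out patients:

```r
library(akuseg)

sc  <- scene_config(height = 256L, width = 256L, n_lesions = c(1L, 3L),
                    lesion_diameter_mm = c(6, 16), contrast = c(0.15, 0.30),
                    seed = 1L)
ds  <- generate_dataset(10L, 2L, sc)
man <- split_by_patient(ds$images, c(train = 0.6, val = 0.2, test = 0.2), seed = 1L)
cs  <- build_crop_sets(ds$images, man, side = 128L, final_side = 64L,
                       n_offsets = 3L, seed = 1L)

m <- build_model(aku_model_config(input_side = 64L, base_filters = 8L,
                                  convlstm_grid = c(2L, 2L), seed = 1L))
m <- fit_akunet(m, cs$train, cs$val,
                train_config(batch_size = 8L, epochs = 3L, seed = 1L),
                verbose = TRUE)
#> epoch 1: train 0.7431 val 0.6639 dice 0.272
#> epoch 2: train 0.5583 val 0.4988 dice 0.548
#> epoch 3: train 0.4624 val 0.4510 dice 0.694

mean(sapply(cs$test, function(cr)
  dice_coef(predict(m, cr$image, type = "mask"), cr$mask)))
#> [1] 0.801938
```

The training loss falls monotonically, validation Dice climbs, and the
held-out crops from the two test patients — never seen in any form —
reach a mean Dice of 0.80. The identically budgeted `"concat"` baseline
reaches 0.58 on the same split, reproducing the architecture ordering.
For a whole photograph, `predict_wide()` pads, tiles, predicts and
reassembles:

```r
img  <- rescale_half(ds$images[[1]])
prob <- predict_wide(img$image, m)
evaluate_pair(prob, img$mask, threshold = 0.5)
```

`run_end_to_end(smoke_run_config())` composes all stages
(synthesize -> split -> crop -> train -> tiled predict -> score) and
writes the resolved config, split manifest, history and metrics report
to a run directory. A thin CLI over the same functions lives at
`inst/cli/akuseg.R` (subcommands `synth`, `crops`, `train`, `predict`,
`score`).

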