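---
title: "Segmenting actinic keratosis in wide-field photographs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting actinic keratosis in wide-field photographs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Actinic keratosis (AK) is a precancerous keratinocyte lesion of
chronically sun-exposed skin. Quantifying the AK burden over a whole
cancerization field — rather than grading isolated lesions — requires
finding every affected region in a wide-field clinical photograph. Two
properties make this hard for ordinary segmentation pipelines: AK
presents as low-contrast pink/red/brown patches with ambiguous
boundaries, and the surrounding field is littered with confusers
(hairs, telangiectasias, seborrheic keratoses, solar lentigines) that
are locally far more salient than the target. `akuseg` implements a
complete, self-contained pipeline for this problem: a recurrent-skip
U-Net, lesion-box patch extraction, tiled wide-field inference, and
region-tolerant evaluation, plus a synthetic scene generator that makes
every stage testable without clinical data.

## Network architecture

The segmenter is a U-Net: a contracting encoder and an expanding
decoder joined by skip connections at matching resolutions. The encoder
follows the first four VGG16 convolution blocks — 3x3 convolutions with
ReLU, 2x2 max pooling between blocks, widths
$F, 2F, 4F, 8F$ with $F = 64$ at full size — so ImageNet-pretrained
VGG16 kernels can be dropped in when a local copy is available
(`pretrained_weights`); tests and default builds use seeded He
initialization, and nothing ever downloads.

The departure from a plain U-Net is in the skip connections. Let
$X_e^l$ be the encoder map at level $l$ and $X_d^{l,up}$ the
transposed-convolution upsampling of the decoder map from below. Their
channel concatenation $X^l$ is split into an $n \times m$ grid of
patches $P_{i,j}$ with $h_p = h_l/n$, $w_p = w_l/m$, and a
convolutional LSTM walks the patch sequence $P_t$ in raster order:

$$i_t = \sigma(W_{xi} * P_t + W_{hi} * H_{t-1} + W_{ci} \odot c_{t-1} + b_i)$$
$$f_t = \sigma(W_{xf} * P_t + W_{hf} * H_{t-1} + W_{cf} \odot c_{t-1} + b_f)$$
$$c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_{xc} * P_t + W_{hc} * H_{t-1} + b_c)$$
$$o_t = \sigma(W_{xo} * P_t + W_{ho} * H_{t-1} + W_{co} \odot c_t + b_o)$$
$$H_t = o_t \odot \tanh(c_t)$$

where $*$ is same-padded 2-D convolution and $\odot$ the Hadamard
product. Note the output gate's peephole reads the *new* cell state
$c_t$; we implement the recurrence exactly in this form (it is also the
form validated against a literal equation oracle in the tests). The
hidden outputs $H_t$ are placed back at their grid positions, and the
reassembled K-channel map — not the raw concatenation — feeds the
decoder convolutions. The intent is contextual: each patch's features
are modulated by an accumulated memory of the patches already scanned,
which helps commit to low-contrast boundaries that are ambiguous
locally. Every decoder convolution is followed by batch normalization
and ReLU, and a 1x1 convolution with a sigmoid produces per-pixel
foreground probabilities. Setting `skip_fusion = "concat"` swaps the
fusion for plain concatenation, yielding the baseline U-Net with an
otherwise identical encoder/decoder — the comparison pair used in the
tests.

### Choices the architecture description leaves open

Several details are genuinely underdetermined, and we fixed them as
follows (all are recorded in `aku_model_config()` so experiments are
reproducible):

- **Patch grid**: default $(4, 4)$ per skip level, configurable. It
  divides all skip resolutions of a side-256 input and yields a
  16-step sequence — long enough for the recurrence to matter.
- **Scan order**: row-major raster, single direction. No bidirectional
  pass.
- **Hidden channels**: $K = F_l / 2$, i.e. the encoder width at that
  level — the fused map halves the concatenation's channels exactly as
  a standard decoder stage would.
- **Per-step hidden sequence vs final state**: the fusion uses the full
  hidden sequence reassembled spatially, and its output *replaces* the
  concatenation rather than being re-concatenated to it. The
  alternative (only $H_{nm}$) would discard spatial correspondence
  altogether, which is incompatible with a skip connection's purpose.
- **Gate kernels**: 3x3 for all gate paths (the convLSTM literature
  default). Peephole weights are full elementwise tensors with the
  shape of the state, zero-initialized; the forget-gate bias starts at
  1 so early training does not erase the cell state.
- **Initial state**: $H_0 = c_0 = 0$.
- **Upsampling**: transposed convolution, kernel 2, stride 2, followed
  by BN and ReLU.
- **BN placement**: after each decoder convolution, before ReLU, the
  convention of the original BN formulation.
- **Input scaling**: pixels in $[0, 1]$; a VGG16 mean-subtraction mode
  is only meaningful when pretrained kernels are loaded.
- **Binarization threshold**: 0.5, configurable.

## The computational engine

All layers — im2col convolutions backed by BLAS matrix products, 2x2
max pooling, transposed convolutions, batch normalization, the convLSTM
recurrence with backpropagation through time, and AdamW — are
implemented natively in R as part of the package. Every backward pass
is hand-derived and verified against central finite differences in the
test suite, at the layer level and through the fully assembled network
(tolerance $10^{-6}$ on sampled parameters of a micro model). Two
numerical conventions matter:

- **Normalization statistics** are computed per sample over spatial
  positions during training (samples are processed with gradient
  accumulation within each mini-batch); exponential running moments
  (momentum 0.9) serve inference. This is the instance-style variant of
  batch normalization; it keeps training exactly reproducible for any
  batch size.
- **Max-pool ties** route the gradient to the first maximal element in
  a fixed cell order, making training deterministic.

Training minimizes the pixel-averaged binary cross-entropy
$L(p, y) = -y \log p - (1 - y)\log(1 - p)$ with predictions clipped to
$[10^{-7}, 1 - 10^{-7}]$, using AdamW with learning rate $10^{-3}$ and
decoupled weight decay $10^{-6}$ applied to convolution kernels only.
The published budget of "100 iterations" at batch 32 is read as 100
epochs — 100 gradient steps cannot traverse a 16k-crop training pool —
and both readings remain runnable through `train_config()`. Model
selection keeps the best-validation-Dice epoch; there is no early
stopping.

## Patch pipeline and wide-field inference

High-resolution photographs are not fed to the network whole. For
training, images are rescaled by 0.5, square lesion boxes (512 px at
that scale) are cut — one centered on each connected annotated region,
plus `n_offsets` translation-shifted copies whose windows must still
intersect the source region — and each crop is rescaled by 0.5 again to
the network input (256 px, about 5 px/mm). Masks are always resampled
nearest-neighbor so they stay binary. The number of translation offsets
per lesion is not recoverable from the published crop counts alone; the
default of 8 gives a crop-to-image ratio of the same order. The maximum
shift defaults to a quarter of the box side, which varies perilesional
context while keeping the lesion inside the window. Boxes are clamped
at image borders at extraction time; zero padding is reserved for
inference. Splits are assigned at the patient level (seeded
largest-remainder allocation of whole patients), and the leakage
invariant — no patient in two splits — is asserted on every manifest
and again inside `fit_akunet()`. Test crops are lesion-centered only.

For wide-field inference, `plan_tiling()` computes the minimal
near-symmetric zero padding that makes tiles of the network side (with
stride `tile - overlap`) cover the frame exactly; per-tile
probabilities are placed back at their origins and averaged where tiles
overlap, then the padding is cropped away. The default is non-overlapping
tiles — pure mosaicking, matching the published procedure — with
overlap-averaging available for seam suppression. When the padding on
an axis is odd the extra pixel goes to the bottom/right; tests pin this
convention. `detect_regions()` optionally drops components below a
minimum area; its default of 0 reflects that no such filter is part of
the published procedure.

## Evaluation metrics

Pixel metrics are the Dice coefficient $2|A \cap B| / (|A| + |B|)$ and
IoU $|A \cap B| / |A \cup B|$, related by
$\mathrm{Dice} = 2\,\mathrm{IoU} / (1 + \mathrm{IoU})$ — an identity the
suite asserts on every random pair. Because clinicians annotate AK
roughly, the package also implements the region-tolerant family: with
annotated regions $AK_1, \dots, AK_N$ (connected components of the
ground-truth mask) and predicted set $AK_{pred}$,

$$\mathrm{TPC} = \sum_{i=1}^{N} \mathbf{1}[AK_i \cap AK_{pred} \neq \emptyset],
\qquad a\mathrm{Rec} = \mathrm{TPC}/N, \qquad
a\mathrm{Prec} = \frac{|AK_{area} \cap AK_{pred}|}{|AK_{pred}|},$$

and $aF1$ is their harmonic mean. The $a\mathrm{Prec}$ denominator is
the *total predicted-positive area*, following the metric's verbal
definition. A region counts as detected from a single intersecting
pixel, so $aF1$ forgives imprecise extent while $a\mathrm{Prec}$ still
punishes false-positive area. Conventions at the boundaries: two empty
masks score Dice = IoU = 1; $a\mathrm{Rec}$ is undefined (NA) when
$N = 0$, $a\mathrm{Prec}$ when the prediction is empty, $aF1$ when
either is, and $aF1 = 0$ when both inputs are zero. Aggregation over a
test set is the unweighted mean over crops where the metric is defined,
with the exclusion count reported — so batch averages never divide by
zero silently. Region decomposition uses 8-connectivity by default
(annotation strokes often touch only diagonally); the labeling is a
deterministic flood fill, cross-checked in the tests against an
independent label-propagation oracle and, for 4-connectivity, against
`EBImage::bwlabel`.

One published consistency note: the baseline U-Net row of the
architecture comparison reports a mean Dice below its mean IoU, which
the identity above rules out for any common aggregation; that table's
absolute values are therefore not a reproduction target anywhere in
this package.

## The synthetic scene generator

`generate_scene()` renders the appearance regime the method is designed
for, not photorealistic skin: a per-patient skin tone modulated by
multi-octave smooth noise and a mild vignette; lesions as rotated,
anisotropic superellipses with a reddish-brown shift whose boundary is
Gaussian-blurred (fuzzy edges), at 5 px/mm with diameters defaulting to
4–16 mm; and distractors that are deliberately *not* in the mask —
dark hair-like quadratic curves and small sharp high-contrast discs
mimicking seborrheic keratosis/lentigo confusers. The ground-truth mask
is the sharp pre-blur support, mirroring the rough character of
clinical annotations. The configured contrast is realized exactly as
the mean luminance offset over the support (the edge blur is
compensated), which is what the calibration test measures. Distractors
are masked off lesion pixels by construction. Scenes are bitwise
deterministic given their seed; patients occupy consecutive seed blocks
of 1000 with a shared skin tone, so patient-level splitting is
exercised meaningfully.

What the generator does *not* emulate — specular highlights, anatomical
structure (eyes, nostrils, hairlines), perspective, camera noise, and
the full morphological variety of AK — bounds what passing tests mean:
they demonstrate that the pipeline recovers low-contrast fuzzy targets
among high-contrast distractors under controlled conditions, not
clinical-grade accuracy.

## Problem sizes used by the test suite

The suite trains genuinely, so sizes are chosen for a single CPU: the
recovery fixture uses 10 synthetic patients x 2 scenes of 256 px
(split 6/2/2 by patient), ~100 training crops of 64 px via the
two-stage pipeline (box 128 at half scale, 3 translation offsets), and
a narrow network (base filters 8, 2x2 fusion grid, ~0.34 M parameters)
trained 3 epochs at batch 8 with the default optimizer settings. Under
this budget the convLSTM model reaches held-out Dice >= 0.70 and
scores at or above the identically budgeted concat baseline — the
published architecture ordering reproduced as a property. The
end-to-end smoke configuration (`smoke_run_config()`) is smaller still
and exists to verify stage composition, not accuracy.

## Known limitations

- Training at the published full scale (256-px crops, base 64, 100
  epochs, 16k crops) is expressible in configuration but impractical in
  plain R; the engine is intended for method verification and
  small-scale experiments.
- Batch normalization uses per-sample spatial statistics rather than
  cross-sample batch statistics; with the small batches used here the
  practical difference is minor, but exact numerical parity with
  GPU-framework training should not be expected.
- The generator's lesions are simply connected; `extract_regions()`
  handles arbitrary topology, but the recovery fixture never exercises
  annotations with holes.
- Pretrained-encoder initialization requires a locally provided weight
  file; no download path exists by design.
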