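---
title: "Multi-encoder segmentation with wavelet fusion and global context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-encoder segmentation with wavelet fusion and global context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`waveseg` implements a five-level multi-encoder/single-decoder convolutional
network for multimodal brain-tumor segmentation in the BraTS convention.
Each of the four MR modalities (T1, T1ce, T2, FLAIR) has its own encoder:
the modalities carry complementary tissue contrast, and separate encoders
(late fusion) let each branch specialise before any mixing happens.  Two
components distinguish the architecture from a plain multi-branch U-Net:

**Wavelet fusion module (WFM).**  At every level the four per-modality
feature maps $X_1,\dots,X_4$ are merged in the wavelet domain:

$$F = \mathrm{IDWT}\!\big(f(\mathrm{DWT}(X_1),\dots,\mathrm{DWT}(X_4))\big),
\qquad X_i' = X_i + F, \qquad
\mathrm{Output} = \mathrm{Concat}(X_1',\dots,X_4').$$

The single-level separable 3D DWT splits each channel into one low-frequency
subband ($X_{LLL}$, the coarse appearance) and seven high-frequency subbands
(edges and texture).  The fusion rule $f$ averages the low-frequency
coefficients and **sums** the high-frequency ones, so fine detail from any
modality is accentuated rather than diluted.  The fused map is added back to
each branch (a residual enhancement) and the four enhanced maps are
concatenated and reduced by a $1{\times}1{\times}1$ convolution to form the
decoder skip (levels 1–4) or the bottleneck (level 5).  The module has no
trainable state.

**Global context-aware module (GCAM).**  Convolutions see only local
neighbourhoods; at the two deepest levels each encoder branch therefore
carries a light global-attention block:

$$L_{\mathrm{context}} = S \otimes \mathrm{softmax}(\mathrm{Conv}_{1\times1\times1}(S)),\quad
L_{\mathrm{trans}} = \mathrm{Conv}_{1\times1\times1}(\mathrm{ReLU}(\mathrm{LN}(\mathrm{Conv}_{1\times1\times1}(L_{\mathrm{context}})))),\quad
L_{\mathrm{fusion}} = S + L_{\mathrm{trans}}.$$

A scalar key per spatial position is softmax-normalised over **all**
positions, giving one pooled context vector per volume; a bottleneck
transform (ratio $r$, layer-normalised) maps it back to $C$ channels, and the
result is broadcast-added everywhere.  The update is spatially constant per
channel, which is both the point (global context) and a cheap invariant to
test.  Cost is linear in the number of voxels, unlike full pairwise
self-attention.

The training objective is the sum of binary cross-entropy and soft Dice,

$$L_{\mathrm{BCE}}(u,v) = -(u\log v + (1-u)\log(1-v)),\qquad
L_{\mathrm{Dice}}(u,v) = 1 - \frac{2|u\cap v| + \varepsilon}{|u|+|v|+\varepsilon},\qquad
L = L_{\mathrm{BCE}} + L_{\mathrm{Dice}},$$

computed per region channel and averaged.  The three output channels are
*independent sigmoids* for the nested regions WT $\supseteq$ TC $\supseteq$
ET — the regions overlap, so a mutually exclusive softmax would be wrong.

## Design choices where the design was open

Several details are not pinned down by the architecture description; the
package fixes them as follows.

* **Wavelet family** — orthonormal Haar (`db1`), single level, periodized
  boundaries on even extents.  Haar is exact, shape-preserving, conserves
  energy, and costs almost nothing inside a training loop; the family is
  configurable (`db2` is built in) and odd extents are symmetric-padded with
  the original shape recorded.  Inside the network the fusion operator is
  applied through a batched equivalent path (one transform of the summed
  stack, low band scaled by 1/4), which is algebraically identical to
  fusing the four transforms and is tested against the literal composition.
* **High-frequency rule** — plain summation, as specified; summation can
  grow magnitudes by up to 4x, and no renormalisation is applied because the
  following 1x1x1 reduction convolution can rescale.  `high_freq_rule`
  offers `mean` and `max` as alternatives (`max` for inference-time use
  only, as it is not linear).
* **Channel schedule** — (16, 32, 64, 128, 256) per encoder by default,
  doubling per level, scaled by `base_channels`.  The published architecture
  does not state widths, so the parameter report is informational, not a
  target.
* **Normalisation** — group normalisation (8 groups, falling back to one
  group when the width is not divisible): batch size is 1, so batch
  statistics are unusable.
* **Down/up-sampling** — stride-2 3x3x3 convolutions down; trilinear
  interpolation (half-voxel aligned) up, followed by concatenation with the
  skip and a residual block.
* **GCAM placement and ratio** — one block after the residual block of
  levels 4 and 5 in every encoder branch, none in the decoder; bottleneck
  ratio r = 4.  The output transform is **zero-initialised** so every block
  starts as an exact identity: early training is stabilised and the
  identity is a sharp initialisation test.  (A consequence worth knowing:
  at step 0 the upstream attention parameters receive zero gradient until
  the output transform moves off zero; `init_model(..., gcam_zero_init =
  FALSE)` exists for connectivity audits.)
* **Residual block** — two conv+GN+ReLU stages plus an identity skip
  (1x1x1 projection when widths change), summed without a final activation
  so that the zero-weight block is exactly the identity.
* **Region decoding** — sigmoid channels are thresholded at 0.5 and decoded
  with precedence ET > TC > WT, which resolves any voxel where the three
  channels disagree with the nesting.
* **Loss constants** — Dice smoothing epsilon 1e-5, logarithm clipping floor
  1e-7; neither is stated in the reference protocol.
* **Loss gradient in logit space** — inside the training graph the BCE term
  is differentiated with respect to the logits, `(v - u)/N`, rather than
  chained through the clipped sigmoid.  The loss *value* is identical; the
  gradient is not: with the probability-space form, a head that saturates
  towards "all background" early in training sits where
  `dL/dlogit = dL/dv * v(1-v)` vanishes and the collapse is permanent,
  whereas the logit-space form keeps a unit-scale restoring gradient.  The
  exported `bce_loss()`/`dice_loss()`/`total_loss()` operate on
  probabilities as defined; `total_loss_grad()` audits the analytic
  gradients against finite differences.
* **Polynomial decay power** — 0.9, the conventional value.
* **Awkward shapes at inference** — volumes whose extents are not divisible
  by 16 are zero-padded and cropped back rather than tiled; at the scale of
  this package's phantom studies the padded border never contains tumor,
  and padding keeps the prediction path single-pass and exactly
  reproducible.

## Pre- and post-processing protocol

Z-score normalisation (`Z = (m - mu)/sigma`) is computed per modality over
the *nonzero* voxels only — BraTS-style volumes are skull-stripped, and
including the zero background would let empty space dominate the statistics.
The population standard deviation is used, and background voxels remain
exactly zero.  Augmentation mirrors each axis independently with
probability 0.5 and perturbs foreground intensities as
`(v + delta * sd_fg) * s` with `delta ~ U(-0.1, 0.1)` and
`s ~ U(0.9, 1.1)`; the published factor 0.1 does not say whether the shift
is additive or multiplicative, so the package applies both, each controlled
by the same factor.  Random crops draw one shared offset uniformly for
channels and labels; splits are case-level (never slice-level) to avoid
leakage, with `|train| = round(0.8 n)` at the default 4:1 ratio.

Post-processing follows the champion protocol for the enhancing-tumor
region: if a predicted volume contains fewer than 200 ET voxels *in total*,
all of them are relabelled to necrosis (strictly fewer — 200 voxels are left
untouched).  The total-count reading matches the cited protocol; a
per-connected-component variant is available behind `per_component = TRUE`.

Evaluation reports the Dice coefficient `2TP/(2TP + FP + FN)` and the
symmetric 95th-percentile Hausdorff distance over surface voxels, computed
with an exact Euclidean distance transform.  Empty-mask conventions follow
evaluation-platform practice (both empty → 0; exactly one empty → 373.13),
and `percentile = 100` recovers the classical Hausdorff distance.

## The synthetic phantoms

Real BraTS data cannot ship with a package, so every stage is exercised on
synthetic multimodal phantoms: an ellipsoidal brain on an exactly-zero
background, containing three nested axis-aligned ellipsoids with a jittered
common centre — edema (label 2) around tumor core, the enhancing rim (label
4), and necrosis (label 1) innermost, so all three evaluation regions are
non-empty by default.  Per-modality mean intensities reproduce the
qualitative BraTS appearance (edema bright on T2/FLAIR, the enhancing rim
bright on T1ce, necrosis dark on T1), with i.i.d. Gaussian noise (default
sd 4 against inter-region contrasts of 10–85) and an optional smooth
multiplicative bias field behind a flag.

Ellipsoids were chosen over deformed meshes deliberately: membership in an
axis-aligned ellipsoid can be recomputed exactly by an independent scan of
the voxel grid, which turns the generator itself into an oracle for the
label-encoding and metric tests.  What the phantoms do *not* emulate —
infiltrative boundaries, multifocal disease, registration artifacts, MR
physics — bounds what passing tests show: they validate the implementation
(shapes, gradients, losses, metrics, the full training loop), not clinical
segmentation quality on real gliomas.

## Numerical scale of the shipped studies

Tests and the acceptance script run on one CPU, so problem sizes are chosen
where the mathematics, not the hardware, is the object under test: wavelet
and attention properties on 8³–16³ volumes, metric oracles on masks with a
few hundred surface voxels, and one end-to-end study that overfits the
network (base width 8) on four noise-free 32³ phantoms for 200 Adam steps at
learning rate 1e-3 — a deliberately scaled-down problem whose success
criterion is a training whole-tumor soft Dice of at least 0.8.  The
generator accepts the full 240x240x155 BraTS geometry and the trainer the
full 128³-crop/100-epoch protocol unchanged; they are simply not exercised
at that scale in the shipped suite.

## Known limitations

* Training runs on the CPU through the package's own reverse-mode tape;
  it is suitable for phantom-scale studies and method development, not for
  GPU-scale training on the real BraTS corpus.
* The `max` high-frequency rule has no gradient path and is rejected inside
  the training graph.
* Checkpoints are R serialisations (`.rds`); there is no interchange format
  for weights.
* Tiled inference with overlap averaging is not implemented; out-of-grid
  shapes are zero-padded instead.
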