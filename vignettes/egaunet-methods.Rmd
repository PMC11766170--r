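---
title: "EGAUNet: model, training procedure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EGAUNet: model, training procedure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the scientific and numerical choices behind the
package: the model and its assumptions, the parameters that matter, what the
synthetic phantoms do and do not establish, and the places where the design
was genuinely open and a decision had to be made.

## Problem setting

Multi-organ segmentation of 2-D medical images — here abdominal MRI slices
with labels background/liver/right kidney/left kidney/spleen — under two
practical constraints: annotated data are scarce, and models must be small
and fast enough for routine use. The architecture addresses the second
constraint with ghost convolutions (half the channels computed densely, half
by cheap depthwise transforms) and a slim decoder; the first is addressed by
an adversarial training signal that rewards segmentation maps which are
statistically indistinguishable from expert masks.

## Model

**Encoder.** A 3×3 stride-2 stem to 16 channels, then five stages of ghost
bottlenecks with depths (2, 2, 2, 6, 5) and widths (16, 24, 40, 112, 160);
each of stages 2–5 starts with one stride-2 bottleneck, all other blocks are
stride 1 (this placement is forced by the published per-stage output sizes).
For a 256×256 input the stages emit (16, 128²), (24, 64²), (40, 32²),
(112, 16²), (160, 8²).

A stride-1 bottleneck with equal in/out widths uses an identity shortcut; a
stride-2 or width-changing bottleneck projects the shortcut with a depthwise
3×3 (stride matched) plus a pointwise convolution, and inserts a depthwise
stride-2 convolution between the two ghost modules. Batch normalisation
follows every convolution; ReLU is applied in the first ghost module only
(the projection module is linear, following inverted-residual practice).
Normalisation uses batch statistics in training mode and stored running
statistics in eval mode, making inference deterministic.

**GSCA.** Skip features (and the deepest feature) pass through Global
Spatial-Channel Attention. The channel branch forms a global context vector
by softmax-pooling over positions and re-excites it through a two-layer 1×1
bottleneck with layer normalisation in between; the spatial branch forms a
per-pixel score by channel-softmax-weighted mixing and normalises it with a
spatial softmax. Both branches are added residually:
`Eout = Ein + E4 + E6`. Every softmax here is a true softmax (no sigmoids);
E4 enters the output pre-softmax — its softmax is used only to build the
channel-mixing weights.

**EMCB decoder.** Each decoder layer upsamples ×2 (bilinear, parameter-free)
and applies an Efficient Mapping Convolutional Block: 3×3 convolution to
half the output width (BN + ReLU), depthwise 3×3 "mapping" copy (BN),
concatenation, an ECA-style per-channel sigmoid gate whose 1-D cross-channel
convolution has kernel `k(C) = ceil(log2 C) + 1`, raised to the next odd
integer so it can be symmetrically padded, floored at 3 — so k(112) = 9,
k(160) = 9, k(4) = 3 — and a pointwise residual projection of the block
input. Layers 1–4 concatenate the matching skip feature after the block,
giving the decoder channel trace 160→112, 224→40, 80→24, 48→16, 32→8 and a
1×1 head to K classes at full resolution.

The sentence describing the gate in the source architecture is ambiguous
about whether F2 itself is sigmoid-activated before the product; applying a
sigmoid to F2 would destroy the residual magnitudes and contradict the
stated purpose ("assign a weight value to each channel"), so only the gate
F3 passes through the sigmoid.

**Discriminator.** A small ghost-bottleneck classifier over K-channel masks:
stem (K→16, stride 2), three stride-2 bottlenecks (24, 40, 80 channels,
expansion 3), a 1×1 conv-BN-ReLU neck, global average pooling, a linear unit
and a sigmoid. The neck matters: without a ReLU between the last batch
normalisation and the pooling, train-mode BN pins every channel's batch mean
and the pooled score degenerates to a constant per batch — a failure mode we
hit and fixed during development. The discriminator sees only mask
probability maps (ground truth as one-hot); concatenating the image is
available as an option but off by default.

## Losses and training

* Supervised: `L_sup` is mean pixel cross-entropy, soft multi-class Dice
  over the foreground classes (smoothing 1e-6), or their sum. The printed
  loss definition is cross-entropy while the surrounding text calls the term
  Dice-based; the default mode `ce+dice` covers both readings, and both pure
  modes are available.
* Adversarial: `L_adv = −mean log D(f(x))`, weighted by λ = 0.01 (the value
  found optimal in the source's sweep). All probabilities inside logs are
  clamped at 1e-7, so losses are finite even for saturated scores.
* Discriminator: averaged binary cross-entropy with targets 1 for one-hot
  ground truth and 0 for (detached) generator output.
* Protocol: Adam at 0.001 for both parties, batch size 8, 100 epochs,
  multi-step decay (milestones 50 and 80, factor 0.1 — the milestones are
  not published; these are conventional for a 100-epoch schedule).
  Discriminator updates fire every 30th generator iteration; during
  generator updates the discriminator is frozen (its parameter leaves are
  detached, and it runs in eval mode so its running statistics are not
  polluted), and the generator output is detached for discriminator updates.
  With λ = 0 and discriminator updates disabled the loop is bit-identical
  to plain supervised training — this is asserted by a test.
* Augmentation: random horizontal flip and ±10° rotation (bilinear for
  images, nearest for masks), switchable; one seed drives weight
  initialisation, shuffling and augmentation.

## Model-budget calibration (frozen)

The published figures for this architecture are 13.687 MB and 15.26 GFLOPs
at 1×256×256. The per-bottleneck hidden (expansion) widths are not
published, and a conventional ghost encoder (1×1 primary convolutions,
expansion ≈3) comes out far below both figures (≈0.8 M parameters,
≈0.9 GFLOPs). The only free axes the architecture leaves are the hidden
widths and the primary-kernel sizes of the ghost modules, so those were
calibrated once against the two published numbers and frozen as package
defaults:

* primary ghost convolutions are dense 3×3 in stages 1–2 (the
  high-resolution stages, which carry the FLOP budget) and 1×1 in stages
  3–5 (as in standard ghost bottlenecks);
* per-stage expansion factors (87, 3, 3, 15, 15), i.e. hidden widths
  (1392, 1392 | 48, 72 | 72, 120 | 600, 1680×5 | 1680, 2400×4), rounded to
  multiples of 4.

This yields 3 585 799 parameters = 13.679 MB (−0.06%) and 15.29 GFLOPs
(+0.22%) under the frozen conventions: 4 bytes per parameter, 2²⁰ bytes per
MB, 2 FLOPs per multiply-accumulate, convolution/linear layers only, batch
1. The stage-1 expansion factor is far larger than any published ghost
network uses; we make no claim that it reproduces the source's (unpublished)
internal widths — it is the unique two-parameter solution within this
layout that meets both printed budget figures simultaneously, and the
package treats the budget, not the widths, as the specification.
Squeeze-and-excitation inside bottlenecks is available behind a flag but
omitted from the calibrated default.

## Synthetic phantoms: what they establish

`generate_phantoms()` draws, per sample, 2–4 elliptical "organs" at
anatomically plausible positions (liver left-of-centre, kidneys paired
below, spleen right), with semi-axes 5–22% of the image side, class-specific
mean intensities (0.45, 0.62, 0.72, 0.85 on a 0.15 background) and Gaussian
pixel noise (sd 0.05), clamped to [0, 1]; the mask records the generating
class per pixel, later classes overwriting earlier ones. Every draw is
seeded and reproducible.

The phantoms reproduce the features the architecture's tests need —
multi-class blobs, class-intensity separability comparable to T2 contrast,
overlap and absence of organs, noise — but none of the hard parts of real
abdominal MRI: texture, partial-volume boundaries, coil inhomogeneity,
inter-subject anatomy, or class imbalance at clinical severity. A green
training-sanity run therefore establishes that the full pipeline (model,
gradients, adversarial loop, metrics) can fit a learnable segmentation
problem; it says nothing about clinical accuracy, and the published
benchmark metrics are deliberately out of scope.

The sanity run itself is scaled to a CPU budget: 16 phantoms at 64×64,
batch 2, 300 generator iterations at constant learning rate 0.001 with
λ = 0.01 and discriminator period 30, augmentation off (fixed before its
Dice outcome was measured; ~6–7 minutes single-threaded). It reaches ≈94%
training-set foreground Dice against the ≥85% criterion.

## Numerical choices and degenerate cases

* Probabilities inside logarithms are clamped at 1e-7; Dice uses smoothing
  1e-6 (a disjoint prediction's Dice loss tends to 1 as the smoothing
  vanishes).
* Min–max normalisation maps constant images to all-zeros rather than
  dividing by zero.
* A class absent from both truth and prediction scores 100 on every
  overlap metric (perfect); a class absent from truth but predicted scores
  0 (hallucination). This keeps macro averages defined without rewarding
  false positives.
* `eca_kernel_size` resolves the rounding ambiguity in `k = log2(C) + 1`
  as ceil-then-add-one, with the even→odd adjustment needed for symmetric
  padding.
* Softmax implementations subtract the per-group maximum before
  exponentiation.
* Bilinear resampling uses half-pixel centre alignment with border
  clamping; masks are always resized nearest-neighbour so no new labels
  appear.
* Inputs must be divisible by 32 (five stride-2 stages); 32×32 inputs are
  legal and reduce the deepest feature to a single pixel, where the spatial
  softmaxes degenerate to the constant 1 as expected.

## Known limitations

* Strict translation consistency cannot hold through the encoder (its
  receptive field spans the input) nor through EMCB's global-average gate;
  the locality test therefore checks the double-conv ablation decoder on
  padded feature pyramids, where interior outputs reproduce exactly.
* The training loop is single-device, double-precision CPU code; it is
  budgeted for the package's sanity scale (minutes), not for full
  100-epoch, 256×256 training runs.
* DICOM support is deliberately minimal (single-frame, uncompressed, little
  endian) and PGM replaces PNG for mask I/O, because the target environment
  provides neither a PNG codec nor a DICOM library.
* The empty-class and aggregation conventions above are one defensible
  reading; the source does not publish its averaging scheme, so absolute
  metric values on real data may not be comparable beyond ~1 percentage
  point.
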