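# egaunet

Lightweight generative-adversarial U-Net for multi-organ segmentation of 2-D
medical images, implemented entirely in R (with RcppArmadillo compute
kernels). The package targets abdominal MRI slices labelled with five
classes — background (0), liver (1), right kidney (2), left kidney (3) and
spleen (4) — but works for any K-class 2-D segmentation problem with inputs
divisible by 32.

## The model

EGAUNet is an encoder–decoder network trained as the generator of a
generative-adversarial pair:

* **Encoder** — a 3×3 stride-2 stem to 16 channels followed by five stages of
  stacked *ghost bottlenecks* (2, 2, 2, 6 and 5 blocks emitting 16, 24, 40,
  112 and 160 channels at 1/2 … 1/32 resolution). A ghost module produces
  half of its output channels with a dense convolution and the other half by
  a cheap 3×3 depthwise transform of those, halving the cost of a dense
  layer; bottlenecks wrap two ghost modules (expand → project) in a residual
  shortcut, with a depthwise stride-2 convolution for downsampling blocks.
* **GSCA (Global Spatial-Channel Attention)** on every skip connection and on
  the deepest feature. A 1×1 convolution scores each pixel; the spatial
  softmax of the scores pools the feature map into a global context vector
  E3 (softmax-weighted sum over positions); two 1×1 convolutions with layer
  normalisation re-excite it into E4; the channel softmax of E4 weights the
  channel rows of the input, and the spatial softmax of that map is E6.
  Output: `Eout = Ein + E4 + E6` (E4 broadcast over pixels, E6 over
  channels).
* **Decoder** — five *Efficient Mapping Convolutional Blocks* (EMCB) with ×2
  bilinear upsampling and skip concatenation (channel trace
  160→112, 224→40, 80→24, 48→16, 32→8, then a 1×1 head to K classes).
  An EMCB halves the width with a 3×3 convolution (F1), expands back by
  concatenating a depthwise-mapped copy (F2), rescales channels with an
  ECA-style gate `F3 = sigmoid(Conv1d_k(GAP(F2)))` where
  `k = ceil(log2 C) + 1` (raised to odd, floor 3), and adds a pointwise
  projection of the input: `Fout = F2 · F3 + PConv(Fin)`.
* **Adversarial training** — the generator minimises
  `L_total = L_sup + λ·L_adv` with `λ = 0.01`, where `L_sup` is pixel
  cross-entropy plus soft multi-class Dice and
  `L_adv = −E[log D(f(x))]`. The discriminator D, a small ghost-bottleneck
  classifier over K-channel masks, is updated once every 30 generator
  iterations with binary cross-entropy (one-hot truth → 1, generated
  probability maps → 0). Optimiser: Adam, initial learning rate 0.001,
  batch size 8, 100 epochs, multi-step decay.

Evaluation reports Accuracy, Jaccard, Dice, Recall and Precision in percent
(counts accumulated over the evaluation set; macro average over foreground
classes; accuracy includes background).

There is no deep-learning framework dependency: the package carries its own
reverse-mode automatic differentiation over `(H, W, C, B)` arrays, with
BLAS-backed convolution kernels in C++.

## Worked example

No data download is required: a seeded phantom generator emulates the
abdominal layout (elliptical "organs" of class-specific intensity on a noisy
background).

```r
library(egaunet)

ph   <- generate_phantoms(phantom_config(n_samples = 16, image_size = 64, seed = 11))
gen  <- build_egaunet(num_classes = 5, seed = 11)
disc <- build_discriminator(num_classes = 5, seed = 12)
cfg  <- train_config(learning_rate = 0.001, batch_size = 2, lambda_adv = 0.01,
                     disc_update_period = 30, lr_milestones = integer(0),
                     augment = FALSE, seed = 11, max_iters = 300)
res  <- train(gen, disc, ph, cfg)
evaluate_model(res$generator, ph)$aggregate
#>  Accuracy   Jaccard      Dice    Recall Precision
#>  98.99750  89.69921  94.50959  98.90390  90.61645
```

After 300 adversarial iterations on 16 phantoms the generator reaches a
training-set foreground Dice of 94.5% — the overfit sanity check that stands
in for full-scale benchmark training. Model profiling:

```r
profile_model(build_egaunet(5), c(1, 256, 256))
#> parameters : 3585799
#> size       : 13.679 MB (4 bytes/parameter, 2^20 bytes/MB)
#> GFLOPs     : 15.29 at 1x256x256 (2 FLOPs per MAC, conv/linear only)
```

3.59 M parameters ≈ 13.68 MB serialized at 4 bytes each, and 15.3 GFLOPs for
one 256×256 slice — the lightweight budget this architecture is designed
around (an order of magnitude below classical U-Net variants).

## Command line

A thin CLI wraps the same functions (installed as `exec/egaunet`):

```sh
Rscript exec/egaunet make-synthetic --n 16 --size 256 --out run1
Rscript exec/egaunet train --synthetic --size 64 --batch 2 --epochs 10 --seed 7 --out run1
Rscript exec/egaunet evaluate --checkpoint run1/checkpoint.rds --manifest run1/data/manifest.csv --out run1
Rscript exec/egaunet predict  --checkpoint run1/checkpoint.rds --synthetic --n 4 --out run1
Rscript exec/egaunet profile --input-size 256
```

Flags mirror a flat key=value config file (`--config file`); command-line
values win, and the effective configuration is dumped beside the outputs.
Ablation switches `--no-gsca`, `--no-emcb` and `--no-gal` disable the
attention blocks, the EMCB decoder and adversarial learning respectively.

## Data formats

DICOM (single-frame, uncompressed little-endian; rescale slope/intercept
applied) and PGM (P5/P2, 8/16-bit) images; PGM label masks; CSV manifests
(`image,mask,split`). `map_chaos_labels()` bins raw mask intensities into the
0–4 class convention with configurable edges. PNG is not supported because no
PNG codec is available in the target environment.
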