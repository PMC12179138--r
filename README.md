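# mslinet

Eight-class classification of retinal optical coherence tomography (OCT)
images with a convolutional architecture built around three operators that
target the structure of OCT data: its horizontally elongated, layered tissue
band, the locality of lesions within that band, and the multiplicative
speckle noise intrinsic to coherent imaging. The package is aimed at
researchers in medical image analysis who want a self-contained, fully
testable CPU implementation of the architecture, its evaluation metrics, and
its noise-robustness protocol — including a synthetic OCT-like data
generator so that the entire pipeline runs without any external download.

## The architecture

A ResNet50-style backbone produces stage features c2–c5 at strides 4/8/16/32
(spatial 56/28/14/7 and channels 256/512/1024/2048 for a 224×224 input).
Three operators are wired onto it:

**Multi-scale dilation fusion (MDF).** With input x ∈ R^{W×H×C}, the block
compresses channels (F = ReLU(BN(Conv1×1(x))), C → C/2), runs parallel 3×3
convolutions at dilation factors d ∈ {6, 12, 18} (padding d, so a 3×3 kernel
covers an extent of 2d + 1 = 13/25/37 pixels), scale-aligns each branch and a
skip path with 1×1 convolution + batch norm, fuses them as
F_r = ReLU(Σᵢ Fᵢ′ + F′), mixes channels pointwise, restores C channels, and
adds the result back: y = ReLU(BN(Conv1×1(PW(F_r))) + x).

**Multi-segmented lesion localization (LLM).** The feature map is split into
7 row segments (segment height ⌊H/7⌋, remainder on the last segment); the
retina typically occupies about 4 consecutive segments. Each of the four
sliding windows of 4 segments is cropped, refined with squeeze-and-excitation
channel attention, re-stitched into the untouched remaining rows, and
projected (1×1 conv + BN). A fifth global branch applies SE to the whole
map. The five full-size maps are summed.

**Wavelet subband spatial attention (WSSA).** One level of orthonormal Haar
analysis yields the LL/LH/HL/HH subbands at half resolution; they are
stacked along channels (4C), smoothed by a 3×3 shape-preserving average
pooling, passed through a convolutional multi-scale attention core (5×5
depthwise convolution; identity plus three paired-strip depthwise paths of
extents 7/11/21; 1×1 mix), squashed to gates W_q = σ(Att), split back into
four C-channel maps, multiplied against the original subbands, and
reconstructed: y = IWT(I_LL·W_q1, I_LH·W_q2, I_HL·W_q3, I_HH·W_q4). With all
gates at 1 the block is the identity; with all gates at 0 it annihilates its
input — both laws are tested exactly.

The stage outputs pass through per-stage MDF blocks, a reduced feature
pyramid (per-stage 1×1 lateral projections only — no top-down pathway, no
upsampling), per-branch LLM blocks, and WSSA on the first three branches
(the deepest 7×7 branch is odd-sized and bypasses the wavelet transform).
Global average pooling and channel concatenation feed a single linear
classifier.

Because no deep-learning framework is available to R here, the package ships
its own compact CPU tensor engine: im2col + BLAS GEMM convolutions (with
dedicated depthwise and pointwise fast paths), batch normalization, pooling,
a reverse-mode tape, and Adam — all verified against brute-force oracles in
the test suite.

## Worked example

```r
library(mslinet)

# synthetic OCT-like data: 8 classes, layered band + class-specific lesions
spec <- synthetic_spec(n_per_class = 24, seed = 11,
                       split_fractions = c(16, 0, 8) / 24)
ds <- generate_dataset(spec)
tr <- dataset_split(ds, "train")   # 128 images
te <- dataset_split(ds, "test")    # 64 images

# quarter-width network, reference training protocol (Adam, lr 0.001,
# cross-entropy, weight decay 1e-4), single-precision convolutions
set.seed(11)
net <- msli_net(msli_config(width_multiplier = 0.25))
cfg <- train_config(batch_size = 8, epochs = 30, mixed_precision = TRUE,
                    seed = 11, early_stop_train_acc = 0.99)
res <- fit(net, tr$images, tr$labels, cfg, verbose = TRUE)
#> epoch   1  loss 1.8830  train acc 0.305
#> epoch   2  loss 1.2813  train acc 0.531
#> ...
#> epoch   8  loss 0.0950  train acc 0.984
#> epoch   9  loss 0.0263  train acc 1.000

evaluate_model(net, te$images, te$labels, norm = res$norm)
# held-out accuracy 0.890625, plus macro precision/sensitivity/F1

# speckle robustness: noise only at test time, five variance levels
robustness_protocol(net, te$images, te$labels, seed = 11, norm = res$norm)
#>   sigma  psnr_db accuracy
#> 1   0.1 29.08325 1.000000
#> 2   0.2 23.39193 0.671875
#> 3   0.3 20.10365 0.234375
#> 4   0.4 17.81550 0.125000
#> 5   0.5 16.15387 0.125000
```

Training accuracy reaches 1.0 by epoch 9 and the held-out synthetic accuracy
is 0.89; under test-time speckle the mean PSNR falls from 29.1 dB (σ = 0.1)
to 16.2 dB (σ = 0.5) and accuracy degrades monotonically toward the 0.125
chance level — the expected behavior for a clean-trained classifier.

The metrics follow the standard definitions — accuracy n/N, per-class
precision TP/(TP+FP) and sensitivity TP/(TP+FN), F1 their harmonic mean,
macro-averaged over the eight classes. The speckle model is
F(x,y) = g(x,y)(1 + u(x,y)) with u ~ N(0, σ²), and PSNR is reported as
20·log10(Max/RMSE) in dB.

A thin command-line wrapper over the same functions is installed under
`inst/cli/msli.R` (`generate-data`, `train`, `evaluate`, `robustness`).

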