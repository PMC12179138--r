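---
title: "Multi-scale, lesion-localized, wavelet-gated OCT classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale, lesion-localized, wavelet-gated OCT classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each operator, the tunable parameters, the numerical
choices, and the limits of what the synthetic-data tests demonstrate.

## The problem and the modeling assumptions

Retinal OCT cross-sections are grayscale images with three structural
regularities that a generic classifier ignores:

1. the tissue of interest is a horizontally elongated, layered band that
   occupies roughly the middle half of the image — most rows are background;
2. pathology (neovascular membranes, fluid pockets, cysts, drusen, holes) is
   *local*: it occupies a small region inside or adjacent to that band;
3. coherent imaging carries *multiplicative* speckle — the noise standard
   deviation scales with the local gray value, so bright layers are noisier
   than the background in absolute terms.

The three operators in this package each target one regularity, and each
comes with an algebraic law that the test suite checks exactly rather than
statistically.

## Multi-scale dilation fusion (MDF)

A 3×3 convolution at dilation $d$ covers an extent of $2d+1$ pixels, so
parallel branches at $d \in \{6, 12, 18\}$ see 13/25/37-pixel neighborhoods
at unchanged resolution. The block compresses channels to $C/2$
(1×1 + batch norm + ReLU), runs the three dilated branches, scale-aligns each
with 1×1 + batch norm (no rectification before the fusion sum — the branches
must be able to cancel), adds a 1×1-projected skip of the compressed map,
rectifies the sum, mixes channels pointwise, restores $C$ channels, and adds
the result to the input.

Two wiring points were genuinely open and are worth recording:

* **Rectifier placement in the output stage.** The composition
  "ReLU · BN · Conv1×1 · PW · F_r + x" can be read with the rectification
  either before or after the residual addition. The package defaults to the
  standard post-add residual pattern, $y = \mathrm{ReLU}(\mathrm{BN}(\ldots) + x)$,
  which also yields the exact *zero-branch identity*: with all learned
  parameters at zero and non-negative input (the regime after any upstream
  ReLU), the block is the identity. A `relu_position = "before_add"` switch
  provides the other reading for ablation.
* **"Pointwise convolution" vs. "1×1 convolution"** in the output stage are
  implemented as two distinct layers: a $C/2 \to C/2$ channel mixer followed
  by the $C/2 \to C$ expansion, matching the separation between "mining
  channel relationships" and "restoring the original dimension".

Convolution weights use Kaiming fan-in initialization; batch-norm scale
starts at 1 and offset at 0. Width/height smaller than the dilated extent
are allowed — zero padding handles the borders.

## Multi-segmented lesion localization (LLM)

The map is divided into 7 row segments; the band prior says the retina fits
in 4 consecutive ones, so there are exactly $7 - 4 + 1 = 4$ windows. Each
window is cropped, passed through squeeze-and-excitation (SE) channel
attention (global average pool, $C \to C/r \to C$ bottleneck with $r = 16$
by default, sigmoid gates), and *re-stitched*: the refined rows replace the
window's rows while all other rows are copied verbatim from the input — the
block's purpose is size restoration so later stages can tell *which*
window the lesion lives in, not masking. Each stitched map gets its own
1×1 + batch norm; a fifth branch applies SE to the whole map; the five
full-size maps are summed with no trailing activation.

Choices made where the definition was silent:

* **Heights not divisible by 7**: segment height is $\lfloor H/7 \rfloor$
  with the remainder appended to the last segment, keeping the first six
  boundaries deterministic. All backbone heights used here (56/28/14/7)
  divide evenly anyway.
* **Five independent SE blocks** (no weight sharing across branches).
* The identity-reduction law — unit gates, identity 1×1, identity norm give
  exactly $5q$ — pins the summation wiring and is tested to machine
  precision.

## Wavelet subband spatial attention (WSSA)

One level of *orthonormal* Haar analysis (filter taps $\pm 1/2$) splits the
map into LL/LH/HL/HH at half resolution. Orthonormality is a deliberate
numerical choice: it gives exact energy conservation and an inverse that is
literally the transpose, so the round trip is exact to machine precision and
both properties double as tests. With the package's (row, column) layout,
LH responds to oscillation across the width axis (horizontal detail) and HL
across the height axis; the convention is fixed by a worked example in the
tests.

The four subbands are stacked along channels ($4C$ at half size — stacking
four half-size maps cannot be full-size, so the attention operates at
$W/2 \times H/2$), smoothed by an average pooling that must preserve shape
(3×3, stride 1, padding 1 by default; the divisor counts only in-bounds
taps), and passed through a convolutional multi-scale attention core: a 5×5
depthwise convolution, four parallel feed-forward paths — identity plus one
paired strip path ($1{\times}k$ then $k{\times}1$, depthwise) per extent
$k \in \{7, 11, 21\}$ — summed, then a 1×1 mix. A sigmoid turns the result
into gates in $(0,1)$, which multiply the *original* (not pooled) subbands
before synthesis. Although the cited attention core is often described in
self-attention vocabulary, its defining equation is convolutional, and that
convolutional reading is what is implemented.

Ablation wirings are construction-time switches: `drop_subband` excludes one
subband from stacking and gating (it passes to synthesis unmodified, so the
unit-gate identity still holds); `mode = "owt"` is the bare analysis/
synthesis round trip; `mode = "per_subband_msa"` runs an independent
attention core on each subband with no gating.

## Assembly

Backbone stages → per-stage MDF → reduced feature pyramid (per-stage 1×1
lateral projections to a common width, default 256, no top-down pathway) →
per-branch LLM → WSSA on the first three branches only — the deepest branch
is 7×7, odd-sized, and a half-resolution wavelet split would be ill-defined
there — → global average pooling → channel concatenation → one linear
classifier. Width scaling for desk-scale work multiplies every channel
count (backbone and laterals) and rounds to even values so the MDF
compression stays exact; `width_multiplier = 0.25` gives stage channels
64/128/256/512 and a 64-wide pyramid. The backbone is randomly initialized;
no pretrained weights are bundled, and the classifier head is deliberately
minimal (no dropout). Grayscale inputs are replicated to three channels
before the stem.

## Training protocol

Cross-entropy loss; Adam with $\beta_1 = 0.9$, $\beta_2 = 0.999$; learning
rate fixed at 0.001 (no schedule); weight decay $10^{-4}$ added to the
gradient; batch size 64; 60 epochs; the final-epoch weights are evaluated;
six independent repeats re-seeded as `seed + 0..5`, metrics averaged.
Input images are standardized with mean/sd computed from the training split.
The `mixed_precision` flag runs the convolution kernels in single precision
(GEMM in `float`, everything else in double) — the package's
reduced-precision training mode; it is off by default and bit-for-bit
deterministic either way since all kernels are single-threaded.

## Metrics and the noise protocol

Accuracy is $n/N$; precision, sensitivity and F1 are computed per class from
TP/FP/FN and macro-averaged — on the class-balanced splits used throughout,
macro and support-weighted averaging coincide, and accuracy equals the mean
per-class sensitivity (a tested invariant). Zero-support classes contribute
0 with a warning.

Speckle is $F = g(1+u)$, $u \sim N(0, \sigma^2)$ i.i.d. per pixel, clipped
back to $[0, 1]$ before inference so the model input range matches its
training normalization; the pre-clip field satisfies
$E[(F-g)^2] = \sigma^2\,\overline{g^2}$, checked by Monte Carlo at $10^6$
pixels. PSNR is implemented in the standard form
$20\log_{10}(\mathrm{Max}/\mathrm{RMSE})$; a printed variant of the ratio
without the root is sometimes seen, and a `strict` flag evaluates that
literal form, but the standard form is the default and the one reported.
The robustness protocol trains on clean images, corrupts only the test set
at $\sigma \in \{0.1, \ldots, 0.5\}$, derives a per-$\sigma$ seed as
`seed + round(100 σ)` so any row is reproducible in isolation, and reports
per-image-averaged PSNR (a `pooled_psnr` switch averages over the pooled
pixel population instead).

## The synthetic data generator

The generator is a structural phantom, not a clinical simulator. Each image
contains: a dim background with a vertical gradient; a smoothly curved,
layered band (bright inner line, darker body, mid reflective stripe, bright
outer line) whose per-column thickness is drawn from 0.47–0.58 of the image
height and whose curvature amplitude is at most 0.03, keeping the band's
vertical footprint inside $[3/7, 5/7]$ of the height — the regime the
4-of-7 row windows assume; one class-specific local primitive (dome
elevation, bright irregular blob, dark fluid ellipse, multiple cysts, band
thinning, lower-boundary bumps, full-thickness notch, or nothing for the
intact class); and multiplicative speckle at $\sigma = 0.08$, a visibly
grainy but not destructive level. Splits are class-balanced with
largest-remainder apportionment (ties resolved toward later splits, so the
default 2300/350/350-shaped fractions put the remainder seat in the test
split), and every image derives its own seed, making datasets bitwise
reproducible.

What passing on this generator shows: the blocks are differentiable and
correctly wired, the full network is trainable from random initialization,
lesion information that is local and band-anchored is sufficient for
classification, and accuracy degrades gracefully under test-time speckle.
What it does not show: performance on real OCT — real speckle is spatially
correlated and non-Gaussian, real lesions vary far more in shape and
contrast, and class boundaries are clinically subtle. Numbers obtained on
the phantom say nothing quantitative about any real dataset.

## Problem sizes and numerical notes

The test suite and the acceptance script run the end-to-end experiment at
`width_multiplier = 0.25`, 224×224 inputs, 16 training and 8 test images per
class, batch size 8, at most 30 epochs with early stopping once the running
training accuracy reaches 0.99 — sizes chosen so a single CPU completes the
whole experiment in minutes while still exercising every block at the
reference input geometry. Batch normalization uses biased variance with
$\epsilon = 10^{-5}$ and momentum 0.1; the identity-law tests set the
running variance to $1 - \epsilon$ so the normalization is exactly the
identity rather than approximately. Convolution correctness is pinned by
direct-loop oracles; gradients by central finite differences. The engine is
single-threaded and therefore bitwise deterministic under a fixed seed,
which the determinism tests assert on logs, checkpoints and evaluations.

## Known limitations

* CPU only, and sized for desk-scale experiments; full-width training at
  dataset scale is out of reach by design.
* No pretrained backbone weights; transfer-learning comparisons are not
  reproducible here.
* The attention core follows the convolutional reading of its definition;
  a token-based self-attention variant is not implemented.
* Gradient-based saliency visualization is not included.
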