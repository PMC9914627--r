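---
title: "Pruned multi-scale segmentation networks: models, conventions and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pruned multi-scale segmentation networks: models, conventions and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(prunet)
```

## The model family

All four networks share one five-level encoder: two 3×3
convolution + batch-norm + ReLU units per level, 2×2 max-pooling between
levels, channel widths doubling from `w1` to `w5` (64→1024 at full
scale, 8→128 in the reduced regime). They differ only in how decoder
level `i` gathers its inputs:

* **unet** — up-sample `de_{i+1}`, concatenate with `en_i`, two 3×3
  convolutions.
* **unet3plus** — project *every* encoder `en_1..en_i` (down-sampled by
  the matching power of two) and *every* deeper decoder
  `de_{i+1}..de_N` (up-sampled) to a common branch width, concatenate,
  fuse with one 3×3 convolution + batch norm.
* **unet3plus_pruned** — keep only three of those sources: the
  same-level encoder `en_i`, the next-deeper decoder `de_{i+1}`, and the
  encoder two levels shallower `en_{i-2}` (when `i > 2`). Decoder 1 is
  the special case: it receives `en_1` plus the up-sampled decoders
  `de_2..de_{N-2}`. The rationale is that *adjacent* scales contribute
  nearly redundant information, so dropping `en_{i-1}` and the deeper
  decoders beyond `i+1` saves parameters with little information loss.
* **attention = TRUE** inserts a CBAM between the fusion convolution and
  the decoder ReLU (`A(C(...))` with `A` = CBAM then ReLU; the
  equation's wording fixes the ReLU *after* the attention block).

The bottleneck has no decoder block: `de_N` *is* `en_N`, used directly
as a source. A consequence worth knowing: at `N = 3` the pruned
decoder 1 reduces to `{en_1}` and decoder 2's output is never consumed;
the graph is still built as specified, the unused block simply receives
no gradient. The study regime is `N = 5`, where every block is live.

CBAM uses reduction ratio `r = 16` and a 7×7 spatial kernel — the
defaults of the original attention module, since the segmentation
description leaves them unstated. The shared channel perceptron has no
biases; the spatial convolution has one. Channels not divisible by `r`
clamp the hidden width to `max(1, C %/% r)` with a logged note — this
matters in the reduced-width regime, where fusion maps have 16–24
channels.

## Parameter accounting and convention calibration

`count_parameters()` counts every convolution kernel/bias, batch-norm
scale/shift and attention weight exactly (running statistics are
buffers, not parameters). Published parameter tables for this model
family, however, underdetermine the construction: whether convolutions
followed by batch norm carry biases, whether branch transforms include
batch norm, how the classic UNet decoder up-samples, and how wide the
fusion convolution is. `calibrate_conventions()` therefore enumerates
the documented 16-set space (bias on/off × branch-BN on/off × bilinear
vs transposed up-sampling × fusion width `branch × n_branches` vs
`branch × N`) and picks the set minimising the *total absolute
deviation* from all seven published counts simultaneously — four
variants at widths 64→1024 and three at 8→128, the small regime
evaluated with the same set, never re-fit.

The winner (bias-free convolutions, no branch batch norm, bilinear
up-sampling, fusion width `branch × n_branches`) is the repository
default. Its residuals are honest and worth stating plainly: the
computed counts are 34.52 / 26.96 / 21.65 / 21.67 M (published: 32.92 /
25.71 / 21.00 / 21.02 M) and 0.54 / 0.42 / 0.34 M (published: 0.60 /
0.40 / 0.33 M). A considerably wider structural search (1–3 decoder
convolutions, eight up-sampling styles, alternative fusion and head
kernels) brackets but never hits the published values — for reference,
the standard full-scale design with fusion width 320 reproduces the
*original* full-scale network's published 26.97 M exactly, while this
family's published table prints 25.71 M for the same architecture. We
conclude the published counts reflect implementation idiosyncrasies that
the prose does not describe, report best-fit residuals instead of
chasing them, and verify the claims that are robust to conventions: the
strict ordering pruned < full-scale < classic at five levels, and the
near-zero cost of attention (+0.075 %, i.e. 21.65 → 21.67 M). Under the
calibrated set the parameter reductions are 37.2 % vs UNet and 19.6 %
vs UNet 3+ (published: ~36 % and ~18 %).

Two caveats on the calibration knobs. The margin between branch
batch-norm on and off is 0.006 M — far below the residuals — so that
choice is effectively free; we keep the calibrated winner for counting
and training alike. And the same-scale branch description in the
literature includes batch normalisation, so readers comparing against
other implementations should expect a ±0.003 M difference from that
term.

## Numerical core

Feature maps are `(H, W, batch, channel)` arrays. Convolutions run
through a compiled im2col + BLAS GEMM kernel (Rcpp/RcppArmadillo) with
explicit forward and backward passes; the backward pass rebuilds the
patch matrix rather than caching it, trading a little compute for a much
smaller memory footprint. Bilinear resampling uses half-pixel centres
and is implemented as two small interpolation matrices whose transposes
give the exact adjoint in the backward pass. Max-pooling routes
gradients to the first maximiser on ties. Batch normalisation uses
ε = 1e-5 and momentum 0.1 on running statistics (biased batch variance);
evaluation always uses the running statistics. Every layer's gradient is
tested against central finite differences at tolerance 1e-6 or better.

Initialisation is He-normal with a twist: each parameter's seed is
derived from a hash of its *name*, so two models built from the same
seed share bitwise-identical weights for every layer they have in common
— inserting attention blocks provably leaves all other initial weights
untouched, which makes ablation comparisons exact.

Training follows the published protocol: ADAM (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8, the optimiser's standard moments, since only the method is
cited), learning rate 2e-4, weight decay 1e-4 added to the gradient,
soft Dice loss on probabilities with smoothing ε = 1 (the loss must stay
differentiable, so it is never computed on binarised maps), per-sample
augmentation probability 0.5, 200 epochs by default, binarisation
threshold 0.5 with the `≥` boundary convention. "Iterations" we read as
epochs — 200 gradient steps could not traverse the study-scale datasets.
Batch size is unstated in the protocol; we default to 8. The 0/0 metric
conventions: undefined ratios return 0 with a logged note; two empty
masks have JS = DC = 1. Fold tables always report both aggregation
scopes, per-image mean and pooled-count global, because published tables
in this literature print F1 ≠ DC even though the two are algebraically
identical for a single binarised pair — the difference can only come
from an unstated averaging scope, so we refuse to guess and print both.

## Synthetic benchmarks

The generator emulates the statistical character of three public
benchmark types so that the pipeline is testable without downloads:

* `skin_like` — one large irregular bright lesion (perturbed-ellipse
  boundary, Fourier harmonics 2–5) on a textured darker background;
  foreground 0.75, background 0.35, additive noise σ = 0.05, declared
  contrast 0.25, foreground fraction 8–45 %. Dermoscopy lesions with
  distinct boundaries are genuinely "easy", and so is this profile: a
  plain Otsu threshold reaches Dice ≈ 0.99 on it. That is deliberate —
  it guarantees the task is learnable, so a network that misses the
  0.90 bar is wrong, not unlucky; the bar certifies that architecture,
  loss and optimiser learn the image→mask mapping end to end, not that
  they beat thresholding on such scenes.
* `breast_like` — one small dark (hypoechoic) lesion, multiplicative
  speckle (σ = 0.25), contrast 0.10: the hard, low-contrast profile.
* `lung_like` — exactly two smooth bright regions, one per image half
  with a guaranteed separating line (mediastinum-like), contrast 0.40.

Masks are rasterised perturbed ellipses whose radius is rescaled (up to
25 deterministic retries) until the foreground fraction lands in the
declared range. Every sample draws its own seed from the dataset seed
and index, so datasets are bitwise-reproducible and order-independent.
What the profiles deliberately do *not* model: acquisition physics,
vignetting, hair/probe artefacts, anatomical shape priors, annotation
noise. Passing the synthetic benchmarks therefore demonstrates that the
architecture, loss, optimiser and harness are correct and that the
pruned+attention model can learn lesion segmentation end to end on CPU —
it does not certify clinical-grade accuracy on real dermoscopy,
ultrasound or CT data, which would require the original datasets.

Augmentation applies one random element of {horizontal flip, vertical
flip, 90/180/270° rotation} with probability `ratio` (the published
"augmentation ratio 0.5" we read as a per-sample probability, not a
dataset expansion factor), identically to image and mask.

## Problem sizes used by the tests

The test-suite and acceptance runs are desk-scale by design: parameter
accounting runs at the full published widths (it is symbolic and takes
seconds); learnability trains the widths-8→128 pruned+attention model on
sixty 64×64 skin-like samples for 30 epochs (≈4 minutes on one CPU core,
held-out per-image Dice 0.966 with the reference seeds 101/202/1,
comfortably above the 0.90 bar; the training loss itself sits near 0.28
at that point because probabilities are not yet saturated — overlap
converges much earlier than calibration); the CLI smoke test
cross-validates 20 samples, k = 5, five epochs. Full-scale training at
256×256 with widths 64→1024 is architecturally identical and supported,
just not exercised by the tests.

## Known limitations

* Binary segmentation only; one output channel.
* No deep supervision or classification-guided module (present in the
  original full-scale design, absent from this family's description).
* No GPU path; the compiled convolution is single-threaded apart from
  BLAS.
* FLOP counting is out of scope: published GFLOPs figures for this
  family are not reconcilable with 256×256 inputs under standard
  counting, so the package does not attempt them.
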