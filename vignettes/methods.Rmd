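---
title: "Semisupervised adversarial deblurring of serial SEM micrographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semisupervised adversarial deblurring of serial SEM micrographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serial-section scanning electron microscopy (sSEM) produces the aligned
nanometre-resolution image stacks from which neural connectomes are
reconstructed.  During months-long automated acquisition, autofocus and
autostigmation occasionally fail, leaving tiles degraded by defocus,
astigmatism, or both.  Re-imaging every blurry tile is impractical, and
blurry tiles measurably degrade downstream instance segmentation of axons
and myelin.  `semdeblur` implements a blind (kernel-free) restoration
method for such micrographs: a generative adversarial network trained on a
small set of paired clear/blurry images, with a *semisupervised* term that
exploits the much larger pool of unpaired blurry images that any real
acquisition produces.

## Image formation model

A blurry micrograph is modelled as

$$ z = k * x + \eta, $$

a clean image $x$ convolved with an unknown point-spread function $k$ plus
additive noise $\eta$.  The simulator (`blur_spec()`, `render_kernel()`,
`apply_blur()`) renders $k$ for the aberration taxonomy seen in practice:

* **underfocus / overfocus** — an isotropic uniform disc of the defocus
  radius, convolved with a narrow Gaussian ($\sigma = 0.5$ px) to soften the
  rim.  In a linear intensity model the two defocus signs are
  indistinguishable; overfocus is rendered as a 1.5× larger radius tier so
  that the two modes remain distinct degradation strengths.
* **astigmatism** — an anisotropic oriented Gaussian
  ($\sigma_\text{major} \ne \sigma_\text{minor}$).
* **combined** — the convolution of both.

Kernels are nonnegative and normalized to sum 1.  Convolution uses
reflective padding, so borders are not darkened — artifacts there would
leak into training crops.  $\eta$ is zero-mean Gaussian with configurable
standard deviation; the formation model in the source literature leaves the
noise law unspecified, and Gaussian read-noise is the standard SEM
surrogate that keeps the model linear-plus-noise.

## Synthetic phantoms

Real corpus-callosum training corpora are not publicly deposited, so the
package generates its own study material (`phantom_spec()`,
`generate_phantom()`): dense fields of myelinated-axon cross-sections —
dark osmium-stained myelin annuli around lighter axoplasm — over a smooth
textured background (low-pass-filtered Gaussian noise).  Axons are placed
by rejection sampling so they never overlap, and an instance label mask is
returned with every phantom for segmentation-agreement experiments.  The
phantoms emulate the *geometry and contrast convention* of the real tissue;
they do **not** emulate charging artifacts, stitching seams,
section-thickness effects, or the full texture spectrum of biological EM,
so passing tests demonstrate that the training machinery works, not that
any particular PSNR value transfers to real micrographs.

## Generator

The generator is a residual refiner: `output = z + tanh(head(X^{0,5}))`.
The bounded Tanh residual on top of a global skip means an untrained
network is already close to the identity, and the output can both brighten
and darken (hence the internal $[-1, 1]$ value convention).

Internally it has three stages:

1. **Pyramid encoder** — five scales (spatial size $/2^i$, $i = 0..4$),
   each scale a convolution (stride-2 for downsampling) followed by
   light-weight residual blocks (conv–ReLU–conv with an identity skip and
   *no* normalization inside the block), then per-scale instance
   normalization, which stabilizes adversarial training.
2. **Coarse decoder** — top-down: the coarsest block seeds $X^{4,1}$ and
   each finer column-1 node is `upsample(X^{i+1,1}) + conv1x1(E_i)`, with
   the 1×1 convolutions reducing skip channels.
3. **Progressive decoding grid** — the triangular node set $X^{i,j}$,
   $i \in \{0..4\}$, $j \le 5 - i$: 15 nodes, 5,4,3,2,1 per scale.  Column
   $j = 1$ receives no extra processing.  Node $(i, j)$ is produced by a
   *hybrid feature extractor* (HFE) from its own-scale predecessor
   $(i, j-1)$ and the two immediately coarser predecessors $(i+1, j-1)$
   (upsampled ×2) and $(i+2, j-1)$ (×4), where those exist.

The HFE computes

```
a   = ReLU(conv3x3(skip))
m   = conv3x3(concat(a, up2(c1), up4(c2)))
s   = skip + m
out = s + conv3x3(ReLU(s))
```

so with all weights zero it is the identity on its skip input — the grid
degenerates gracefully and the whole generator reduces bitwise to the
identity map when the head is zeroed.

**Index-direction choice.**  The grid constraint $j \le 5 - i$ makes it
impossible for a node to consume *equal-step* features of coarser scales
(they do not reach that step).  The package therefore wires node $(i, j)$
to the coarser nodes at the *previous* step, $(i+1, j-1)$ and
$(i+2, j-1)$ — the only wiring that satisfies the constraint while
decoding progressively from low to high resolution.  This is the largest
single interpretation decision in the package and reduces the architecture
to a nested-dense-decoder topology.

**Widths and depths.**  The source architecture's channel widths are not
published.  Defaults are 32·(1, 2, 4, 8, 8) channels per scale and two
residual blocks per scale, all configurable down to 4 base channels so the
full architecture runs in CPU-scale tests.

**Initialization.**  He-normal weights throughout, with two deliberate
exceptions: (a) the closing convolution of every residual branch (encoder
residual blocks, the HFE `conv_cat` and `conv_post`) starts downscaled by
0.1 (fixup-style) — without this, feature variance doubles at every grid
step and the terminal node's magnitude grows ~16-fold; (b) the output head
uses a small (σ = 10⁻³) initialization, so a fresh generator is a
near-identity map and training starts from the blurry baseline rather than
from noise.

**Upsampling** defaults to bilinear interpolation followed by a 3×3
convolution (avoiding the checkerboard artifacts of transposed
convolutions); nearest-neighbour and 4×4/stride-2 transposed convolution
are available by configuration.  Encoder downsampling is a stride-2
convolution.

## Discriminator and adversarial objective

The discriminator is a patch scorer: `n_layers` (default 4) stages of
4×4/stride-2 convolution + instance normalization + LeakyReLU (slope 0.2),
then a 1-channel convolution head with *no* output nonlinearity, producing
a spatial score map (input/2⁴ per side).  A patch map rather than a
fully-connected scalar keeps the network input-size agnostic; the scalar
score of an image is its map mean.

Training uses the least-squares GAN objective with the 0–1 coding
(fake label $a = 0$, real label $b = 1$, generator target $c = 1$):

$$ L_D = \tfrac12 E[(D(T(x)) - 1)^2] + \tfrac12 E[D(T(\hat z_s))^2], $$
$$ L_{adv} = E[(D(T(\hat z_s)) - 1)^2], $$

with $T(\cdot)$ the differentiable augmentation described below and
$\hat z_s = G(z_s)$ the restored supervised image.  The discriminator sees
only supervised material (clear images vs. detached supervised
restorations).

## Semisupervised term

Unpaired blurry images $z_u$ are passed through the generator alongside
the supervised batch and scored by the same discriminator:

$$ L_{us} = E[(D(T(\hat z_s)) - D(T(\hat z_u)))^2]. $$

This anchors the unlabeled branch to the *supervised restoration domain*
rather than to clear images: matching unpaired outputs directly against
real data is known to collapse quickly because the discriminator then
identifies the dataset instead of the distribution.  The expectation is
over pairs; the package pairs per-sample scalar scores by index when batch
sizes agree and falls back to comparing batch means otherwise (the
published form is written over expectations and does not fix this choice).
An empty unsupervised bank makes the term exactly zero, reducing training
to a plain supervised least-squares GAN — a reduction the test suite
asserts bitwise.

## Content and perceptual losses

The pixel term is a robust L1: $L_c = \lVert x - \hat z_s\rVert_1$ (mean
per pixel).  The perceptual term is the squared Euclidean distance between
features of a *frozen* network, normalized by the feature extent
$C\,H\,W$.  The package exposes this as a pluggable backbone contract: any
deterministic frozen mapping image → feature block qualifies.  The shipped
default is a small three-stage He-initialized convolution stack drawn from
a fixed seed and never updated — fully self-contained and offline, serving
the same architectural role as a pretrained classifier slice (a frozen,
generic feature map); users with a pretrained network can plug it in
through the same contract.

The total generator objective is

$$ L_G = L_c + \lambda_{adv} L_{adv} + \lambda_{us} L_{us}
        + \lambda_p L_p, \qquad
   (\lambda_{adv}, \lambda_{us}, \lambda_p) = (0.1,\, 0.01,\, 0.02). $$

## Differentiable augmentation

Every image entering the discriminator — real or fake, in both the D and G
steps — first passes through $T(\cdot)$: a composition of grayscale color
jitter (brightness shift ±0.5, contrast scale 0.5–1.5 about the *detached*
image mean, so the pixel gradient is exactly the contrast factor), integer
translation (up to 1/8 of the side, zero-filled), and cutout (a square of
half the side set to zero).  Parameters are drawn freshly per image per
call; real and fake batches get independent draws.  All three transforms
are differentiable in the pixel values wherever defined, so adversarial
gradients reach the generator; because the cutout never covers more than
half the side, a nonzero-gradient region always survives.  Disabling all
three reduces every objective to its unaugmented value exactly.

## Training procedure

Each step: (1) forward both blurry batches through the generator (one
batched pass); (2) one discriminator update on augmented real images and
augmented *detached* fakes; (3) one generator update against the refreshed
discriminator.  Optimization is SGD with momentum 0.9 under a linear
warm-up to the peak learning rate of 10⁻⁴ (1000 steps by default); batch
size 2 at 256×256 crops follows the published recipe.  Supervised batches
are randomly cropped and flipped (training augmentation, distinct from
$T$); the unsupervised bank is sampled uniformly with replacement.  The
D:G update ratio defaults to 1:1 (not published).  Checkpoints embed
weights, optimizer momenta, configuration and the RNG state, so a resumed
run reproduces the uninterrupted run bitwise.

Gradient hygiene is structural: the discriminator step sees only detached
generator outputs, the generator step applies updates only to generator
parameters, and the perceptual backbone is never attached to any
optimizer.

## Quality metrics

* `psnr()` — $10\log_{10}(R^2/\text{MSE})$, with an `Inf` sentinel for
  identical images.  Metrics are computed on $[0,1]$-normalized images
  with data range 1 unless 8-bit evaluation is requested explicitly (the
  evaluation convention of the source tables is unstated).
* `ssim()` — the standard mean structural similarity with an 11×11
  Gaussian window ($\sigma = 1.5$), $K_1 = 0.01$, $K_2 = 0.03$,
  sample-covariance normalization, replicate-padding filtering and a
  half-window border crop.  The test suite pins it to an independent
  reference implementation at 10⁻⁶.
* `adapted_rand_error()` — $1 -$ F-score of Rand precision/recall over all
  unordered pairs of distinct foreground pixels, with ground-truth
  background excluded (the segmentation-challenge convention).  The test
  suite verifies exact agreement with an $O(n^2)$ brute-force pair count.

## Tiled inference

Real micrographs (1K–3K px) exceed the 256×256 training resolution, so
`deblur_array()` processes overlapping tiles (default 256 px, 32 px
overlap) and blends them with feathered linear ramps; averaging is
available.  Feathering suppresses tile seams that would otherwise corrupt
downstream segmentation.  Images are reflect-padded to multiples of 16
(the encoder's total downsampling factor) and cropped back.  With a
zero-head generator the tiled and whole-image paths agree exactly; for a
trained network they agree up to boundary-context differences inside the
overlaps.

## The scaled-down study

`synthetic_study()` defines the package's self-contained experiment, used
by both the test suite and `scripts/acceptance.R`: 64×64 phantoms with 5
axons; 8 supervised pairs, 8 unsupervised blurry images, 4 held-out pairs;
the base domain is defocus (radius 1.5 px, noise σ 0.01), the shifted
domain adds an oriented astigmatic component (the cross-sample setting).
The tiny configuration is 8 base channels with multipliers (1,1,2,2,2),
one residual block per scale, a 4-layer/8-channel discriminator, and a
(4,8,8)-channel frozen backbone.  Training uses batch 2, 32×32 crops, and
a peak learning rate of 2×10⁻³ after a 50-step warm-up — a smaller network
trained for far fewer steps supports a proportionally larger rate than the
full-scale recipe.  The in-domain learning check runs 200 steps; the
semisupervised cross-domain contrast is a smaller effect and uses a
longer 600-step horizon.  These sizes are the package's own study
conditions: they
demonstrate the direction of each effect, not the magnitudes reported for
real multi-GPU-scale training.

## Numerical engine

No deep-learning framework is used: the package carries its own
reverse-mode automatic differentiation engine for the handful of tensor
operations the networks need (convolution and its transpose via
im2col/GEMM on BLAS, bilinear/nearest upsampling, instance normalization,
activations, concatenation, translation, masking, reductions).  Every
operation's analytic gradient is pinned against central finite differences
in the test suite.  Tensors are plain R arrays in (H, W, C, N) layout;
compute-heavy kernels are C++.

## Known limitations

* The phantom generator does not model charging, seams, or
  section-thickness effects; domain shift is emulated only through blur
  and noise parameters.
* The shipped perceptual backbone is a random frozen network, not a
  pretrained classifier; it regularizes feature-space distance but does
  not carry semantic features.
* Training at the published scale (256×256, thousands of steps) is
  possible but slow in this R implementation; the package is tuned for
  method verification and small-scale use, not production training
  throughput.
* No multi-GPU or mixed-precision support; no attention or recurrent
  variants.
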