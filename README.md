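# semdeblur

Blind deblurring of serial scanning-electron-microscopy (sSEM) micrographs
for connectomics preprocessing.

During months-long automated sSEM acquisition, autofocus and autostigmation
failures leave a significant fraction of tiles blurred by defocus,
astigmatism, or both; those tiles measurably degrade the neuron instance
segmentation from which connectomes are reconstructed, and re-imaging them
is impractical.  `semdeblur` restores such tiles without knowing the blur
kernel.  It trains a generative adversarial network from a *small* set of
paired clear/blurry images plus the much larger pool of unpaired blurry
images every real acquisition produces:

* **Generator** — a 5-scale pyramid encoder and a progressive decoding grid
  of hybrid feature extractors: 15 nodes $X^{i,j}$ ($i \in \{0..4\}$,
  $j \le 5-i$), each refining its own scale with features upsampled from
  the two next-coarser scales.  The output is a bounded residual,
  $\hat z = z + \tanh(\mathrm{conv}(X^{0,5}))$.
* **Discriminator** — a least-squares patch scorer (4×4/stride-2 stages,
  instance norm, LeakyReLU), trained with the 0–1 coding
  ($a=0$, $b=c=1$).
* **Objective** — $L_G = L_c + 0.1\,L_{adv} + 0.01\,L_{us} + 0.02\,L_p$:
  pixel L1, adversarial, *semisupervised* score matching
  $E[(D(T(\hat z_s)) - D(T(\hat z_u)))^2]$ that anchors unpaired blurry
  images to the supervised restoration domain, and a perceptual distance
  under a frozen feature backbone.  All discriminator inputs pass through
  differentiable augmentation $T(\cdot)$ (color, translation, cutout).
* **Simulator** — myelinated-axon phantoms and the forward model
  $z = k * x + \eta$ with underfocus / overfocus / astigmatism / combined
  kernels, so the whole method is trainable and verifiable with no
  external data.
* **Metrics** — PSNR, SSIM (pinned to the standard reference formulation),
  and the adapted Rand error for segmentation agreement.

No deep-learning framework is required: the package includes a small
reverse-mode autodiff engine over R arrays with Rcpp/BLAS convolution
kernels.

## Worked example

Simulate a paired + unpaired corpus, train a small model, and evaluate:

```r
library(semdeblur)

blurs <- list(blur_spec("underfocus", defocus_radius = 1.5, noise_sigma = 0.01))
ds   <- make_dataset(n_pairs = 8, n_unsup = 8,
                     phantom = phantom_spec(height = 64, width = 64, n_axons = 5,
                                            radius_range = c(6, 10)),
                     blur_distribution = blurs, seed = 101)
hold <- make_dataset(4, 0, phantom_spec(height = 64, width = 64, n_axons = 5,
                                        radius_range = c(6, 10)),
                     blur_distribution = blurs, seed = 901)$pairs

fit <- fit_deblur(
  ds,
  train_config(batch_size = 2, crop_size = 32, peak_lr = 2e-3,
               warmup_steps = 50, total_steps = 200, seed = 11),
  generator_config(base_channels = 8, channel_multipliers = c(1, 1, 2, 2, 2),
                   residual_blocks_per_scale = 1),
  discriminator_config(n_layers = 4, base_channels = 8),
  holdout = hold, backbone = feature_backbone(c(4, 8, 8)))

fit$eval
#>   step psnr_deblurred psnr_blurry ssim_deblurred ssim_blurry
#> 1  200       23.83891    22.14217       0.913543   0.8631105
```

The held-out PSNR of the deblurred outputs (23.8 dB) exceeds that of the
raw blurry inputs (22.1 dB): two hundred steps of the adversarial
semisupervised objective already recover about +1.7 dB on this synthetic
defocus domain, with SSIM rising from 0.863 to 0.914.  Exact digits vary
with the seed; `synthetic_study()` wraps this experiment with derived
seeds for reproducible multi-seed studies.

Single images or large micrographs are restored tile-by-tile:

```r
save_checkpoint("model.rds", fit$generator)
deblur_image("blurry_tile.tiff", "model.rds", "restored.tiff",
             tiling_plan(tile = 256, overlap = 32))
```

A command-line wrapper with `simulate` / `train` / `deblur` / `evaluate`
subcommands is installed at `inst/cli/semdeblur.R`.

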