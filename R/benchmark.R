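# ---------------------------------------------------------------------------
# A self-contained scaled-down training study on synthetic phantoms, small
# enough to run on one CPU core in a couple of minutes.  Both the test
# suite and scripts/acceptance.R drive their experiments through this one
# function so the study conditions are defined in a single place.
# ---------------------------------------------------------------------------

#' Blur domains of the synthetic study
#'
#' The base domain is pure defocus; the shifted domain combines defocus
#' with an oriented astigmatic component, emulating a different acquisition
#' (cross-sample domain shift).
#'
#' @param noise_sigma additive Gaussian noise level
#' @return list with `base` and `shifted` blur distributions
#' @export
study_domains <- function(noise_sigma = 0.01) {
  list(
    base = list(blur_spec("underfocus", defocus_radius = 1.5,
                          noise_sigma = noise_sigma)),
    shifted = list(blur_spec("combined", defocus_radius = 1.5,
                             sigma_major = 2, sigma_minor = 0.8,
                             angle = pi / 6, noise_sigma = noise_sigma))
  )
}

# Tiny CPU-scale network configurations used by the study.
study_configs <- function() {
  list(
    generator = generator_config(base_channels = 8L,
                                 channel_multipliers = c(1L, 1L, 2L, 2L, 2L),
                                 residual_blocks_per_scale = 1L),
    discriminator = discriminator_config(n_layers = 4L, base_channels = 8L),
    backbone_channels = c(4L, 8L, 8L)
  )
}

#' Run the scaled-down synthetic deblurring study
#'
#' Simulates a small corpus of 64x64 myelinated-axon phantoms, degrades them
#' with the chosen blur domains, trains a tiny generator/discriminator pair,
#' and reports held-out PSNR/SSIM of the deblurred outputs against the raw
#' blurry inputs.
#'
#' Conditions: 8 supervised pairs and 8 unsupervised blurry images, 4
#' held-out pairs, batch 2, 32x32 crops, SGD with momentum 0.9 and a linear
#' warm-up; the tiny model uses a larger peak learning rate (2e-3) than the
#' full-scale recipe, as appropriate for a much smaller network trained for
#' far fewer steps.
#'
#' @param seed master seed; dataset and training seeds are derived from it
#' @param total_steps optimization steps
#' @param semisupervised include the unsupervised bank and loss term?
#' @param domain_shift if `TRUE`, the unsupervised bank and the held-out set
#'   come from the shifted blur domain while supervised pairs stay in the
#'   base domain (the cross-sample setting); if `FALSE` everything is drawn
#'   from the base domain
#' @param n_pairs,n_unsup,n_holdout corpus sizes
#' @return list with `eval` (named vector of held-out metrics), `log`
#'   (per-step losses), `generator`
#' @export
synthetic_study <- function(seed, total_steps = 200L, semisupervised = TRUE,
                            domain_shift = FALSE, n_pairs = 8L,
                            n_unsup = 8L, n_holdout = 4L) {
  seed <- as.integer(seed)
  dom <- study_domains()
  sup_blur <- dom$base
  unsup_blur <- if (domain_shift) dom$shifted else dom$base
  hold_blur <- if (domain_shift) dom$shifted else dom$base

  ph <- phantom_spec(height = 64L, width = 64L, n_axons = 5L,
                     radius_range = c(6, 10),
                     myelin_thickness_range = c(1.5, 3), seed = 1L)
  ds <- make_dataset(n_pairs, if (semisupervised) n_unsup else 0L, ph,
                     blur_distribution = sup_blur,
                     unsup_blur_distribution = unsup_blur,
                     seed = seed %% 899999L + 101L)
  hold <- make_dataset(n_holdout, 0L, ph, blur_distribution = hold_blur,
                       seed = seed %% 899999L + 7901L)$pairs

  cf <- study_configs()
  tc <- train_config(
    batch_size = 2L, crop_size = 32L, peak_lr = 2e-3, warmup_steps = 50L,
    total_steps = as.integer(total_steps), momentum = 0.9,
    unsup_batch_size = if (semisupervised) 2L else 0L,
    seed = seed %% 899999L + 11L,
    weights = loss_weights(lambda_us = if (semisupervised) 0.01 else 0)
  )
  bb <- feature_backbone(cf$backbone_channels)
  fit <- fit_deblur(ds, tc, cf$generator, cf$discriminator, holdout = hold,
                    backbone = bb)
  ev <- fit$eval[nrow(fit$eval), ]
  list(eval = unlist(ev), log = fit$log, generator = fit$generator)
}
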