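# Shared tiny configurations and helpers for CPU-scale tests.

tiny_gen_cfg <- function() {
  generator_config(base_channels = 4L,
                   channel_multipliers = c(1L, 1L, 2L, 2L, 2L),
                   residual_blocks_per_scale = 1L)
}

tiny_disc_cfg <- function() discriminator_config(n_layers = 4L,
                                                 base_channels = 4L)

tiny_backbone <- function() feature_backbone(c(4L, 4L, 4L))

rand_img4 <- function(h = 32L, w = 32L, n = 1L) {
  array(stats::runif(h * w * n, -1, 1), dim = c(h, w, 1L, n))
}

# Access to internal autodiff ops for white-box tests.
sd_ns <- asNamespace("semdeblur")

tiny_phantom <- function(seed = 1L) {
  phantom_spec(height = 64L, width = 64L, n_axons = 4L,
               radius_range = c(5, 9), myelin_thickness_range = c(1.5, 3),
               seed = seed)
}

# One small supervised/unsupervised batch pair for train_step tests.
tiny_batches <- function(seed = 5L, n = 2L, crop = 32L) {
  ds <- make_dataset(n, n, tiny_phantom(),
                     list(blur_spec("underfocus", defocus_radius = 1.5,
                                    noise_sigma = 0.01)),
                     seed = seed)
  crop1 <- function(m) m[seq_len(crop), seq_len(crop)]
  ns <- sd_ns
  list(
    sup = list(z = ns$stack_batch(lapply(ds$pairs, function(p) crop1(p$z))),
               x = ns$stack_batch(lapply(ds$pairs, function(p) crop1(p$x)))),
    unsup = ns$stack_batch(lapply(ds$unsup, function(u) crop1(u$z)))
  )
}

# Brute-force adapted Rand error over all unordered pairs of distinct
# foreground pixels -- the O(n^2) oracle for the contingency-table version.
brute_force_arand <- function(pred, gt) {
  fg <- which(gt > 0L)
  p <- pred[fg]; g <- gt[fg]
  n <- length(fg)
  joined_both <- joined_pred <- joined_gt <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      sp <- p[i] == p[j]
      sg <- g[i] == g[j]
      if (sp && sg) joined_both <- joined_both + 1
      if (sp) joined_pred <- joined_pred + 1
      if (sg) joined_gt <- joined_gt + 1
    }
  }
  if (joined_pred == 0 || joined_gt == 0) {
    return(if (joined_pred == joined_gt) 0 else 1)
  }
  pr <- joined_both / joined_pred
  rc <- joined_both / joined_gt
  if (pr + rc == 0) return(1)
  1 - 2 * pr * rc / (pr + rc)
}
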