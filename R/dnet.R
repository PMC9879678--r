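# ---------------------------------------------------------------------------
# Least-squares discriminator: a stack of 4x4 stride-2 convolution stages,
# each followed by instance normalization and LeakyReLU, then a 1-channel
# convolution head producing a spatial patch score map with no output
# nonlinearity (least-squares GAN).  The scalar score of an image is the
# mean of its map.
# ---------------------------------------------------------------------------

#' Discriminator configuration
#'
#' @param n_layers number of stride-2 stages (>= 3)
#' @param base_channels channels of the first stage; doubled per stage,
#'   capped at `8 * base_channels`
#' @param leaky_slope negative slope of the LeakyReLU activations
#' @return a `discriminator_config` list
#' @export
discriminator_config <- function(n_layers = 4L, base_channels = 64L,
                                 leaky_slope = 0.2) {
  stopifnot(n_layers >= 3L, base_channels >= 4L,
            leaky_slope > 0, leaky_slope < 1)
  structure(list(n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope),
            class = "discriminator_config")
}

#' Build the discriminator network
#'
#' @param cfg a [discriminator_config()]
#' @return list with `cfg`, modules and `params`
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  if (!inherits(cfg, "discriminator_config")) {
    cfg <- do.call(discriminator_config, cfg)
  }
  stages <- list()
  cin <- 1L
  for (l in seq_len(cfg$n_layers)) {
    cout <- min(cfg$base_channels * 2L^(l - 1L), 8L * cfg$base_channels)
    stages[[l]] <- nn_conv(sprintf("d%d", l), cin, cout, k = 4L,
                           stride = 2L, pad = 1L)
    cin <- cout
  }
  head <- nn_conv("dhead", cin, 1L, k = 3L, stride = 1L, pad = 1L)
  d <- list(cfg = cfg, stages = stages, head = head)
  d$params <- collect_params(d[c("stages", "head")])
  d
}

#' Score an image batch with the discriminator
#'
#' @param disc a built discriminator
#' @param tape autodiff tape
#' @param img input node, dims (H, W, 1, N), values nominally in `[-1, 1]`
#' @return node holding the spatial score map (H/2^n_layers x W/2^n_layers)
#' @export
d_score <- function(disc, tape, img) {
  d <- dim(img$value)
  if (d[1] < 2L^disc$cfg$n_layers || d[2] < 2L^disc$cfg$n_layers) {
    stop("input too small for ", disc$cfg$n_layers, " stride-2 stages")
  }
  h <- img
  for (l in seq_len(disc$cfg$n_layers)) {
    h <- disc$stages[[l]]$fwd(tape, h)
    h <- op_inorm(tape, h)
    h <- op_lrelu(tape, h, disc$cfg$leaky_slope)
  }
  disc$head$fwd(tape, h)
}
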