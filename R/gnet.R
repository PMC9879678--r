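# ---------------------------------------------------------------------------
# Generator: a 5-scale feature-pyramid encoder, a coarse top-down decoder
# with 1x1-reduced skip connections, and a progressive decoding grid of
# hybrid feature extractors (HFEs).  The grid holds nodes X[i, j] with scale
# i in 0..4 (0 finest, spatial size input/2^i) and step j in 1..(5 - i):
# 15 nodes in total, 5,4,3,2,1 per scale.  Column j = 1 is the coarse-decoded
# feature set and passes through no further processing before entering the
# grid.  Node (i, j) is produced from (i, j-1) plus the two immediately
# coarser nodes (i+1, j-1) and (i+2, j-1), upsampled x2 and x4, where those
# exist.  The output head applies Tanh and adds the input globally, so the
# generator is a residual refiner of the blurry image.
# ---------------------------------------------------------------------------

N_SCALES <- 5L

#' Generator configuration
#'
#' @param base_channels channel count at the finest scale (>= 4 so that tiny
#'   test configurations remain legal)
#' @param channel_multipliers integer multipliers for the five scales,
#'   finest to coarsest; scale-i width is `base_channels * multipliers[i+1]`
#' @param residual_blocks_per_scale light-weight residual blocks per encoder
#'   scale
#' @param upsample_mode `"bilinear"` (default; followed by a 3x3 convolution
#'   in the coarse decoder), `"nearest"`, or `"transposed"` (4x4/stride-2
#'   transposed convolution)
#' @param norm `"instance"` for per-scale instance normalization of encoder
#'   features, or `"none"`
#' @return a `generator_config` list
#' @export
generator_config <- function(base_channels = 32L,
                             channel_multipliers = c(1L, 2L, 4L, 8L, 8L),
                             residual_blocks_per_scale = 2L,
                             upsample_mode = c("bilinear", "nearest",
                                               "transposed"),
                             norm = c("instance", "none")) {
  upsample_mode <- match.arg(upsample_mode)
  norm <- match.arg(norm)
  stopifnot(base_channels >= 4L, length(channel_multipliers) == N_SCALES,
            all(channel_multipliers >= 1L), residual_blocks_per_scale >= 1L)
  structure(list(base_channels = as.integer(base_channels),
                 channel_multipliers = as.integer(channel_multipliers),
                 residual_blocks_per_scale =
                   as.integer(residual_blocks_per_scale),
                 upsample_mode = upsample_mode, norm = norm),
            class = "generator_config")
}

gen_channels <- function(cfg) cfg$base_channels * cfg$channel_multipliers

# Enumerate the (i, j) nodes of the decoding grid, i in 0..4, j in 1..5-i.
grid_nodes <- function() {
  out <- list()
  for (i in 0:(N_SCALES - 1L)) {
    for (j in seq_len(N_SCALES - i)) out[[length(out) + 1L]] <- c(i = i, j = j)
  }
  out
}

# Which coarser nodes feed node (i, j)?  (i+1, j-1) and (i+2, j-1), when
# they exist in the triangular grid.
hfe_inputs <- function(i, j) {
  stopifnot(j >= 2L)
  out <- list()
  if (i + 1L <= N_SCALES - 1L && (j - 1L) <= N_SCALES - (i + 1L)) {
    out$c1 <- c(i = i + 1L, j = j - 1L)
  }
  if (i + 2L <= N_SCALES - 1L && (j - 1L) <= N_SCALES - (i + 2L)) {
    out$c2 <- c(i = i + 2L, j = j - 1L)
  }
  out
}

# Upsampling module used by the coarse decoder (maps channels cin -> cout).
nn_upsample <- function(name, cin, cout, mode) {
  if (mode == "transposed") return(nn_convT2(name, cin, cout))
  cv <- nn_conv(paste0(name, ".conv"), cin, cout)
  raw <- if (mode == "bilinear") "bilinear" else "nearest"
  list(
    conv = cv,
    fwd = function(tape, x) cv$fwd(tape, op_up2(tape, x, raw))
  )
}

# One hybrid feature extractor producing node (i, j).
#
# Wiring: a = ReLU(conv_a(skip)); m = conv_cat(concat(a, up2(c1), up4(c2)));
# s = skip + m; out = s + conv_post(ReLU(s)).  With all weights zero the
# block is the identity on `skip`.  The two convolutions feeding the
# additive skips start downscaled (fixup-style) so feature variance does
# not grow multiplicatively along the decoding grid at init.
nn_hfe <- function(name, ch_i, ch_c1 = NULL, ch_c2 = NULL) {
  cin_cat <- ch_i + (ch_c1 %||% 0L) + (ch_c2 %||% 0L)
  conv_a <- nn_conv(paste0(name, ".a"), ch_i, ch_i)
  conv_cat <- nn_conv(paste0(name, ".cat"), cin_cat, ch_i,
                      std = 0.1 * sqrt(2 / (9 * cin_cat)))
  conv_post <- nn_conv(paste0(name, ".post"), ch_i, ch_i,
                       std = 0.1 * sqrt(2 / (9 * ch_i)))
  list(
    conv_a = conv_a, conv_cat = conv_cat, conv_post = conv_post,
    has_c1 = !is.null(ch_c1), has_c2 = !is.null(ch_c2),
    fwd = function(tape, skip, c1 = NULL, c2 = NULL) {
      a <- op_relu(tape, conv_a$fwd(tape, skip))
      parts <- list(a)
      if (!is.null(c1)) parts <- c(parts, list(op_up2(tape, c1)))
      if (!is.null(c2)) {
        parts <- c(parts, list(op_up2(tape, op_up2(tape, c2))))
      }
      m <- conv_cat$fwd(tape, if (length(parts) > 1L) {
        op_concat(tape, parts)
      } else {
        parts[[1L]]
      })
      s <- op_add(tape, skip, m)
      op_add(tape, s, conv_post$fwd(tape, op_relu(tape, s)))
    }
  )
}

#' Build the generator network
#'
#' @param cfg a [generator_config()]
#' @return list with `cfg`, the module tree, and `params` (flat named list)
#' @export
build_generator <- function(cfg = generator_config()) {
  if (!inherits(cfg, "generator_config")) cfg <- do.call(generator_config, cfg)
  ch <- gen_channels(cfg)

  enc <- list(inconv = nn_conv("enc0.in", 1L, ch[1]))
  for (i in 2:N_SCALES) {
    enc[[paste0("down", i - 1L)]] <-
      nn_conv(sprintf("enc%d.down", i - 1L), ch[i - 1L], ch[i], stride = 2L)
  }
  for (i in seq_len(N_SCALES)) {
    for (r in seq_len(cfg$residual_blocks_per_scale)) {
      enc[[sprintf("res%d_%d", i - 1L, r)]] <-
        nn_resblock(sprintf("enc%d.res%d", i - 1L, r), ch[i])
    }
  }

  skip1x1 <- list()
  updec <- list()
  for (i in seq_len(N_SCALES - 1L)) {      # scales 0..3
    skip1x1[[i]] <- nn_conv(sprintf("dec%d.skip", i - 1L), ch[i], ch[i],
                            k = 1L, pad = 0L)
    updec[[i]] <- nn_upsample(sprintf("dec%d.up", i - 1L), ch[i + 1L], ch[i],
                              cfg$upsample_mode)
  }

  hfe <- list()
  for (nd in grid_nodes()) {
    i <- nd[["i"]]; j <- nd[["j"]]
    if (j < 2L) next
    ins <- hfe_inputs(i, j)
    hfe[[sprintf("h%d_%d", i, j)]] <- nn_hfe(
      sprintf("hfe%d_%d", i, j), ch[i + 1L],
      ch_c1 = if (!is.null(ins$c1)) ch[i + 2L],
      ch_c2 = if (!is.null(ins$c2)) ch[i + 3L]
    )
  }

  # Near-identity residual head: small-variance init so a fresh generator is
  # approximately the identity map (the Tanh residual starts near zero).
  head <- nn_conv("head", ch[1], 1L, std = 1e-3)

  g <- list(cfg = cfg, enc = enc, skip1x1 = skip1x1, updec = updec,
            hfe = hfe, head = head)
  g$params <- collect_params(g[c("enc", "skip1x1", "updec", "hfe", "head")])
  g
}

#' Encode a blurry image into the 5-scale feature pyramid
#'
#' @param gen a built generator
#' @param tape autodiff tape
#' @param z input node with values in `[-1, 1]`, spatial dims divisible by 16
#' @return list of 5 feature nodes, finest first
#' @export
gen_encode <- function(gen, tape, z) {
  d <- dim(z$value)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop("input spatial dims must be divisible by 16; pad required")
  }
  cfg <- gen$cfg
  blocks <- vector("list", N_SCALES)
  h <- gen$enc$inconv$fwd(tape, z)
  for (i in seq_len(N_SCALES)) {
    if (i > 1L) h <- gen$enc[[paste0("down", i - 1L)]]$fwd(tape, h)
    for (r in seq_len(cfg$residual_blocks_per_scale)) {
      h <- gen$enc[[sprintf("res%d_%d", i - 1L, r)]]$fwd(tape, h)
    }
    if (cfg$norm == "instance") h <- op_inorm(tape, h)
    blocks[[i]] <- h
  }
  blocks
}

#' Coarse top-down decoding: fill column j = 1 of the grid
#'
#' The coarsest encoder block seeds X[4, 1]; each finer node is
#' `upsample(X[i+1, 1]) + conv1x1(encoder block i)`.
#'
#' @param gen a built generator
#' @param tape autodiff tape
#' @param blocks encoder pyramid from [gen_encode()]
#' @return list of 5 column-1 nodes, finest first
#' @export
gen_coarse_decode <- function(gen, tape, blocks) {
  stopifnot(length(blocks) == N_SCALES)
  col1 <- vector("list", N_SCALES)
  col1[[N_SCALES]] <- blocks[[N_SCALES]]
  for (i in seq(N_SCALES - 1L, 1L)) {
    up <- gen$updec[[i]]$fwd(tape, col1[[i + 1L]])
    sk <- gen$skip1x1[[i]]$fwd(tape, blocks[[i]])
    col1[[i]] <- op_add(tape, up, sk)
  }
  col1
}

#' Progressive decoding through the HFE grid
#'
#' Fills columns j = 2..(5 - i) in increasing j and returns the full grid.
#' The finest terminal node is `grid[[1]][[5]]` (X[0, 5]).
#'
#' @param gen a built generator
#' @param tape autodiff tape
#' @param col1 column-1 nodes from [gen_coarse_decode()]
#' @return nested list `grid[[i+1]][[j]]` of nodes
#' @export
gen_progressive_decode <- function(gen, tape, col1) {
  grid <- lapply(seq_len(N_SCALES), function(si) {
    v <- vector("list", N_SCALES - si + 1L)
    v[[1L]] <- col1[[si]]
    v
  })
  for (j in 2:N_SCALES) {
    for (si in seq_len(N_SCALES - j + 1L)) {       # scale index = i + 1
      i <- si - 1L
      ins <- hfe_inputs(i, j)
      mod <- gen$hfe[[sprintf("h%d_%d", i, j)]]
      c1 <- if (!is.null(ins$c1)) grid[[si + 1L]][[j - 1L]]
      c2 <- if (!is.null(ins$c2)) grid[[si + 2L]][[j - 1L]]
      grid[[si]][[j]] <- mod$fwd(tape, grid[[si]][[j - 1L]], c1, c2)
    }
  }
  grid
}

#' Full generator forward pass
#'
#' `output = z + Tanh(head_conv(X[0, 5]))`: the network predicts a bounded
#' residual on top of the blurry input.
#'
#' @param gen a built generator
#' @param tape autodiff tape
#' @param z input node, values in `[-1, 1]`, dims (H, W, 1, N)
#' @return output node, same shape as the input
#' @export
gen_forward <- function(gen, tape, z) {
  blocks <- gen_encode(gen, tape, z)
  col1 <- gen_coarse_decode(gen, tape, blocks)
  grid <- gen_progressive_decode(gen, tape, col1)
  x05 <- grid[[1L]][[N_SCALES]]
  r <- op_tanh(tape, gen$head$fwd(tape, x05))
  op_add(tape, z, r)
}

# Convenience: run the generator on a plain array, no gradients kept.
gen_apply <- function(gen, z_array) {
  tape <- ad_tape()
  out <- gen_forward(gen, tape, op_input(tape, z_array))
  out$value
}
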