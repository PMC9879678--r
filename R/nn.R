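# ---------------------------------------------------------------------------
# Network building blocks on top of the autodiff engine: convolution modules
# with He initialization, light-weight residual blocks, parameter
# collection, SGD-with-momentum optimizer, and checkpoint (de)serialization.
# ---------------------------------------------------------------------------

# He-normal initialization for a (kh, kw, cin, cout) weight tensor.
init_conv_w <- function(kh, kw, cin, cout, gain = sqrt(2), std = NULL) {
  if (is.null(std)) std <- gain / sqrt(kh * kw * cin)
  array(stats::rnorm(kh * kw * cin * cout, sd = std),
        dim = c(kh, kw, cin, cout))
}

#' Create a convolution module
#'
#' @param name parameter name prefix
#' @param cin,cout input/output channel counts
#' @param k kernel size (square)
#' @param stride stride
#' @param pad zero padding (defaults to `k %/% 2`, i.e. "same" for odd k)
#' @param std optional weight s.d. override (used for the near-identity head)
#' @return list with params `w`, `b` and a `fwd(tape, x)` closure
#' @keywords internal
nn_conv <- function(name, cin, cout, k = 3L, stride = 1L, pad = k %/% 2L,
                    std = NULL) {
  w <- new_param(init_conv_w(k, k, cin, cout, std = std),
                 paste0(name, ".w"))
  b <- new_param(numeric(cout), paste0(name, ".b"))
  list(
    w = w, b = b,
    fwd = function(tape, x) op_conv(tape, x, w, b, stride, pad)
  )
}

# Transposed convolution (kernel 4, stride 2, pad 1): doubles H and W.
nn_convT2 <- function(name, cin, cout) {
  w <- new_param(init_conv_w(4L, 4L, cout, cin), paste0(name, ".w"))
  b <- new_param(numeric(cout), paste0(name, ".b"))
  list(
    w = w, b = b,
    fwd = function(tape, x) op_convT2(tape, x, w, b)
  )
}

# Light-weight residual block: conv -> ReLU -> conv, plus identity skip.
# No normalization inside the block; the closing conv starts downscaled
# (fixup-style) so stacked blocks preserve feature variance at init.
nn_resblock <- function(name, ch) {
  c1 <- nn_conv(paste0(name, ".c1"), ch, ch)
  c2 <- nn_conv(paste0(name, ".c2"), ch, ch,
                std = 0.1 * sqrt(2 / (9 * ch)))
  list(
    c1 = c1, c2 = c2,
    fwd = function(tape, x) {
      h <- op_relu(tape, c1$fwd(tape, x))
      op_add(tape, x, c2$fwd(tape, h))
    }
  )
}

# Recursively collect all parameter environments from a nested module list.
collect_params <- function(x) {
  if (is.environment(x)) {
    if (!is.null(x$name)) return(stats::setNames(list(x), x$name))
    return(list())
  }
  if (is.list(x)) {
    out <- list()
    for (el in x) {
      if (is.function(el)) next
      out <- c(out, collect_params(el))
    }
    return(out)
  }
  list()
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

param_values <- function(params) lapply(params, function(p) p$value)

set_param_values <- function(params, values) {
  stopifnot(all(names(params) %in% names(values)))
  for (nm in names(params)) params[[nm]]$value <- values[[nm]]
  invisible(NULL)
}

# --- SGD with momentum ------------------------------------------------------

sgd_new <- function(params, momentum = 0.9) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$momentum <- momentum
  st$velocity <- lapply(params, function(p) p$value * 0)
  st
}

sgd_step <- function(opt, lr) {
  for (nm in names(opt$params)) {
    p <- opt$params[[nm]]
    if (is.null(p$grad)) next
    v <- opt$momentum * opt$velocity[[nm]] + p$grad
    opt$velocity[[nm]] <- v
    p$value <- p$value - lr * v
  }
  invisible(NULL)
}

# --- checkpoints ------------------------------------------------------------

#' Save a training checkpoint
#'
#' Stores generator and discriminator weights, optimizer momenta, the full
#' configuration, the step counter and the RNG state, so that training can be
#' resumed bitwise-identically.
#'
#' @param path file to write (RDS format)
#' @param generator,discriminator networks as built by [build_generator()]
#'   and [build_discriminator()]
#' @param opt_g,opt_d optimizer states (may be `NULL` for inference-only)
#' @param step global step counter
#' @param config full experiment configuration list
#' @param rng_state the current `.Random.seed`, if any
#' @export
save_checkpoint <- function(path, generator, discriminator = NULL,
                            opt_g = NULL, opt_d = NULL, step = 0L,
                            config = list(), rng_state = NULL) {
  ck <- list(
    format = "semdeblur-checkpoint-1",
    step = step,
    config = config,
    generator = list(config = generator$cfg,
                     params = param_values(generator$params)),
    discriminator = if (!is.null(discriminator))
      list(config = discriminator$cfg,
           params = param_values(discriminator$params)),
    opt_g = if (!is.null(opt_g)) list(momentum = opt_g$momentum,
                                      velocity = opt_g$velocity),
    opt_d = if (!is.null(opt_d)) list(momentum = opt_d$momentum,
                                      velocity = opt_d$velocity),
    rng_state = rng_state
  )
  saveRDS(ck, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file
#' @return list with rebuilt `generator` (and `discriminator`, optimizer
#'   momenta, step, config, rng_state when present)
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "semdeblur-checkpoint-1")) {
    stop("not a semdeblur checkpoint: ", path)
  }
  g <- build_generator(ck$generator$config)
  set_param_values(g$params, ck$generator$params)
  d <- NULL
  if (!is.null(ck$discriminator)) {
    d <- build_discriminator(ck$discriminator$config)
    set_param_values(d$params, ck$discriminator$params)
  }
  list(generator = g, discriminator = d, step = ck$step, config = ck$config,
       opt_g = ck$opt_g, opt_d = ck$opt_d, rng_state = ck$rng_state)
}
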