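#' @useDynLib semdeblur, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation over 4D image tensors.
#
# A tape records operation nodes in execution order; ad_backward() walks the
# tape in reverse, accumulating gradients.  Tensors are plain R arrays with
# dim (H, W, C, N); scalar losses are length-1 numerics.  Trainable
# parameters are environments created by new_param(); operations that
# consume parameters accumulate directly into param$grad, so parameters are
# not tape nodes themselves.
# ---------------------------------------------------------------------------

#' Create a fresh autodiff tape
#'
#' @return an environment holding the ordered list of operation nodes
#' @keywords internal
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 64L)
  t$n <- 0L
  t
}

ad_push <- function(tape, value, parents = list(), backward = NULL,
                    needs = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  # does any gradient have to flow *into* this node?  Operations with
  # trainable parameters always set needs = TRUE; pure ops inherit it, so
  # backward work on constant subgraphs is skipped entirely.
  node$needs <- if (!is.null(needs)) needs else
    any(vapply(parents, function(p) isTRUE(p$needs), TRUE))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node$id <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

ad_accum <- function(node, g) {
  if (!isTRUE(node$needs)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the tape
#'
#' @param tape the tape that recorded the forward pass
#' @param loss a node holding a length-1 value
#' @keywords internal
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(loss$id, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    node$backward(node)
  }
  invisible(NULL)
}

#' Create a trainable parameter
#'
#' @param value initial numeric array
#' @param name identifier used in checkpoints
#' @return an environment with fields `value`, `grad`, `name`
#' @keywords internal
new_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$name <- name
  p
}

param_accum <- function(p, g) {
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(NULL)
}

# --- source nodes -----------------------------------------------------------

op_input <- function(tape, value) ad_push(tape, value, needs = TRUE)

op_const <- function(tape, value) {
  ad_push(tape, value, needs = FALSE)  # gradient sink
}

# --- convolution ------------------------------------------------------------

op_conv <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  xd <- dim(x$value)
  wd <- dim(w$value)
  y <- cpp_conv2d_fw(x$value, xd, w$value, wd, b$value, stride, pad)
  ad_push(tape, y, parents = list(x), needs = TRUE,
          backward = function(node) {
    if (isTRUE(x$needs)) {
      g <- cpp_conv2d_bw(x$value, xd, w$value, wd, node$grad, stride, pad)
      param_accum(w, g$dw)
      param_accum(b, g$db)
      ad_accum(x, g$dx)
    } else {
      param_accum(w, cpp_conv2d_bw_dw(x$value, xd, node$grad,
                                      dim(node$grad), stride, pad))
      param_accum(b, apply(node$grad, 3, sum))
    }
  })
}

# Transposed convolution with stride 2, kernel 4, pad 1 (doubles H and W).
op_convT2 <- function(tape, x, w, b) {
  xd <- dim(x$value)
  wd <- dim(w$value)
  oh <- 2L * xd[1]; ow <- 2L * xd[2]
  y <- cpp_convT_fw(x$value, xd, w$value, wd, b$value, 2L, 1L, oh, ow)
  ad_push(tape, y, parents = list(x), needs = TRUE,
          backward = function(node) {
    gd <- dim(node$grad)
    zb <- numeric(xd[3])
    dx <- cpp_conv2d_fw(node$grad, gd, w$value, wd, zb, 2L, 1L)
    dw <- cpp_conv2d_bw_dw(node$grad, gd, x$value, xd, 2L, 1L)
    db <- apply(node$grad, 3, sum)
    param_accum(w, dw)
    param_accum(b, db)
    ad_accum(x, dx)
  })
}

# --- resampling -------------------------------------------------------------

op_up2 <- function(tape, x, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  xd <- dim(x$value)
  if (mode == "bilinear") {
    y <- cpp_up2_fw(x$value, xd)
    ad_push(tape, y, parents = list(x), backward = function(node) {
      ad_accum(x, cpp_up2_bw(node$grad, xd))
    })
  } else {
    ih <- rep(seq_len(xd[1]), each = 2L)
    iw <- rep(seq_len(xd[2]), each = 2L)
    y <- x$value[ih, iw, , , drop = FALSE]
    ad_push(tape, y, parents = list(x), backward = function(node) {
      g <- node$grad
      gh <- g[seq(1, 2 * xd[1], 2), , , , drop = FALSE] +
        g[seq(2, 2 * xd[1], 2), , , , drop = FALSE]
      gg <- gh[, seq(1, 2 * xd[2], 2), , , drop = FALSE] +
        gh[, seq(2, 2 * xd[2], 2), , , drop = FALSE]
      ad_accum(x, gg)
    })
  }
}

# --- elementwise ------------------------------------------------------------

op_relu <- function(tape, x) {
  ad_push(tape, cpp_relu_fw(x$value), parents = list(x),
          backward = function(node) {
    ad_accum(x, cpp_lrelu_bw(x$value, node$grad, 0))
  })
}

op_lrelu <- function(tape, x, slope = 0.2) {
  ad_push(tape, cpp_lrelu_fw(x$value, slope), parents = list(x),
          backward = function(node) {
    ad_accum(x, cpp_lrelu_bw(x$value, node$grad, slope))
  })
}

op_tanh <- function(tape, x) {
  y <- tanh(x$value)
  ad_push(tape, y, parents = list(x), backward = function(node) {
    ad_accum(x, node$grad * (1 - y * y))
  })
}

op_add <- function(tape, a, b) {
  ad_push(tape, a$value + b$value, parents = list(a, b),
          backward = function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, node$grad)
  })
}

op_sub <- function(tape, a, b) {
  ad_push(tape, a$value - b$value, parents = list(a, b),
          backward = function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, -node$grad)
  })
}

op_scale <- function(tape, x, k) {
  ad_push(tape, x$value * k, parents = list(x), backward = function(node) {
    ad_accum(x, node$grad * k)
  })
}

op_add_scalar <- function(tape, x, k) {
  ad_push(tape, x$value + k, parents = list(x), backward = function(node) {
    ad_accum(x, node$grad)
  })
}

# y = A * x + C with constant arrays A, C (broadcast already expanded)
op_affine_const <- function(tape, x, A, C) {
  ad_push(tape, A * x$value + C, parents = list(x),
          backward = function(node) ad_accum(x, node$grad * A))
}

op_mul_mask <- function(tape, x, mask) {
  ad_push(tape, x$value * mask, parents = list(x),
          backward = function(node) ad_accum(x, node$grad * mask))
}

op_square <- function(tape, x) {
  ad_push(tape, x$value^2, parents = list(x), backward = function(node) {
    ad_accum(x, node$grad * 2 * x$value)
  })
}

op_abs <- function(tape, x) {
  s <- sign(x$value)
  ad_push(tape, abs(x$value), parents = list(x), backward = function(node) {
    ad_accum(x, node$grad * s)
  })
}

# --- normalization ----------------------------------------------------------

# Instance normalization without affine parameters: for each (channel,
# sample), standardize over the spatial extent.
op_inorm <- function(tape, x, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- matrix(x$value, nrow = hw)
  mu <- colMeans(m)
  cen <- sweep(m, 2, mu)
  v <- colMeans(cen * cen)
  s <- sqrt(v + eps)
  ym <- sweep(cen, 2, s, "/")
  y <- array(ym, dim = d)
  ad_push(tape, y, parents = list(x), backward = function(node) {
    g <- matrix(node$grad, nrow = hw)
    gm <- colMeans(g)
    gym <- colMeans(g * ym)
    dxm <- sweep(sweep(g, 2, gm) - sweep(ym, 2, gym, "*"), 2, s, "/")
    ad_accum(x, array(dxm, dim = d))
  })
}

# --- structural -------------------------------------------------------------

op_concat <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  cc <- vapply(ds, `[`, integer(1), 3L)
  d1 <- ds[[1]]
  y <- cpp_concat_c(lapply(xs, function(x) x$value), cc, d1[1], d1[2],
                    d1[4])
  ad_push(tape, y, parents = xs, backward = function(node) {
    at <- 0L
    for (i in seq_along(xs)) {
      ad_accum(xs[[i]], cpp_slice_c(node$grad, dim(node$grad), at + 1L,
                                    cc[i]))
      at <- at + cc[i]
    }
  })
}

# Integer-pixel translation with zero fill; per-sample shifts.
# shifts: N x 2 matrix of (rows, cols); positive moves content down/right.
op_translate <- function(tape, x, shifts) {
  d <- dim(x$value)
  shift1 <- function(a, dh, dw) {
    out <- array(0, dim = dim(a))
    H <- dim(a)[1]; W <- dim(a)[2]
    if (abs(dh) >= H || abs(dw) >= W) return(out)
    sr <- max(1, 1 + dh):min(H, H + dh)
    sc <- max(1, 1 + dw):min(W, W + dw)
    out[sr, sc, , ] <- a[sr - dh, sc - dw, , , drop = FALSE]
    out
  }
  y <- x$value
  for (n in seq_len(d[4])) {
    if (shifts[n, 1] != 0 || shifts[n, 2] != 0) {
      y[, , , n] <- shift1(x$value[, , , n, drop = FALSE],
                           shifts[n, 1], shifts[n, 2])
    }
  }
  ad_push(tape, y, parents = list(x), backward = function(node) {
    g <- node$grad
    for (n in seq_len(d[4])) {
      if (shifts[n, 1] != 0 || shifts[n, 2] != 0) {
        g[, , , n] <- shift1(node$grad[, , , n, drop = FALSE],
                             -shifts[n, 1], -shifts[n, 2])
      }
    }
    ad_accum(x, g)
  })
}

# Concatenate two equal-shape stacks along the batch dimension.
op_concat_n <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  y <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3],
                                          da[4] + db[4]))
  ad_push(tape, y, parents = list(a, b), backward = function(node) {
    ad_accum(a, node$grad[, , , seq_len(da[4]), drop = FALSE])
    ad_accum(b, node$grad[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

# Slice samples [from, from+count-1] along the batch dimension.
op_slice_n <- function(tape, x, from, count) {
  d <- dim(x$value)
  idx <- from:(from + count - 1L)
  y <- x$value[, , , idx, drop = FALSE]
  ad_push(tape, y, parents = list(x), backward = function(node) {
    g <- array(0, dim = d)
    g[, , , idx] <- node$grad
    ad_accum(x, g)
  })
}

# --- reductions -------------------------------------------------------------

op_mean <- function(tape, x) {
  n <- length(x$value)
  ad_push(tape, mean(x$value), parents = list(x), backward = function(node) {
    ad_accum(x, array(node$grad / n, dim = dim(x$value) %||% n))
  })
}

# per-sample means: (H,W,C,N) -> length-N vector
op_sample_means <- function(tape, x) {
  d <- dim(x$value)
  hwc <- d[1] * d[2] * d[3]
  v <- colMeans(matrix(x$value, nrow = hwc))
  ad_push(tape, v, parents = list(x), backward = function(node) {
    g <- array(rep(node$grad / hwc, each = hwc), dim = d)
    ad_accum(x, g)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
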