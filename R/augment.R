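# ---------------------------------------------------------------------------
# Differentiable augmentation T(.) applied to every image entering the
# discriminator.  Three transforms, composed color -> translation -> cutout,
# each sampled freshly per image per call and each differentiable w.r.t.
# pixel values wherever defined, so adversarial gradients flow through T to
# the generator.
# ---------------------------------------------------------------------------

#' Augmentation policy
#'
#' Defaults follow the published defaults of the differentiable-augmentation
#' method for GAN training: brightness shift +-0.5, contrast scale in
#' [0.5, 1.5], translation up to 1/8 of the side, cutout square of half the
#' side.
#'
#' @param enable_color,enable_translation,enable_cutout switches
#' @param brightness_range half-width of the uniform brightness shift
#' @param contrast_range half-width of the uniform contrast factor about 1
#' @param translation_fraction max shift as a fraction of the side (<= 0.5)
#' @param cutout_fraction half the cutout side as a fraction of the image
#'   side (< 0.5, so a nonzero-gradient region always survives)
#' @return an `aug_policy` list
#' @export
aug_policy <- function(enable_color = TRUE, enable_translation = TRUE,
                       enable_cutout = TRUE, brightness_range = 0.5,
                       contrast_range = 0.5, translation_fraction = 0.125,
                       cutout_fraction = 0.25) {
  stopifnot(translation_fraction >= 0, translation_fraction <= 0.5,
            cutout_fraction >= 0, cutout_fraction < 0.5,
            brightness_range >= 0, contrast_range >= 0, contrast_range < 1)
  structure(list(enable_color = enable_color,
                 enable_translation = enable_translation,
                 enable_cutout = enable_cutout,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 translation_fraction = translation_fraction,
                 cutout_fraction = cutout_fraction),
            class = "aug_policy")
}

#' Grayscale color augmentation (brightness + contrast)
#'
#' `out = m + s * (img + b - m)` with the per-image mean `m` treated as a
#' constant, so the gradient w.r.t. every pixel is exactly `s`.
#'
#' @param tape autodiff tape
#' @param img image node (H, W, 1, N)
#' @param b per-sample brightness shifts (length N or 1)
#' @param s per-sample contrast factors (length N or 1)
#' @return augmented node
#' @export
apply_color <- function(tape, img, b, s) {
  d <- dim(img$value)
  n <- d[4]
  b <- rep_len(b, n); s <- rep_len(s, n)
  hwc <- d[1] * d[2] * d[3]
  m <- colMeans(matrix(img$value, nrow = hwc))   # detached per-image mean
  A <- array(rep(s, each = hwc), dim = d)
  C <- array(rep(m + s * (b - m), each = hwc), dim = d)
  op_affine_const(tape, img, A, C)
}

#' Integer-pixel translation with zero padding
#'
#' @param tape autodiff tape
#' @param img image node
#' @param shifts N x 2 integer matrix (rows, cols); positive moves content
#'   down/right, vacated pixels become 0
#' @return translated node
#' @export
apply_translation <- function(tape, img, shifts) {
  op_translate(tape, img, shifts)
}

#' Cutout: zero a square region per image
#'
#' Gradient is 1 outside the square and 0 inside.
#'
#' @param tape autodiff tape
#' @param img image node
#' @param centers N x 2 matrix of square centers (rows, cols)
#' @param size side length of the square in pixels (scalar or length N)
#' @return node with the squares zeroed
#' @export
apply_cutout <- function(tape, img, centers, size) {
  d <- dim(img$value)
  n <- d[4]
  size <- rep_len(as.integer(size), n)
  mask <- array(1, dim = d)
  for (k in seq_len(n)) {
    if (size[k] <= 0L) next
    h0 <- centers[k, 1] - size[k] %/% 2L
    w0 <- centers[k, 2] - size[k] %/% 2L
    rr <- max(1L, h0):min(d[1], h0 + size[k] - 1L)
    cc <- max(1L, w0):min(d[2], w0 + size[k] - 1L)
    if (length(rr) > 0L && length(cc) > 0L) mask[rr, cc, , k] <- 0
  }
  op_mul_mask(tape, img, mask)
}

#' Differentiable augmentation pipeline T(.)
#'
#' Composes color, translation and cutout with freshly drawn parameters for
#' every image in the batch (from the current R RNG stream).  Real and fake
#' batches each receive independent draws.
#'
#' @param tape autodiff tape
#' @param img image node (H, W, 1, N)
#' @param policy an [aug_policy()]
#' @return augmented node, differentiable end-to-end
#' @export
aug_T <- function(tape, img, policy = aug_policy()) {
  d <- dim(img$value)
  n <- d[4]
  side <- min(d[1], d[2])
  out <- img
  if (policy$enable_color) {
    b <- stats::runif(n, -policy$brightness_range, policy$brightness_range)
    s <- stats::runif(n, 1 - policy$contrast_range, 1 + policy$contrast_range)
    out <- apply_color(tape, out, b, s)
  }
  if (policy$enable_translation) {
    mx <- floor(policy$translation_fraction * side)
    if (mx > 0) {
      sh <- cbind(sample.int(2L * mx + 1L, n, replace = TRUE) - mx - 1L,
                  sample.int(2L * mx + 1L, n, replace = TRUE) - mx - 1L)
      out <- apply_translation(tape, out, sh)
    }
  }
  if (policy$enable_cutout) {
    sz <- as.integer(round(2 * policy$cutout_fraction * side))
    if (sz > 0) {
      ce <- cbind(sample.int(d[1], n, replace = TRUE),
                  sample.int(d[2], n, replace = TRUE))
      out <- apply_cutout(tape, out, ce, sz)
    }
  }
  out
}
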