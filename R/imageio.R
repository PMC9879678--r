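# ---------------------------------------------------------------------------
# Grayscale image I/O (PNG and TIFF, 8/16-bit) and tiled inference over
# large micrographs.
# ---------------------------------------------------------------------------

#' Read a grayscale image (PNG or TIFF)
#'
#' Multi-channel images are reduced to grayscale by channel averaging.
#'
#' @param path image file; format chosen by extension
#' @return numeric matrix in `[0, 1]`
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  as.matrix(img)
}

#' Write a grayscale image (PNG or TIFF)
#'
#' PNG output is 8-bit; TIFF honours `bitdepth` (use 16 for lossless
#' storage of label masks and high-precision intensities).
#'
#' @param img numeric matrix in `[0, 1]`
#' @param path output file; format chosen by extension
#' @param bitdepth 8 or 16 (TIFF only)
#' @return `path`, invisibly
#' @export
write_gray_image <- function(img, path, bitdepth = 8L) {
  stopifnot(bitdepth %in% c(8L, 16L))
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path,
                                bits.per.sample = as.integer(bitdepth)),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Tiling plan for large-micrograph inference
#'
#' @param tile tile side in pixels, divisible by 16
#' @param overlap overlap between adjacent tiles, `< tile / 2`
#' @param blend `"feather"` (linear-ramp weights in the overlaps) or
#'   `"average"`
#' @return a `tiling_plan` list
#' @export
tiling_plan <- function(tile = 256L, overlap = 32L,
                        blend = c("feather", "average")) {
  blend <- match.arg(blend)
  stopifnot(tile %% 16L == 0L, overlap >= 0L, overlap < tile / 2)
  structure(list(tile = as.integer(tile), overlap = as.integer(overlap),
                 blend = blend), class = "tiling_plan")
}

# Tile start positions covering [1, n] with the requested overlap.
tile_starts <- function(n, tile, overlap) {
  if (tile >= n) return(1L)
  step <- tile - overlap
  s <- seq(1L, n - tile, by = step)
  if (s[length(s)] + tile - 1L < n) s <- c(s, n - tile + 1L)
  as.integer(s)
}

# Feather weight profile along one axis of a tile.
feather_profile <- function(tile, overlap, at_start, at_end) {
  w <- rep(1, tile)
  if (overlap > 0L) {
    ramp <- seq_len(overlap) / (overlap + 1)
    if (!at_start) w[seq_len(overlap)] <- ramp
    if (!at_end) w[tile - overlap + seq_len(overlap)] <- rev(ramp)
  }
  w
}

# Reflect-pad a matrix up to the next multiple of 16 in both dims.
pad_to_16 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  ph <- (16L - H %% 16L) %% 16L
  pw <- (16L - W %% 16L) %% 16L
  if (ph > 0L) x <- x[c(seq_len(H), H - seq_len(ph)), , drop = FALSE]
  if (pw > 0L) x <- x[, c(seq_len(W), W - seq_len(pw)), drop = FALSE]
  list(x = x, H = H, W = W)
}

#' Deblur an image array with a generator, tile by tile
#'
#' The image is reflect-padded to multiples of 16, split according to the
#' plan, each tile is mapped to `[-1, 1]`, passed through the generator and
#' blended back (feathered linear ramps by default).
#'
#' @param gen a built generator
#' @param img numeric matrix in `[0, 1]`
#' @param plan a [tiling_plan()]
#' @return deblurred matrix in `[0, 1]`, same size as `img`
#' @export
deblur_array <- function(gen, img, plan = tiling_plan()) {
  pd <- pad_to_16(img)
  x <- pd$x
  H <- nrow(x); W <- ncol(x)
  tile <- min(plan$tile, H, W)
  tile <- tile - tile %% 16L
  if (tile >= H && tile >= W) {
    z <- array(x * 2 - 1, dim = c(H, W, 1L, 1L))
    out <- matrix(gen_apply(gen, z), H, W)
  } else {
    rs <- tile_starts(H, tile, plan$overlap)
    cs <- tile_starts(W, tile, plan$overlap)
    acc <- matrix(0, H, W)
    wsum <- matrix(0, H, W)
    for (r0 in rs) {
      for (c0 in cs) {
        rr <- r0:(r0 + tile - 1L)
        cc <- c0:(c0 + tile - 1L)
        z <- array(x[rr, cc] * 2 - 1, dim = c(tile, tile, 1L, 1L))
        y <- matrix(gen_apply(gen, z), tile, tile)
        w <- if (plan$blend == "feather") {
          outer(feather_profile(tile, plan$overlap, r0 == 1L,
                                r0 + tile - 1L == H),
                feather_profile(tile, plan$overlap, c0 == 1L,
                                c0 + tile - 1L == W))
        } else {
          matrix(1, tile, tile)
        }
        acc[rr, cc] <- acc[rr, cc] + w * y
        wsum[rr, cc] <- wsum[rr, cc] + w
      }
    }
    out <- acc / wsum
  }
  out <- (out + 1) / 2
  pmin(pmax(out[seq_len(pd$H), seq_len(pd$W), drop = FALSE], 0), 1)
}

#' Deblur an image file with a checkpointed generator
#'
#' @param path input image (PNG/TIFF, 8/16-bit grayscale)
#' @param checkpoint checkpoint file from [save_checkpoint()], or an
#'   already-loaded generator
#' @param out output path; written at 16-bit for TIFF, PNG defaults
#' @param plan a [tiling_plan()]
#' @return `out`, invisibly
#' @export
deblur_image <- function(path, checkpoint, out,
                         plan = tiling_plan()) {
  gen <- if (is.character(checkpoint)) {
    load_checkpoint(checkpoint)$generator
  } else {
    checkpoint
  }
  img <- read_gray_image(path)
  res <- deblur_array(gen, img, plan)
  write_gray_image(res, out, bitdepth = 16L)
  invisible(out)
}
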