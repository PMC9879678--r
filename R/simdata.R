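# ---------------------------------------------------------------------------
# Synthetic training data: myelinated-axon phantoms degraded with the linear
# blur formation model z = k * x + eta.  Phantoms emulate osmium-stained
# corpus-callosum cross-sections: dark myelin annuli around lighter axoplasm
# over a textured background.  Blur kernels cover the electron-optical
# aberration taxonomy: underfocus / overfocus (isotropic defocus discs),
# astigmatism (oriented anisotropic Gaussian), and their combination.
# ---------------------------------------------------------------------------

#' Parametric blur kernel description
#'
#' @param mode one of `"underfocus"`, `"overfocus"`, `"astigmatism"`,
#'   `"combined"`, `"identity"`
#' @param defocus_radius disc radius in pixels (>= 0); overfocus is rendered
#'   as a larger-radius defocus tier (x1.5), both being defocus point-spread
#'   functions of opposite defocus sign, indistinguishable in a linear
#'   intensity model
#' @param sigma_major,sigma_minor astigmatic Gaussian sigmas in pixels;
#'   astigmatism requires `sigma_major != sigma_minor`
#' @param angle orientation of the major axis, radians
#' @param noise_sigma s.d. of the additive zero-mean Gaussian noise
#' @param seed integer seed for the noise draw
#' @return a `blur_spec` list
#' @export
blur_spec <- function(mode = c("underfocus", "overfocus", "astigmatism",
                               "combined", "identity"),
                      defocus_radius = 2, sigma_major = 3, sigma_minor = 1,
                      angle = 0, noise_sigma = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(defocus_radius >= 0, sigma_major >= 0, sigma_minor >= 0,
            noise_sigma >= 0)
  if (mode == "astigmatism" && sigma_major == sigma_minor) {
    stop("astigmatism requires sigma_major != sigma_minor")
  }
  structure(list(mode = mode, defocus_radius = defocus_radius,
                 sigma_major = sigma_major, sigma_minor = sigma_minor,
                 angle = angle, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "blur_spec")
}

# A normalized uniform disc kernel of the given radius, anti-aliased by area
# coverage at the rim.
disc_kernel <- function(radius) {
  r <- max(radius, 1e-6)
  n <- 2L * as.integer(ceiling(r)) + 1L
  c0 <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
  k <- pmin(pmax(r + 0.5 - d, 0), 1)
  k / sum(k)
}

gauss_kernel2 <- function(sx, sy, angle = 0, nsig = 3) {
  sx <- max(sx, 1e-3); sy <- max(sy, 1e-3)
  half <- as.integer(ceiling(nsig * max(sx, sy)))
  n <- 2L * half + 1L
  u <- seq_len(n) - (half + 1L)
  X <- matrix(u, n, n)          # rows
  Y <- t(X)                     # cols
  ca <- cos(angle); sa <- sin(angle)
  a <- X * ca + Y * sa          # along major axis
  b <- -X * sa + Y * ca
  k <- exp(-0.5 * ((a / sx)^2 + (b / sy)^2))
  k / sum(k)
}

conv_full <- function(a, b) {
  # full 2D convolution of two small kernels
  na <- dim(a); nb <- dim(b)
  out <- matrix(0, na[1] + nb[1] - 1L, na[2] + nb[2] - 1L)
  for (i in seq_len(nb[1])) {
    for (j in seq_len(nb[2])) {
      out[i + seq_len(na[1]) - 1L, j + seq_len(na[2]) - 1L] <-
        out[i + seq_len(na[1]) - 1L, j + seq_len(na[2]) - 1L] + a * b[i, j]
    }
  }
  out
}

#' Render the point-spread function of a blur specification
#'
#' Underfocus and overfocus give an isotropic uniform disc (overfocus at a
#' 1.5x radius tier) convolved with a small Gaussian; astigmatism gives an
#' oriented anisotropic Gaussian; `"combined"` convolves both; `"identity"`
#' gives the delta kernel.  Kernels are nonnegative and sum to 1.
#'
#' @param spec a [blur_spec()]
#' @return a square odd-sized numeric matrix
#' @export
render_kernel <- function(spec) {
  stopifnot(inherits(spec, "blur_spec"))
  k <- switch(
    spec$mode,
    identity = matrix(1, 1, 1),
    underfocus = conv_full(disc_kernel(spec$defocus_radius),
                           gauss_kernel2(0.5, 0.5)),
    overfocus = conv_full(disc_kernel(1.5 * spec$defocus_radius),
                          gauss_kernel2(0.5, 0.5)),
    astigmatism = gauss_kernel2(spec$sigma_major, spec$sigma_minor,
                                spec$angle),
    combined = conv_full(disc_kernel(spec$defocus_radius),
                         gauss_kernel2(spec$sigma_major, spec$sigma_minor,
                                       spec$angle))
  )
  if (any(k < 0) || nrow(k) < 1L) stop("invalid kernel support")
  k / sum(k)
}

# Reflective (mirror) padding of a 2D matrix by (ph, pw) on each side.
reflect_pad <- function(x, ph, pw) {
  H <- nrow(x); W <- ncol(x)
  if (ph >= H || pw >= W) stop("kernel larger than image")
  ri <- c(rev(seq_len(ph) + 1L), seq_len(H), H - seq_len(ph))
  ci <- c(rev(seq_len(pw) + 1L), seq_len(W), W - seq_len(pw))
  x[ri, ci, drop = FALSE]
}

# 2D correlation with reflective boundary via the package's conv kernel.
# All kernels rendered here are 180-degree symmetric, so correlation and
# convolution coincide.
filter2_reflect <- function(img, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- kh %/% 2L; pw <- kw %/% 2L
  xp <- reflect_pad(img, ph, pw)
  x4 <- array(xp, dim = c(nrow(xp), ncol(xp), 1L, 1L))
  w4 <- array(k, dim = c(kh, kw, 1L, 1L))
  y <- cpp_conv2d_fw(x4, dim(x4), w4, dim(w4), 0, 1L, 0L)
  matrix(y, nrow = nrow(xp) - kh + 1L)
}

#' Apply the blur formation model z = k * x + eta
#'
#' Convolution uses a reflective boundary; the noise is zero-mean Gaussian
#' with the spec's `noise_sigma`, drawn from the spec's `seed`; the result
#' is clipped to `[0, 1]`.
#'
#' @param x numeric matrix in `[0, 1]`
#' @param spec a [blur_spec()]
#' @return blurred matrix, same size as `x`
#' @export
apply_blur <- function(x, spec) {
  stopifnot(is.matrix(x), min(x) >= -1e-9, max(x) <= 1 + 1e-9)
  k <- render_kernel(spec)
  if (nrow(k) > nrow(x) || ncol(k) > ncol(x)) {
    stop("kernel larger than image")
  }
  z <- if (nrow(k) == 1L && ncol(k) == 1L) x * k[1, 1] else
    filter2_reflect(x, k)
  if (spec$noise_sigma > 0) {
    z <- z + withr_seed(spec$seed, stats::rnorm(length(z),
                                                sd = spec$noise_sigma))
  }
  matrix(pmin(pmax(z, 0), 1), nrow = nrow(x))
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}

#' Phantom field specification
#'
#' @param height,width canvas size in pixels (>= 16)
#' @param n_axons number of myelinated-axon cross-sections
#' @param radius_range outer myelin radius range, pixels
#' @param myelin_thickness_range annulus thickness range, pixels
#' @param texture_amplitude amplitude of the smooth cytoplasmic texture
#' @param background_level mean background intensity
#' @param seed integer seed
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(height = 128L, width = 128L, n_axons = 12L,
                         radius_range = c(8, 16),
                         myelin_thickness_range = c(2, 4),
                         texture_amplitude = 0.08, background_level = 0.55,
                         seed = 1L) {
  stopifnot(height >= 16L, width >= 16L, n_axons >= 0L,
            length(radius_range) == 2L, radius_range[1] <= radius_range[2],
            texture_amplitude >= 0)
  if (2 * radius_range[2] + 2 > min(height, width)) {
    stop("canvas too small for radius_range")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_axons = as.integer(n_axons), radius_range = radius_range,
                 myelin_thickness_range = myelin_thickness_range,
                 texture_amplitude = texture_amplitude,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a clear EM-like phantom
#'
#' Dark myelin annuli (EM contrast convention: osmium-stained myelin on a
#' lighter background) with lighter axoplasmic lumina, over a smoothly
#' textured background.  Axons are placed without overlap by rejection
#' sampling.  Returns the image and an instance label mask (full axon discs
#' labelled 1..n, background 0) for segmentation experiments.
#'
#' @param spec a [phantom_spec()]
#' @return list with `image` (matrix in `[0, 1]`) and `labels` (integer
#'   matrix)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    img <- matrix(spec$background_level, H, W)
    if (spec$texture_amplitude > 0) {
      tex <- matrix(stats::rnorm(H * W), H, W)
      tex <- filter2_reflect(tex, gauss_kernel2(2, 2))
      tex <- tex / max(stats::sd(tex), 1e-9)
      img <- img + spec$texture_amplitude * tex
    }
    labels <- matrix(0L, H, W)
    if (spec$n_axons > 0L) {
      centers <- matrix(0, 0, 3)          # row, col, radius
      tries <- 0L
      while (nrow(centers) < spec$n_axons && tries < 20000L) {
        tries <- tries + 1L
        r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
        cy <- stats::runif(1, r + 1, H - r)
        cx <- stats::runif(1, r + 1, W - r)
        if (nrow(centers) > 0) {
          dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
          if (any(dd < centers[, 3] + r + 2)) next
        }
        centers <- rbind(centers, c(cy, cx, r))
      }
      if (nrow(centers) < spec$n_axons) {
        stop("could not place ", spec$n_axons, " axons on a ",
             H, "x", W, " canvas")
      }
      rows <- matrix(seq_len(H), H, W)
      cols <- matrix(seq_len(W), H, W, byrow = TRUE)
      for (a in seq_len(nrow(centers))) {
        cy <- centers[a, 1]; cx <- centers[a, 2]; r <- centers[a, 3]
        th <- stats::runif(1, spec$myelin_thickness_range[1],
                           spec$myelin_thickness_range[2])
        d <- sqrt((rows - cy)^2 + (cols - cx)^2)
        lum <- 0.78 + stats::runif(1, -0.05, 0.05)
        mye <- 0.12 + stats::runif(1, -0.04, 0.04)
        img[d <= r - th] <- lum
        img[d <= r & d > r - th] <- mye
        labels[d <= r] <- a
      }
    }
    list(image = matrix(pmin(pmax(img, 0), 1), H, W), labels = labels)
  })
}

#' Assemble a paired + unpaired synthetic dataset
#'
#' Supervised items are aligned (blurry, clear) pairs; unsupervised items
#' are blurry-only, optionally drawn from a different blur distribution to
#' emulate cross-sample domain shift.  Label masks are retained for
#' segmentation-agreement experiments.
#'
#' @param n_pairs number of supervised pairs (>= 0)
#' @param n_unsup number of unsupervised blurry images (>= 0)
#' @param phantom phantom specification template (its seed is re-derived per
#'   item)
#' @param blur_distribution nonempty list of [blur_spec()]s sampled
#'   uniformly for supervised items
#' @param unsup_blur_distribution blur distribution for the unsupervised
#'   bank (defaults to `blur_distribution`)
#' @param seed master seed; the full dataset is reproducible under
#'   (seed, specs)
#' @return a `sem_dataset` list with `pairs`, `unsup`, `seed`
#' @export
make_dataset <- function(n_pairs, n_unsup, phantom = phantom_spec(),
                         blur_distribution = default_blur_distribution(),
                         unsup_blur_distribution = blur_distribution,
                         seed = 1L) {
  stopifnot(n_pairs >= 0, n_unsup >= 0)
  if (length(blur_distribution) == 0L ||
      (n_unsup > 0L && length(unsup_blur_distribution) == 0L)) {
    stop("empty blur_distribution")
  }
  withr_seed(seed, {
    item_seeds <- sample.int(.Machine$integer.max - 1L, n_pairs + n_unsup)
    bidx <- if (n_pairs > 0)
      sample.int(length(blur_distribution), n_pairs, replace = TRUE)
    uidx <- if (n_unsup > 0)
      sample.int(length(unsup_blur_distribution), n_unsup, replace = TRUE)
    pairs <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      ps <- phantom; ps$seed <- item_seeds[i]
      ph <- generate_phantom(ps)
      bs <- blur_distribution[[bidx[i]]]
      bs$seed <- item_seeds[i] %% 1000003L + 7L
      pairs[[i]] <- list(x = ph$image, z = apply_blur(ph$image, bs),
                         labels = ph$labels, blur = bs)
    }
    unsup <- vector("list", n_unsup)
    for (i in seq_len(n_unsup)) {
      ps <- phantom; ps$seed <- item_seeds[n_pairs + i]
      ph <- generate_phantom(ps)
      bs <- unsup_blur_distribution[[uidx[i]]]
      bs$seed <- item_seeds[n_pairs + i] %% 1000003L + 13L
      unsup[[i]] <- list(z = apply_blur(ph$image, bs), blur = bs)
    }
    structure(list(pairs = pairs, unsup = unsup, phantom = phantom,
                   seed = as.integer(seed)),
              class = "sem_dataset")
  })
}

#' Default blur distribution: one spec per aberration mode
#'
#' @param noise_sigma additive noise level shared by all modes
#' @return list of [blur_spec()]s
#' @export
default_blur_distribution <- function(noise_sigma = 0.01) {
  list(
    blur_spec("underfocus", defocus_radius = 2, noise_sigma = noise_sigma),
    blur_spec("overfocus", defocus_radius = 2, noise_sigma = noise_sigma),
    blur_spec("astigmatism", sigma_major = 3, sigma_minor = 1,
              angle = pi / 4, noise_sigma = noise_sigma),
    blur_spec("combined", defocus_radius = 1.5, sigma_major = 2,
              sigma_minor = 0.8, angle = pi / 6, noise_sigma = noise_sigma)
  )
}

#' Write a dataset to disk as 16-bit TIFF images plus a JSON manifest
#'
#' @param ds a `sem_dataset`
#' @param dir output directory (created if needed)
#' @param bitdepth 8 or 16
#' @return the manifest path, invisibly
#' @export
write_dataset <- function(ds, dir, bitdepth = 16L) {
  stopifnot(inherits(ds, "sem_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(format = "semdeblur-dataset-1", seed = ds$seed,
              bitdepth = bitdepth, pairs = list(), unsup = list())
  for (i in seq_along(ds$pairs)) {
    p <- ds$pairs[[i]]
    fx <- sprintf("pair%03d_clear.tiff", i)
    fz <- sprintf("pair%03d_blurry.tiff", i)
    fl <- sprintf("pair%03d_labels.tiff", i)
    write_gray_image(p$x, file.path(dir, fx), bitdepth)
    write_gray_image(p$z, file.path(dir, fz), bitdepth)
    write_gray_image(p$labels / 65535, file.path(dir, fl), 16L)
    man$pairs[[i]] <- list(clear = fx, blurry = fz, labels = fl,
                           blur = unclass(p$blur))
  }
  for (i in seq_along(ds$unsup)) {
    fz <- sprintf("unsup%03d_blurry.tiff", i)
    write_gray_image(ds$unsup[[i]]$z, file.path(dir, fz), bitdepth)
    man$unsup[[i]] <- list(blurry = fz, blur = unclass(ds$unsup[[i]]$blur))
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`
#' @return a `sem_dataset` (blur specs restored; label masks as integers)
#' @export
read_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  restore_blur <- function(b) do.call(blur_spec, b)
  pairs <- lapply(man$pairs, function(p) {
    x <- read_gray_image(file.path(dir, p$clear))
    lab <- read_gray_image(file.path(dir, p$labels))
    list(x = x,
         z = read_gray_image(file.path(dir, p$blurry)),
         labels = matrix(as.integer(round(lab * 65535)), nrow = nrow(x)),
         blur = restore_blur(p$blur))
  })
  unsup <- lapply(man$unsup, function(u) {
    list(z = read_gray_image(file.path(dir, u$blurry)),
         blur = restore_blur(u$blur))
  })
  structure(list(pairs = pairs, unsup = unsup, seed = man$seed),
            class = "sem_dataset")
}
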