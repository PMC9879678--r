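# Blur kernel rendering, the z = k*x + eta formation model, and phantom /
# dataset generation.

test_that("rendered kernels are normalized and mode-appropriate", {
  for (spec in c(default_blur_distribution(),
                 list(blur_spec("identity"),
                      blur_spec("underfocus", defocus_radius = 3)))) {
    k <- render_kernel(spec)
    expect_true(all(k >= 0))
    expect_lt(abs(sum(k) - 1), 1e-6)
  }

  kd <- render_kernel(blur_spec("identity"))
  expect_identical(dim(kd), c(1L, 1L))
  expect_equal(kd[1, 1], 1)

  # astigmatism: second-moment ratio along the axes ~ (sigma ratio)^2
  ka <- render_kernel(blur_spec("astigmatism", sigma_major = 4,
                                sigma_minor = 1, angle = 0))
  n <- nrow(ka); c0 <- (n + 1) / 2
  rows <- matrix(seq_len(n) - c0, n, n)
  cols <- t(rows)
  m_major <- sum(ka * rows^2)   # angle 0: major axis along rows
  m_minor <- sum(ka * cols^2)
  expect_lt(abs(m_major / m_minor - 16), 1)

  # underfocus/overfocus are isotropic; overfocus is the wider tier
  ku <- render_kernel(blur_spec("underfocus", defocus_radius = 2))
  ko <- render_kernel(blur_spec("overfocus", defocus_radius = 2))
  iso <- function(k) {
    n <- nrow(k); c0 <- (n + 1) / 2
    r <- matrix(seq_len(n) - c0, n, n)
    abs(sum(k * r^2) - sum(k * t(r)^2))
  }
  expect_lt(iso(ku), 1e-9)
  expect_lt(iso(ko), 1e-9)
  expect_gt(nrow(ko), nrow(ku))

  expect_error(blur_spec("astigmatism", sigma_major = 2, sigma_minor = 2),
               "sigma_major")
})

test_that("apply_blur implements the formation model contracts", {
  set.seed(21)
  x <- generate_phantom(tiny_phantom())$image

  # identity kernel with zero noise is a fixed point
  id <- blur_spec("identity", noise_sigma = 0)
  expect_equal(apply_blur(x, id), x)

  # normalized kernel preserves the mean under reflective padding
  bs <- blur_spec("underfocus", defocus_radius = 2, noise_sigma = 0)
  z <- apply_blur(x, bs)
  expect_lt(abs(mean(z) - mean(x)), 1e-3)
  expect_identical(dim(z), dim(x))

  # fixed seed => bitwise-identical noise
  bn <- blur_spec("underfocus", defocus_radius = 2, noise_sigma = 0.05,
                  seed = 99L)
  expect_identical(apply_blur(x, bn), apply_blur(x, bn))

  # kernel larger than image is rejected
  tiny <- x[1:4, 1:4] / max(x)
  expect_error(apply_blur(tiny, blur_spec("underfocus", defocus_radius = 8)),
               "larger than image")
})

test_that("PSNR degrades monotonically with defocus radius", {
  x <- generate_phantom(tiny_phantom(seed = 8L))$image
  ps <- vapply(c(1, 2, 4, 8), function(r) {
    psnr(x, apply_blur(x, blur_spec("underfocus", defocus_radius = r,
                                    noise_sigma = 0)))
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("phantoms contain the requested axon structures", {
  spec <- phantom_spec(height = 96L, width = 96L, n_axons = 5L,
                       radius_range = c(6, 10), seed = 31L)
  ph <- generate_phantom(spec)
  expect_true(all(is.finite(ph$image)))
  expect_true(min(ph$image) >= 0 && max(ph$image) <= 1)

  # deterministic under the seed
  expect_identical(generate_phantom(spec)$image, ph$image)

  # exactly 5 labelled components, and the annuli are dark on the light
  # background (myelin contrast convention)
  expect_identical(sort(unique(as.vector(ph$labels))), 0:5)
  for (a in 1:5) {
    inside <- ph$image[ph$labels == a]
    outside_mean <- mean(ph$image[ph$labels == 0])
    expect_lt(min(inside), 0.3)          # dark myelin ring present
    expect_gt(outside_mean, 0.4)         # lighter background
  }

  # n_axons = 0 gives pure textured background
  ph0 <- generate_phantom(phantom_spec(height = 64L, width = 64L,
                                       n_axons = 0L, seed = 2L))
  expect_true(all(ph0$labels == 0L))

  # canvas too small for the radius range is rejected
  expect_error(phantom_spec(height = 16L, width = 16L,
                            radius_range = c(8, 16)), "too small")
})

test_that("make_dataset assembles aligned pairs and honours the seed", {
  ds <- make_dataset(4, 0, tiny_phantom(), seed = 77L)
  expect_length(ds$pairs, 4L)
  expect_length(ds$unsup, 0L)
  for (p in ds$pairs) expect_identical(dim(p$x), dim(p$z))

  ds2 <- make_dataset(4, 0, tiny_phantom(), seed = 77L)
  expect_identical(ds, ds2)

  expect_error(make_dataset(2, 0, tiny_phantom(),
                            blur_distribution = list()), "empty")

  # a combined-only distribution yields anisotropic, defocused kernels
  comb <- list(blur_spec("combined", defocus_radius = 2, sigma_major = 3,
                         sigma_minor = 1))
  ds3 <- make_dataset(3, 0, tiny_phantom(), blur_distribution = comb,
                      seed = 5L)
  for (p in ds3$pairs) {
    k <- render_kernel(p$blur)
    n <- nrow(k); c0 <- (n + 1) / 2
    r <- matrix(seq_len(n) - c0, n, n)
    # second moments reflect both the disc and the anisotropic part
    expect_gt(sum(k * r^2), sum(k * t(r)^2))
    expect_gt(sum(k * t(r)^2), 0.3)
  }
})

test_that("datasets round-trip through the PNG + JSON manifest format", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(2, 2, tiny_phantom(), seed = 13L)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dataset(dir)
  expect_length(back$pairs, 2L)
  expect_length(back$unsup, 2L)
  # 16-bit quantization: within half a gray level
  expect_lt(max(abs(back$pairs[[1]]$x - ds$pairs[[1]]$x)), 1 / 65535)
  expect_identical(back$pairs[[1]]$labels, ds$pairs[[1]]$labels)
  expect_identical(back$pairs[[2]]$blur$mode, ds$pairs[[2]]$blur$mode)
})
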