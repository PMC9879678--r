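# Loss arithmetic: every term evaluates to its closed-form value, is zero
# at its analytic optimum, and respects the least-squares coding.

const_node <- function(tape, v, dims = c(2, 2, 1, 1)) {
  sd_ns$op_input(tape, array(v, dim = dims))
}

test_that("content loss is the mean absolute difference", {
  ns <- sd_ns
  tape <- ns$ad_tape()
  a <- const_node(tape, 0.2)
  b <- const_node(tape, 0.5)
  expect_equal(content_loss(tape, a, b)$value, 0.3)
  expect_equal(content_loss(tape, b, a)$value, 0.3)   # symmetry
  expect_equal(content_loss(tape, a, a)$value, 0)
  expect_error(content_loss(tape, a, const_node(tape, 1, c(4, 4, 1, 1))),
               "shape mismatch")
})

test_that("perceptual loss is the CHW-normalized squared feature distance", {
  ns <- sd_ns
  bb <- identity_backbone()
  tape <- ns$ad_tape()
  a <- const_node(tape, 0)          # 1x2x2 feature block per sample
  b <- const_node(tape, 1)
  expect_equal(perceptual_loss(tape, a, b, bb)$value, 1)
  expect_equal(perceptual_loss(tape, a, a, bb)$value, 0)

  # nonnegative under the frozen conv backbone, zero on identical inputs
  set.seed(1)
  fb <- tiny_backbone()
  t2 <- ns$ad_tape()
  x <- ns$op_input(t2, rand_img4(32, 32))
  y <- ns$op_input(t2, rand_img4(32, 32))
  expect_gte(perceptual_loss(t2, x, y, fb)$value, 0)
  expect_equal(perceptual_loss(t2, x, x, fb)$value, 0)

  # the backbone is deterministic: same seed, same features
  fb2 <- tiny_backbone()
  t3 <- ns$ad_tape()
  x3 <- ns$op_input(t3, x$value)
  expect_identical(fb$fwd(t3, x3)$value, fb2$fwd(t3, x3)$value)
})

test_that("generator adversarial loss matches the least-squares target", {
  ns <- sd_ns
  tape <- ns$ad_tape()
  expect_equal(adversarial_loss_G(tape, const_node(tape, 1))$value, 0)
  expect_equal(adversarial_loss_G(tape, const_node(tape, 0.5))$value, 0.25)
  expect_equal(adversarial_loss_G(tape, const_node(tape, 0))$value, 1)
})

test_that("unsupervised loss compares supervised and unsupervised scores", {
  ns <- sd_ns
  tape <- ns$ad_tape()
  s1 <- const_node(tape, 0.9, c(2, 2, 1, 2))
  s2 <- const_node(tape, 0.4, c(2, 2, 1, 2))
  expect_equal(unsupervised_loss(tape, s1, s2)$value, 0.25)
  expect_equal(unsupervised_loss(tape, s1, s1)$value, 0)
  # batch-size mismatch falls back to comparing batch means
  s3 <- const_node(tape, 0.4, c(2, 2, 1, 3))
  expect_equal(unsupervised_loss(tape, s1, s3)$value, 0.25)
  # empty unsupervised bank is defined as zero
  expect_equal(unsupervised_loss(tape, s1, NULL)$value, 0)
})

test_that("the weighted total follows the published lambda values", {
  ns <- sd_ns
  w <- loss_weights()
  expect_equal(w$lambda_adv, 0.1)
  expect_equal(w$lambda_us, 0.01)
  expect_equal(w$lambda_p, 0.02)
  tape <- ns$ad_tape()
  one <- ns$op_const(tape, 1)
  expect_equal(total_G_loss(tape, one, one, one, one, w)$value, 1.13)
  zero <- ns$op_const(tape, 0)
  expect_equal(total_G_loss(tape, zero, zero, zero, zero, w)$value, 0)
  w0 <- loss_weights(0, 0, 0)
  lc <- ns$op_const(tape, 0.7)
  expect_equal(total_G_loss(tape, lc, one, one, one, w0)$value, 0.7)
  # non-finite components abort with the offending term named
  bad <- ns$op_const(tape, NaN)
  expect_error(total_G_loss(tape, lc, bad, one, one, w), "adversarial")
})

test_that("discriminator loss is the printed two-term LS objective", {
  ns <- sd_ns
  tape <- ns$ad_tape()
  expect_equal(d_loss(tape, const_node(tape, 1), const_node(tape, 0))$value,
               0)
  expect_equal(d_loss(tape, const_node(tape, 0.7),
                      const_node(tape, 0.2))$value, 0.065)
  expect_equal(d_loss(tape, const_node(tape, 0.5),
                      const_node(tape, 0.5))$value, 0.25)
})

test_that("LS coding constants reproduce the generic a/b/c objectives", {
  # with a = 0, b = c = 1: L_D = 1/2 (D(x) - b)^2 + 1/2 (D(G(z)) - a)^2 and
  # L_G = (D(G(z)) - c)^2, evaluated at scalar scores
  ns <- sd_ns
  cd <- lsgan_coding()
  expect_equal(cd$a, 0)
  expect_equal(cd$b, 1)
  expect_equal(cd$c, 1)
  for (dx in c(0, 0.3, 1)) {
    for (dg in c(0, 0.6, 1)) {
      tape <- ns$ad_tape()
      got <- d_loss(tape, const_node(tape, dx), const_node(tape, dg))$value
      expect_equal(got, 0.5 * (dx - cd$b)^2 + 0.5 * (dg - cd$a)^2)
      gotg <- adversarial_loss_G(tape, const_node(tape, dg))$value
      expect_equal(gotg, (dg - cd$c)^2)
    }
  }
})

test_that("every loss is nonnegative and zero only at its optimum", {
  ns <- sd_ns
  set.seed(5)
  for (rep in 1:5) {
    tape <- ns$ad_tape()
    v <- array(runif(4, -1, 1), c(2, 2, 1, 1))
    sc <- ns$op_input(tape, v)
    expect_gte(adversarial_loss_G(tape, sc)$value, 0)
    expect_gte(d_loss(tape, sc, sc)$value, 0)
    a <- ns$op_input(tape, array(runif(16), c(4, 4, 1, 1)))
    b <- ns$op_input(tape, array(runif(16), c(4, 4, 1, 1)))
    expect_gte(content_loss(tape, a, b)$value, 0)
    expect_gte(unsupervised_loss(tape, sc, ns$op_scale(tape, sc, 0.5))$value,
               0)
  }
})
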