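# Generator architecture contracts: pyramid shapes, the triangular decoding
# grid, residual identities, and gradient flow.

test_that("encoder produces the five-scale pyramid with halving sizes", {
  set.seed(1)
  gen <- build_generator(tiny_gen_cfg())
  ns <- sd_ns
  tape <- ns$ad_tape()
  z <- ns$op_input(tape, rand_img4(64, 64))
  blocks <- gen_encode(gen, tape, z)
  expect_length(blocks, 5L)
  sizes <- vapply(blocks, function(b) dim(b$value)[1], numeric(1))
  expect_equal(sizes, c(64, 32, 16, 8, 4))
  ch <- sd_ns$gen_channels(gen$cfg)
  expect_equal(vapply(blocks, function(b) dim(b$value)[3], numeric(1)),
               as.numeric(ch))

  # non-divisible input is rejected, caller must pad
  tape2 <- ns$ad_tape()
  expect_error(gen_encode(gen, tape2, ns$op_input(tape2, rand_img4(40, 56))),
               "pad required")
})

test_that("coarse decoding fills column 1 top-down and is linear at zero", {
  set.seed(2)
  gen <- build_generator(tiny_gen_cfg())
  ns <- sd_ns
  tape <- ns$ad_tape()
  ch <- ns$gen_channels(gen$cfg)
  zero_blocks <- lapply(1:5, function(i) {
    ns$op_input(tape, array(0, dim = c(64 / 2^(i - 1), 64 / 2^(i - 1),
                                       ch[i], 1)))
  })
  col1 <- gen_coarse_decode(gen, tape, zero_blocks)
  expect_length(col1, 5L)
  for (nodev in col1) expect_true(all(nodev$value == 0))

  # real input: 5 nodes with the right channels and sizes, deterministic
  zin <- rand_img4(64, 64)
  t2 <- ns$ad_tape()
  b2 <- gen_encode(gen, t2, ns$op_input(t2, zin))
  c2 <- gen_coarse_decode(gen, t2, b2)
  for (i in 1:5) {
    expect_equal(dim(c2[[i]]$value)[1], 64 / 2^(i - 1))
    expect_equal(dim(c2[[i]]$value)[3], ch[i])
  }
  t3 <- ns$ad_tape()
  b3 <- gen_encode(gen, t3, ns$op_input(t3, zin))
  c3 <- gen_coarse_decode(gen, t3, b3)
  expect_identical(c2[[1]]$value, c3[[1]]$value)
})

test_that("the decoding grid enumerates 15 nodes, 5..1 per scale", {
  nodes <- sd_ns$grid_nodes()
  expect_length(nodes, 15L)
  per_scale <- table(vapply(nodes, `[`, numeric(1), "i"))
  expect_equal(as.numeric(per_scale), c(5, 4, 3, 2, 1))
  # every node respects j <= 5 - i
  for (nd in nodes) expect_lte(nd[["j"]], 5 - nd[["i"]])
})

test_that("hfe steps wire coarser inputs only where the grid provides them", {
  ins30 <- sd_ns$hfe_inputs(3L, 2L)
  expect_named(ins30, "c1")            # i = 3: only one coarser scale
  ins02 <- sd_ns$hfe_inputs(0L, 2L)
  expect_named(ins02, c("c1", "c2"))
  ins04 <- sd_ns$hfe_inputs(0L, 5L)
  expect_named(ins04, "c1")            # X[2, 4] does not exist
})

test_that("an hfe block with zero weights is the identity on its skip", {
  set.seed(3)
  ns <- sd_ns
  hfe <- ns$nn_hfe("t", 4L, 4L, 8L)
  for (p in ns$collect_params(hfe)) p$value[] <- 0
  tape <- ns$ad_tape()
  skip <- ns$op_input(tape, array(rnorm(16 * 16 * 4), c(16, 16, 4, 1)))
  c1 <- ns$op_input(tape, array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  c2 <- ns$op_input(tape, array(rnorm(4 * 4 * 8), c(4, 4, 8, 1)))
  out <- hfe$fwd(tape, skip, c1, c2)
  expect_identical(out$value, skip$value)

  # with random weights the output preserves the skip's spatial size
  hfe2 <- ns$nn_hfe("t2", 4L, 4L, 8L)
  t2 <- ns$ad_tape()
  skip2 <- ns$op_input(t2, array(rnorm(16 * 16 * 4), c(16, 16, 4, 1)))
  out2 <- hfe2$fwd(t2, skip2,
                   ns$op_input(t2, array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))),
                   ns$op_input(t2, array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))))
  expect_identical(dim(out2$value), dim(skip2$value))
})

test_that("progressive decoding fills the triangle and is zero at zero", {
  set.seed(4)
  gen <- build_generator(tiny_gen_cfg())
  ns <- sd_ns
  tape <- ns$ad_tape()
  b <- gen_encode(gen, tape, ns$op_input(tape, rand_img4(64, 64)))
  grid <- gen_progressive_decode(gen, tape, gen_coarse_decode(gen, tape, b))
  filled <- sum(vapply(grid, function(col) {
    sum(!vapply(col, is.null, TRUE))
  }, numeric(1)))
  expect_equal(filled, 15)
  expect_equal(lengths(grid), c(5L, 4L, 3L, 2L, 1L))

  # zero column-1 plus zero grid weights gives a zero terminal node
  gen0 <- build_generator(tiny_gen_cfg())
  for (p in gen0$params) p$value[] <- 0
  t0 <- ns$ad_tape()
  ch <- ns$gen_channels(gen0$cfg)
  col0 <- lapply(1:5, function(i) {
    ns$op_input(t0, array(0, dim = c(64 / 2^(i - 1), 64 / 2^(i - 1),
                                     ch[i], 1)))
  })
  g0 <- gen_progressive_decode(gen0, t0, col0)
  expect_true(all(g0[[1]][[5]]$value == 0))
})

test_that("a zero-weight head makes the generator the exact identity", {
  set.seed(5)
  gen <- build_generator(tiny_gen_cfg())
  gen$params[["head.w"]]$value[] <- 0
  gen$params[["head.b"]]$value[] <- 0
  z <- rand_img4(48, 48, 2)
  expect_identical(sd_ns$gen_apply(gen, z), z)
})

test_that("the Tanh residual bounds per-pixel change by 1", {
  set.seed(6)
  gen <- build_generator(tiny_gen_cfg())
  # inflate the head so the tanh saturates somewhere
  gen$params[["head.w"]]$value <- gen$params[["head.w"]]$value * 1e4
  z <- rand_img4(32, 32)
  out <- sd_ns$gen_apply(gen, z)
  expect_lte(max(abs(out - z)), 1 + 1e-12)
  expect_identical(dim(out), dim(z))
})

test_that("every generator parameter receives gradient from an L1 loss", {
  set.seed(7)
  ns <- sd_ns
  gen <- build_generator(tiny_gen_cfg())
  tape <- ns$ad_tape()
  z <- ns$op_input(tape, rand_img4(32, 32, 2))
  out <- gen_forward(gen, tape, z)
  tgt <- ns$op_const(tape, rand_img4(32, 32, 2))
  loss <- ns$op_mean(tape, ns$op_abs(tape, ns$op_sub(tape, out, tgt)))
  ns$ad_backward(tape, loss)
  got <- vapply(gen$params, function(p) {
    !is.null(p$grad) && any(p$grad != 0)
  }, TRUE)
  expect_true(all(got))
})

test_that("upsample modes are interchangeable in the architecture", {
  set.seed(8)
  for (mode in c("nearest", "transposed")) {
    cfg <- generator_config(base_channels = 4L,
                            channel_multipliers = c(1L, 1L, 2L, 2L, 2L),
                            residual_blocks_per_scale = 1L,
                            upsample_mode = mode)
    gen <- build_generator(cfg)
    z <- rand_img4(32, 32)
    out <- sd_ns$gen_apply(gen, z)
    expect_identical(dim(out), dim(z))
    expect_true(all(is.finite(out)))
  }
})
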