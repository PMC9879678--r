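# Trainer: warm-up schedule, alternating-step hygiene, determinism, and
# resumable checkpoints.

test_that("warm-up schedule ramps linearly and then holds the peak", {
  cfg <- train_config(warmup_steps = 1000L, peak_lr = 1e-4)
  expect_equal(warmup_lr(1000, cfg), 1e-4)
  expect_equal(warmup_lr(5000, cfg), 1e-4)
  expect_equal(warmup_lr(500, cfg), 5e-5)    # half-way up the ramp
  lrs <- vapply(0:1500, warmup_lr, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) >= 0))
})

make_step_fixture <- function(seed = 5L) {
  set.seed(seed)
  gen <- build_generator(tiny_gen_cfg())
  disc <- build_discriminator(tiny_disc_cfg())
  ns <- sd_ns
  list(gen = gen, disc = disc,
       opt_g = ns$sgd_new(gen$params), opt_d = ns$sgd_new(disc$params),
       batches = tiny_batches(), bb = tiny_backbone(),
       cfg = train_config(batch_size = 2L, crop_size = 32L, peak_lr = 1e-3,
                          warmup_steps = 10L, total_steps = 3L, seed = seed))
}

test_that("train_step is deterministic under a fixed seed", {
  f1 <- make_step_fixture()
  set.seed(99)
  r1 <- train_step(f1$gen, f1$disc, f1$opt_g, f1$opt_d, f1$batches$sup,
                   f1$batches$unsup, 1L, f1$cfg, f1$bb)
  f2 <- make_step_fixture()
  set.seed(99)
  r2 <- train_step(f2$gen, f2$disc, f2$opt_g, f2$opt_d, f2$batches$sup,
                   f2$batches$unsup, 1L, f2$cfg, f2$bb)
  expect_identical(r1, r2)
  expect_true(all(is.finite(unlist(r1))))
})

test_that("gradient hygiene: each update leaves the other network intact", {
  ns <- sd_ns
  f <- make_step_fixture()
  g_before <- ns$param_values(f$gen$params)
  d_before <- ns$param_values(f$disc$params)
  set.seed(42)
  train_step(f$gen, f$disc, f$opt_g, f$opt_d, f$batches$sup,
             f$batches$unsup, 1L, f$cfg, f$bb)
  # both nets updated by their own optimizers only: run a step with zeroed
  # learning rate for G to isolate the D update
  f2 <- make_step_fixture()
  cfg0 <- f2$cfg
  cfg0$peak_lr <- 1e-3
  # manual D-only update: d_loss backward must not touch generator params
  tape <- ns$ad_tape()
  real <- ns$op_input(tape, f2$batches$sup$x)
  zs <- ns$op_input(tape, f2$batches$sup$z)
  zhat <- gen_forward(f2$gen, tape, zs)
  t_d <- ns$ad_tape()
  ld <- d_loss(t_d, d_score(f2$disc, t_d, ns$op_input(t_d, real$value)),
               d_score(f2$disc, t_d, ns$op_const(t_d, zhat$value)))
  ns$zero_grads(f2$gen$params)
  ns$zero_grads(f2$disc$params)
  ns$ad_backward(t_d, ld)
  g_grads <- vapply(f2$gen$params, function(p) is.null(p$grad) ||
                      all(p$grad == 0), TRUE)
  expect_true(all(g_grads))
  d_grads <- vapply(f2$disc$params, function(p) !is.null(p$grad) &&
                      any(p$grad != 0), TRUE)
  expect_true(all(d_grads))

  # and the frozen backbone never accumulates applied updates: values are
  # bitwise stable across training steps
  fb_before <- ns$param_values(f$bb$params)
  set.seed(43)
  train_step(f$gen, f$disc, f$opt_g, f$opt_d, f$batches$sup,
             f$batches$unsup, 2L, f$cfg, f$bb)
  expect_identical(ns$param_values(f$bb$params), fb_before)
})

test_that("a D update on a fixed batch does not increase its d_loss", {
  ns <- sd_ns
  f <- make_step_fixture(seed = 9L)
  eval_d <- function() {
    tape <- ns$ad_tape()
    set.seed(1234)      # same augmentation draws for a paired comparison
    real <- aug_T(tape, ns$op_input(tape, f$batches$sup$x), f$cfg$augment)
    set.seed(5678)
    fake <- aug_T(tape, ns$op_input(tape, f$batches$sup$z), f$cfg$augment)
    list(tape = tape,
         loss = d_loss(tape, d_score(f$disc, tape, real),
                       d_score(f$disc, tape, fake)))
  }
  before <- eval_d()
  ns$zero_grads(f$disc$params)
  ns$ad_backward(before$tape, before$loss)
  ns$sgd_step(f$opt_d, 1e-4)
  after <- eval_d()
  expect_lte(after$loss$value, before$loss$value)
})

test_that("NaN losses abort the step with the offending term named", {
  f <- make_step_fixture()
  f$gen$params[["head.w"]]$value[1] <- NaN
  set.seed(3)
  expect_error(train_step(f$gen, f$disc, f$opt_g, f$opt_d, f$batches$sup,
                          f$batches$unsup, 1L, f$cfg, f$bb),
               "non-finite loss component")
})

test_that("fit with zero steps writes only the initialization checkpoint", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(2, 0, tiny_phantom(), seed = 3L)
  cfg <- train_config(batch_size = 1L, crop_size = 32L, total_steps = 0L,
                      seed = 1L, unsup_batch_size = 0L)
  fit <- fit_deblur(ds, cfg, tiny_gen_cfg(), tiny_disc_cfg(),
                    out_dir = dir, backbone = tiny_backbone())
  expect_true(file.exists(file.path(dir, "checkpoint_init.rds")))
  expect_null(fit$log)
  expect_error(
    fit_deblur(list(pairs = list(), unsup = list()), cfg, tiny_gen_cfg(),
               tiny_disc_cfg()),
    "empty supervised manifest")
})

test_that("resuming from a checkpoint reproduces the straight run bitwise", {
  ns <- sd_ns
  dir <- withr::local_tempdir()
  ds <- make_dataset(3, 2, tiny_phantom(), seed = 21L)
  base_cfg <- function(steps) {
    train_config(batch_size = 2L, crop_size = 32L, peak_lr = 1e-3,
                 warmup_steps = 10L, total_steps = steps, seed = 77L,
                 unsup_batch_size = 2L)
  }
  straight <- fit_deblur(ds, base_cfg(5L), tiny_gen_cfg(), tiny_disc_cfg(),
                         backbone = tiny_backbone())
  partial <- fit_deblur(ds, base_cfg(3L), tiny_gen_cfg(), tiny_disc_cfg(),
                        out_dir = dir, backbone = tiny_backbone())
  resumed <- fit_deblur(ds, base_cfg(5L), tiny_gen_cfg(), tiny_disc_cfg(),
                        backbone = tiny_backbone(),
                        resume_from = file.path(dir, "checkpoint_final.rds"))
  expect_equal(resumed$log$total_G,
               straight$log$total_G[4:5])
  expect_identical(ns$param_values(resumed$generator$params),
                   ns$param_values(straight$generator$params))
})
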