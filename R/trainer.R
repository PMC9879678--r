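# ---------------------------------------------------------------------------
# Alternating generator/discriminator optimization with supervised pairs
# and an unsupervised blurry bank.  Each step: (1) forward both blurry
# batches through the generator; (2) discriminator update on augmented real
# and detached augmented fake supervised outputs; (3) generator update with
# the weighted content + perceptual + adversarial + unsupervised objective.
# SGD with momentum and a linear warm-up to the peak learning rate.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published recipe (SGD, warm-up to 1e-4, batch 2,
#' 256x256 crops); all sizes are configurable down for CPU-scale runs.
#'
#' @param batch_size supervised images per step
#' @param crop_size training crop side, divisible by 16
#' @param peak_lr learning rate after warm-up
#' @param warmup_steps linear warm-up length in steps
#' @param total_steps total optimization steps
#' @param momentum SGD momentum
#' @param d_steps_per_g_step discriminator updates per generator update
#' @param unsup_batch_size unsupervised images per step (0 disables the
#'   semisupervised term)
#' @param seed RNG seed controlling every stochastic choice of the run
#' @param eval_every evaluate held-out PSNR/SSIM every this many steps
#'   (0 = only at the end)
#' @param weights a [loss_weights()]
#' @param augment an [aug_policy()] for discriminator inputs
#' @return a `train_config` list
#' @export
train_config <- function(batch_size = 2L, crop_size = 256L, peak_lr = 1e-4,
                         warmup_steps = 1000L, total_steps = 10000L,
                         momentum = 0.9, d_steps_per_g_step = 1L,
                         unsup_batch_size = batch_size, seed = 1L,
                         eval_every = 0L, weights = loss_weights(),
                         augment = aug_policy()) {
  stopifnot(peak_lr > 0, crop_size %% 16L == 0L, batch_size >= 1L,
            warmup_steps >= 1L, total_steps >= 0L, d_steps_per_g_step >= 1L,
            unsup_batch_size >= 0L)
  structure(list(batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size), peak_lr = peak_lr,
                 warmup_steps = as.integer(warmup_steps),
                 total_steps = as.integer(total_steps), momentum = momentum,
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 unsup_batch_size = as.integer(unsup_batch_size),
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 weights = weights, augment = augment),
            class = "train_config")
}

#' Warm-up learning-rate schedule
#'
#' Linear ramp `peak_lr * step / warmup_steps` for `step < warmup_steps`,
#' constant `peak_lr` afterwards.
#'
#' @param step optimization step (>= 0)
#' @param cfg a [train_config()]
#' @return learning rate
#' @export
warmup_lr <- function(step, cfg) {
  stopifnot(step >= 0)
  cfg$peak_lr * min(1, step / cfg$warmup_steps)
}

# Stack a list of matrices into an (H, W, 1, N) array in [-1, 1].
stack_batch <- function(mats) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE) * 2 - 1,
        dim = c(H, W, 1L, length(mats)))
}

# Random crop + random flips of paired (z, x) matrices.
sample_crop <- function(z, x, crop) {
  H <- nrow(z); W <- ncol(z)
  r0 <- if (H > crop) sample.int(H - crop + 1L, 1L) else 1L
  c0 <- if (W > crop) sample.int(W - crop + 1L, 1L) else 1L
  rr <- r0:(r0 + min(crop, H) - 1L)
  cc <- c0:(c0 + min(crop, W) - 1L)
  z <- z[rr, cc]; x <- if (!is.null(x)) x[rr, cc]
  if (stats::runif(1) < 0.5) {
    z <- z[rev(seq_len(nrow(z))), ]
    if (!is.null(x)) x <- x[rev(seq_len(nrow(x))), ]
  }
  if (stats::runif(1) < 0.5) {
    z <- z[, rev(seq_len(ncol(z)))]
    if (!is.null(x)) x <- x[, rev(seq_len(ncol(x)))]
  }
  list(z = z, x = x)
}

#' One alternating training step
#'
#' @param gen,disc built networks
#' @param opt_g,opt_d optimizer states from [sgd_new()]
#' @param sup_batch list with `z`, `x`: (H, W, 1, N) arrays in `[-1, 1]`
#' @param unsup_batch (H, W, 1, M) array in `[-1, 1]`, or `NULL`
#' @param step global step number (drives the learning-rate schedule)
#' @param cfg a [train_config()]
#' @param backbone frozen feature backbone for the perceptual term
#' @return named list of the six scalar losses plus the learning rate
#' @export
train_step <- function(gen, disc, opt_g, opt_d, sup_batch,
                       unsup_batch = NULL, step = 1L, cfg = train_config(),
                       backbone = feature_backbone()) {
  lr <- warmup_lr(step, cfg)

  # (1) generator forward on both blurry batches (graph kept for the G
  # step); the supervised and unsupervised batches share one batched pass
  tape_g <- ad_tape()
  x <- op_const(tape_g, sup_batch$x)
  ns <- dim(sup_batch$z)[4]
  use_unsup <- !is.null(unsup_batch) && cfg$weights$lambda_us > 0
  if (use_unsup) {
    d <- dim(sup_batch$z)
    nu <- dim(unsup_batch)[4]
    z_all <- op_const(tape_g, array(c(sup_batch$z, unsup_batch),
                                    dim = c(d[1], d[2], 1L, ns + nu)))
    zhat_all <- gen_forward(gen, tape_g, z_all)
    zhat_s <- op_slice_n(tape_g, zhat_all, 1L, ns)
    zhat_u <- op_slice_n(tape_g, zhat_all, ns + 1L, nu)
  } else {
    zhat_s <- gen_forward(gen, tape_g, op_const(tape_g, sup_batch$z))
    zhat_u <- NULL
  }

  # (2) discriminator update(s) on detached fakes; real and fake receive
  # independent augmentation draws but share one batched scoring pass
  dl_val <- NA_real_
  for (k in seq_len(cfg$d_steps_per_g_step)) {
    tape_d <- ad_tape()
    real <- aug_T(tape_d, op_const(tape_d, sup_batch$x), cfg$augment)
    fake <- aug_T(tape_d, op_const(tape_d, zhat_s$value), cfg$augment)
    both <- op_concat_n(tape_d, real, fake)
    sc <- d_score(disc, tape_d, both)
    ld <- d_loss(tape_d, op_slice_n(tape_d, sc, 1L, ns),
                 op_slice_n(tape_d, sc, ns + 1L, ns))
    if (!is.finite(ld$value)) stop("non-finite loss component: d_loss")
    zero_grads(disc$params)
    ad_backward(tape_d, ld)
    sgd_step(opt_d, lr)
    dl_val <- ld$value
  }

  # (3) generator update against the refreshed discriminator
  lc <- content_loss(tape_g, x, zhat_s)
  lp <- perceptual_loss(tape_g, x, zhat_s, backbone)
  if (use_unsup) {
    sc_all <- d_score(disc, tape_g, aug_T(tape_g, zhat_all, cfg$augment))
    sc_s <- op_slice_n(tape_g, sc_all, 1L, ns)
    sc_u <- op_slice_n(tape_g, sc_all, ns + 1L, dim(unsup_batch)[4])
    ladv <- adversarial_loss_G(tape_g, sc_s)
    lus <- unsupervised_loss(tape_g, sc_s, sc_u)
  } else {
    sc_s <- d_score(disc, tape_g, aug_T(tape_g, zhat_s, cfg$augment))
    ladv <- adversarial_loss_G(tape_g, sc_s)
    lus <- op_const(tape_g, 0)
  }
  lg <- total_G_loss(tape_g, lc, ladv, lus, lp, cfg$weights)
  zero_grads(gen$params)
  zero_grads(disc$params)   # G backprop reaches D params; discard those grads
  ad_backward(tape_g, lg)
  sgd_step(opt_g, lr)

  list(step = step, lr = lr, content = lc$value, perceptual = lp$value,
       adversarial = ladv$value, unsupervised = lus$value,
       total_G = lg$value, d_loss = dl_val)
}

#' Train a deblurring model on a synthetic or loaded dataset
#'
#' Runs `cfg$total_steps` alternating steps, sampling supervised pairs and
#' unsupervised images independently with replacement, with random crops and
#' flips as supervised training augmentation (distinct from the
#' differentiable augmentation applied to discriminator inputs).  Optionally
#' evaluates held-out PSNR/SSIM periodically and writes checkpoints and a
#' JSONL loss log.
#'
#' @param dataset a `sem_dataset` (from [make_dataset()] or [read_dataset()])
#' @param cfg a [train_config()]
#' @param gen_cfg a [generator_config()]
#' @param disc_cfg a [discriminator_config()]
#' @param holdout optional list of (z, x) pairs for periodic evaluation
#' @param out_dir checkpoint/log directory, or `NULL` to keep everything in
#'   memory
#' @param backbone frozen feature backbone
#' @param resume_from optional checkpoint path to resume from
#' @return list with the trained `generator`, `discriminator`, `log`
#'   (data.frame of per-step losses), and `eval` (held-out metrics)
#' @export
fit_deblur <- function(dataset, cfg = train_config(),
                       gen_cfg = generator_config(),
                       disc_cfg = discriminator_config(),
                       holdout = NULL, out_dir = NULL,
                       backbone = feature_backbone(),
                       resume_from = NULL) {
  if (length(dataset$pairs) == 0L) stop("empty supervised manifest")
  has_unsup <- length(dataset$unsup) > 0L && cfg$unsup_batch_size > 0L

  start_step <- 0L
  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from)
    gen <- ck$generator
    disc <- ck$discriminator
    opt_g <- sgd_new(gen$params, cfg$momentum)
    opt_d <- sgd_new(disc$params, cfg$momentum)
    if (!is.null(ck$opt_g)) opt_g$velocity <- ck$opt_g$velocity
    if (!is.null(ck$opt_d)) opt_d$velocity <- ck$opt_d$velocity
    start_step <- ck$step
    if (!is.null(ck$rng_state)) assign(".Random.seed", ck$rng_state,
                                       .GlobalEnv)
  } else {
    set.seed(cfg$seed)
    gen <- build_generator(gen_cfg)
    disc <- build_discriminator(disc_cfg)
    opt_g <- sgd_new(gen$params, cfg$momentum)
    opt_d <- sgd_new(disc$params, cfg$momentum)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (start_step == 0L) {
      save_checkpoint(file.path(out_dir, "checkpoint_init.rds"), gen, disc,
                      opt_g, opt_d, step = 0L, config = cfg,
                      rng_state = get(".Random.seed", .GlobalEnv))
    }
  }
  log_path <- if (!is.null(out_dir)) file.path(out_dir, "losses.jsonl")

  logs <- vector("list", max(cfg$total_steps - start_step, 0L))
  evals <- list()
  li <- 0L
  if (cfg$total_steps > start_step) {
    for (step in seq(start_step + 1L, cfg$total_steps)) {
      si <- sample.int(length(dataset$pairs), cfg$batch_size, replace = TRUE)
      zs <- vector("list", cfg$batch_size)
      xs <- vector("list", cfg$batch_size)
      for (b in seq_along(si)) {
        pr <- dataset$pairs[[si[b]]]
        cr <- sample_crop(pr$z, pr$x, cfg$crop_size)
        zs[[b]] <- cr$z; xs[[b]] <- cr$x
      }
      sup <- list(z = stack_batch(zs), x = stack_batch(xs))
      unsup <- NULL
      if (has_unsup) {
        ui <- sample.int(length(dataset$unsup), cfg$unsup_batch_size,
                         replace = TRUE)
        us <- lapply(ui, function(i) {
          sample_crop(dataset$unsup[[i]]$z, NULL, cfg$crop_size)$z
        })
        unsup <- stack_batch(us)
      }
      rep_ <- train_step(gen, disc, opt_g, opt_d, sup, unsup, step, cfg,
                         backbone)
      li <- li + 1L
      logs[[li]] <- rep_
      if (!is.null(log_path)) {
        cat(jsonlite::toJSON(rep_, auto_unbox = TRUE, digits = NA), "\n",
            file = log_path, append = TRUE)
      }
      if (!is.null(holdout) && cfg$eval_every > 0L &&
          step %% cfg$eval_every == 0L) {
        evals[[length(evals) + 1L]] <-
          c(step = step, eval_holdout(gen, holdout))
      }
    }
  }

  if (!is.null(holdout)) {
    evals[[length(evals) + 1L]] <-
      c(step = cfg$total_steps, eval_holdout(gen, holdout))
  }
  if (!is.null(out_dir)) {
    save_checkpoint(file.path(out_dir, "checkpoint_final.rds"), gen, disc,
                    opt_g, opt_d, step = cfg$total_steps, config = cfg,
                    rng_state = get(".Random.seed", .GlobalEnv))
  }
  list(generator = gen, discriminator = disc,
       log = do.call(rbind, lapply(logs[seq_len(li)], as.data.frame)),
       eval = if (length(evals)) as.data.frame(do.call(rbind, evals)))
}

#' Mean held-out PSNR/SSIM of deblurred outputs
#'
#' @param gen a built generator
#' @param holdout list of pairs with `z`, `x` matrices in `[0, 1]`
#' @return named vector: psnr/ssim of the deblurred outputs and of the raw
#'   blurry inputs
#' @export
eval_holdout <- function(gen, holdout) {
  ps <- pb <- ss <- sb <- numeric(length(holdout))
  for (i in seq_along(holdout)) {
    h <- holdout[[i]]
    out <- deblur_array(gen, h$z, tiling_plan(tile = 256L, overlap = 16L))
    ps[i] <- psnr(h$x, out); pb[i] <- psnr(h$x, h$z)
    ss[i] <- ssim(h$x, out); sb[i] <- ssim(h$x, h$z)
  }
  c(psnr_deblurred = mean(ps), psnr_blurry = mean(pb),
    ssim_deblurred = mean(ss), ssim_blurry = mean(sb))
}
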