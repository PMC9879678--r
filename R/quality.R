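# ---------------------------------------------------------------------------
# Full-reference image quality (PSNR, SSIM) and segmentation agreement
# (adapted Rand error) used for evaluation.
# ---------------------------------------------------------------------------

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`; identical images give `Inf`.
#'
#' @param ref,test numeric matrices/arrays of equal shape
#' @param data_range dynamic range of the data (1 for `[0, 1]` images)
#' @return PSNR in dB
#' @export
psnr <- function(ref, test, data_range = 1) {
  if (!identical(dim(ref), dim(test))) stop("psnr: shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# Gaussian window with the truncation convention of the reference SSIM
# implementation: radius = round(truncate * sigma).
ssim_window <- function(sigma = 1.5, truncate = 3.5) {
  r <- as.integer(round(truncate * sigma))
  u <- (-r):r
  g <- exp(-0.5 * (u / sigma)^2)
  k <- outer(g, g)
  k / sum(k)
}

# Filter with replicate ("nearest") boundary handling.
filter2_replicate <- function(img, k) {
  ph <- nrow(k) %/% 2L; pw <- ncol(k) %/% 2L
  H <- nrow(img); W <- ncol(img)
  ri <- c(rep(1L, ph), seq_len(H), rep(H, ph))
  ci <- c(rep(1L, pw), seq_len(W), rep(W, pw))
  xp <- img[ri, ci, drop = FALSE]
  x4 <- array(xp, dim = c(nrow(xp), ncol(xp), 1L, 1L))
  w4 <- array(k, dim = c(nrow(k), ncol(k), 1L, 1L))
  y <- cpp_conv2d_fw(x4, dim(x4), w4, dim(w4), 0, 1L, 0L)
  matrix(y, nrow = H)
}

#' Structural similarity index (mean SSIM)
#'
#' Standard formulation with an 11x11 Gaussian window (sigma 1.5),
#' stabilization constants K1 = 0.01, K2 = 0.03, sample-covariance
#' normalization, replicate boundary filtering, and a half-window border
#' crop before averaging — matching the common reference implementation.
#'
#' @param ref,test numeric matrices of equal shape
#' @param data_range dynamic range (1 for `[0, 1]` images)
#' @param sigma Gaussian window sigma
#' @return mean SSIM in `[-1, 1]`
#' @export
ssim <- function(ref, test, data_range = 1, sigma = 1.5) {
  if (!identical(dim(ref), dim(test))) stop("ssim: shape mismatch")
  k <- ssim_window(sigma)
  win <- nrow(k)
  if (nrow(ref) < win || ncol(ref) < win) {
    stop("image smaller than the ", win, "x", win, " SSIM window")
  }
  np <- win^2
  cov_norm <- np / (np - 1)
  ux <- filter2_replicate(ref, k)
  uy <- filter2_replicate(test, k)
  uxx <- filter2_replicate(ref * ref, k)
  uyy <- filter2_replicate(test * test, k)
  uxy <- filter2_replicate(ref * test, k)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  pad <- (win - 1L) %/% 2L
  mean(s[(pad + 1L):(nrow(s) - pad), (pad + 1L):(ncol(s) - pad)])
}

#' Adapted Rand error between two instance segmentations
#'
#' `1 - F` where `F` is the F-score of Rand precision and recall over all
#' unordered pairs of distinct foreground pixels: precision is the fraction
#' of pairs joined by the prediction that are also joined by the ground
#' truth, recall the converse.  Following the segmentation-challenge
#' convention, ground-truth background (label 0) is excluded; predicted
#' label 0 inside the foreground is treated as a regular segment.  Lower is
#' better; 0 means the partitions agree up to a label permutation.
#'
#' @param pred,gt integer label matrices of equal shape; 0 = background
#' @return adapted Rand error in `[0, 1]`
#' @export
adapted_rand_error <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("adapted_rand_error: shape mismatch")
  }
  fg <- gt > 0L
  if (!any(fg)) stop("all-background ground truth")
  p <- as.integer(factor(pred[fg]))
  g <- as.integer(factor(gt[fg]))
  np <- max(p); ng <- max(g)
  cont <- tabulate((g - 1L) * np + p, nbins = np * ng)
  n <- sum(cont)
  joined_both <- sum(cont^2) - n            # 2 * co-joined distinct pairs
  joined_pred <- sum(tabulate(p, nbins = np)^2) - n
  joined_gt <- sum(tabulate(g, nbins = ng)^2) - n
  if (joined_pred == 0 || joined_gt == 0) {
    # a partition into singletons joins no pairs; agreement is defined by
    # whether the other partition joins any
    return(if (joined_pred == joined_gt) 0 else 1)
  }
  precision <- joined_both / joined_pred
  recall <- joined_both / joined_gt
  if (precision + recall == 0) return(1)
  1 - 2 * precision * recall / (precision + recall)
}

#' Quality report over image pairs
#'
#' @param refs,tests lists of matrices (or a single pair of matrices)
#' @param data_range dynamic range
#' @param names optional row names
#' @return a `data.frame` with per-image `psnr`/`ssim` rows
#' @export
quality_report <- function(refs, tests, data_range = 1, names = NULL) {
  if (is.matrix(refs)) refs <- list(refs)
  if (is.matrix(tests)) tests <- list(tests)
  stopifnot(length(refs) == length(tests))
  data.frame(
    image = names %||% sprintf("img%03d", seq_along(refs)),
    psnr = mapply(psnr, refs, tests, MoreArgs = list(data_range = data_range)),
    ssim = mapply(ssim, refs, tests, MoreArgs = list(data_range = data_range))
  )
}

#' Write a quality report as CSV with an aggregate footer row
#'
#' The footer averages finite PSNR values (infinite rows are reported as
#' `Inf` but excluded from the mean).
#'
#' @param report data frame from [quality_report()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_quality_report <- function(report, path) {
  agg <- data.frame(image = "mean",
                    psnr = mean(report$psnr[is.finite(report$psnr)]),
                    ssim = mean(report$ssim))
  utils::write.csv(rbind(report, agg), path, row.names = FALSE)
  invisible(path)
}
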