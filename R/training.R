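#' @title Paired-data construction and edge-weighted L1 training
#'
#' @description k-space truncation removes the periphery of the spectrum, so
#' edges and fine structure are what a super-resolution network must
#' recover. Training therefore minimises an L1 reconstruction term plus an
#' L1 penalty on the difference of Sobel gradient-magnitude maps, and the
#' checkpoint kept is the one minimising the *validation* edge-L1 (not the
#' final epoch).
#' @name training
NULL

# symmetric (width-1) padding maps for the fixed 3x3 Sobel stencils
sobel_maps <- function(H, W) {
  key <- sprintf("sob_%d_%d", H, W)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + 2L
  Wp <- W + 2L
  rp <- pmin(pmax(rep(seq_len(Hp), times = Wp) - 1L, 1L), H)
  cp <- pmin(pmax(rep(seq_len(Wp), each = Hp) - 1L, 1L), W)
  rmap <- (cp - 1L) * H + rp      # padded cell -> source cell
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  q <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    q <- q + 1L
    idx[, q] <- (cc + dc) * Hp + (r + dr + 1L)
  }
  out <- list(rmap = rmap, idx = idx)
  .nn_cache[[key]] <- out
  out
}

# tap order must match sobel_maps (dr fastest, then dc)
.sobel_kx <- c(-1, -2, -1, 0, 0, 0, 1, 2, 1)   # d/dcol
.sobel_ky <- c(-1, 0, 1, -2, 0, 2, -1, 0, 1)   # d/drow

sobel_gradients <- function(x, H, W) {
  mp <- sobel_maps(H, W)
  xp <- as.vector(x)[mp$rmap]
  cols <- matrix(xp[mp$idx], H * W, 9L)
  list(gx = cols %*% .sobel_kx, gy = cols %*% .sobel_ky)
}

# adjoint of the Sobel pair under symmetric padding
sobel_adjoint <- function(dgx, dgy, H, W) {
  mp <- sobel_maps(H, W)
  dcols <- tcrossprod(dgx, .sobel_kx) + tcrossprod(dgy, .sobel_ky)
  dxp <- numeric((H + 2L) * (W + 2L))
  for (q in 1:9) {
    iq <- mp$idx[, q]
    dxp[iq] <- dxp[iq] + dcols[, q]
  }
  as.vector(rowsum(dxp, mp$rmap))
}

#' Sobel gradient-magnitude edge map
#'
#' 3x3 Sobel pair with symmetric (reflect) padding; the map is nonnegative,
#' zero on constant images, and positively homogeneous
#' (`edge_map(a * x) = a * edge_map(x)` for `a > 0`).
#'
#' @param img a `gray_image` (or matrix).
#' @return A `gray_image` of gradient magnitudes with the same spacing.
#' @export
edge_map <- function(img) {
  img <- as_gray_image(img)
  d <- dim(img$pixels)
  g <- sobel_gradients(img$pixels, d[1], d[2])
  gray_image(matrix(sqrt(g$gx^2 + g$gy^2), d[1], d[2]), spacing = img$spacing)
}

#' Edge-weighted L1 loss
#'
#' `mean(|pred - label|) + lambda * mean(|edge_map(pred) - edge_map(label)|)`.
#' Zero iff the images are identical (for any `lambda >= 0`), and symmetric
#' in its two arguments.
#'
#' @param pred,label `gray_image`s or matrices of matching shape.
#' @param lambda nonnegative edge-term weight (default 1).
#' @return A single nonnegative number.
#' @export
edge_l1_loss <- function(pred, label, lambda = 1) {
  p <- as.matrix(as_gray_image(pred))
  y <- as.matrix(as_gray_image(label))
  if (!identical(dim(p), dim(y))) stop("shape mismatch", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  d <- dim(p)
  out <- mean(abs(p - y))
  if (lambda > 0) {
    gp <- sobel_gradients(p, d[1], d[2])
    gy <- sobel_gradients(y, d[1], d[2])
    sp <- sqrt(gp$gx^2 + gp$gy^2)
    sy <- sqrt(gy$gx^2 + gy$gy^2)
    out <- out + lambda * mean(abs(sp - sy))
  }
  out
}

# loss value and dL/dpred as a vector, for training
edge_l1_grad <- function(p, y, H, W, lambda) {
  n <- H * W
  diff <- p - y
  loss <- mean(abs(diff))
  grad <- sign(diff) / n
  if (lambda > 0) {
    gp <- sobel_gradients(p, H, W)
    gyy <- sobel_gradients(y, H, W)
    sp <- sqrt(gp$gx^2 + gp$gy^2)
    sy <- sqrt(gyy$gx^2 + gyy$gy^2)
    loss <- loss + lambda * mean(abs(sp - sy))
    dS <- sign(sp - sy) * (lambda / n)
    denom <- ifelse(sp > 0, sp, 1)
    dgx <- dS * gp$gx / denom
    dgy <- dS * gp$gy / denom
    grad <- grad + sobel_adjoint(dgx, dgy, H, W)
  }
  list(loss = loss, grad = grad)
}

#' One-cycle learning-rate schedule
#'
#' Cosine warm-up from `max_lr / div` to exactly `max_lr` over the first
#' `pct_start` fraction of steps, then cosine annealing down to
#' `max_lr / final_div`. The sequence is unimodal.
#'
#' @param step 0-based step index, `0 <= step < total_steps`.
#' @param total_steps total optimisation steps in the cycle.
#' @param max_lr peak learning rate.
#' @param pct_start warm-up fraction (default 0.3).
#' @param div initial divisor (default 25).
#' @param final_div final divisor (default 1e4).
#' @return The learning rate at `step`.
#' @export
one_cycle_lr <- function(step, total_steps, max_lr,
                         pct_start = 0.3, div = 25, final_div = 1e4) {
  if (any(step < 0) || any(step >= total_steps))
    stop("`step` must satisfy 0 <= step < total_steps", call. = FALSE)
  warm <- floor(pct_start * (total_steps - 1))
  lo <- max_lr / div
  fin <- max_lr / final_div
  ifelse(step <= warm,
         if (warm > 0) lo + (max_lr - lo) * 0.5 * (1 - cos(pi * step / warm)) else max_lr,
         fin + (max_lr - fin) * 0.5 *
           (1 + cos(pi * (step - warm) / (total_steps - 1 - warm))))
}

#' Draw one training pair from a high-resolution label
#'
#' A uniformly random `crop` x `crop` patch of the label is the target; the
#' input is that patch degraded by k-space truncation, generated inline as
#' in batch training. Uses the current RNG state (seed the session for
#' reproducibility).
#'
#' @param label a `gray_image` at least `crop` in both dimensions.
#' @param crop HR patch size, divisible by `factor`.
#' @param factor down-sampling factor.
#' @return list with elements `input` (`crop/factor` square) and `label`
#'   (`crop` square).
#' @export
make_pair <- function(label, crop, factor = 4) {
  label <- as_gray_image(label)
  d <- dim(label$pixels)
  if (crop %% factor != 0) stop("`crop` must be divisible by `factor`", call. = FALSE)
  if (any(d < crop)) stop("label smaller than requested crop", call. = FALSE)
  r0 <- sample.int(d[1] - crop + 1L, 1L)
  c0 <- sample.int(d[2] - crop + 1L, 1L)
  patch <- gray_image(label$pixels[r0 + seq_len(crop) - 1L, c0 + seq_len(crop) - 1L],
                      spacing = label$spacing)
  list(input = kspace_downsample(patch, factor), label = patch)
}

# deterministic centre crop, for fixed validation pairs
centre_pair <- function(label, crop, factor) {
  d <- dim(label$pixels)
  r0 <- floor((d[1] - crop) / 2) + 1L
  c0 <- floor((d[2] - crop) / 2) + 1L
  patch <- gray_image(label$pixels[r0 + seq_len(crop) - 1L, c0 + seq_len(crop) - 1L],
                      spacing = label$spacing)
  list(input = kspace_downsample(patch, factor), label = patch)
}

#' Training configuration for one stage
#'
#' Three stages mirror the staged curriculum (2x base model, parameter
#' transfer to 4x, fine-tune on the target anatomy); each carries the peak
#' one-cycle learning rate used for that stage (1e-5, 5e-5, 1e-6). All
#' values can be overridden, which small desk-scale runs on synthetic
#' phantoms need (a small freshly initialised model warrants a far larger
#' peak rate than a 43M-parameter fine-tune).
#'
#' @param stage one of `"scale2_base"`, `"scale4_transfer"`, `"finetune"`.
#' @param max_lr peak learning rate; default chosen by stage.
#' @param label_crop HR crop size (divisible by the scale; default 192).
#' @param batch batch size (default 16).
#' @param epochs training epochs.
#' @param seed RNG seed controlling split, crops and shuffling.
#' @param lambda_edge edge-term weight of the loss (default 1).
#' @param val_frac validation fraction of the image-level split (default 0.1).
#' @return An object of class `train_config`.
#' @export
train_config <- function(stage = c("scale2_base", "scale4_transfer", "finetune"),
                         max_lr = NULL, label_crop = 192, batch = 16,
                         epochs = 30, seed = 1L, lambda_edge = 1,
                         val_frac = 0.1) {
  stage <- match.arg(stage)
  if (is.null(max_lr))
    max_lr <- switch(stage, scale2_base = 1e-5, scale4_transfer = 5e-5,
                     finetune = 1e-6)
  stopifnot(max_lr > 0, label_crop >= 4, batch >= 1, epochs >= 1,
            lambda_edge >= 0, val_frac > 0, val_frac < 1)
  structure(list(stage = stage, max_lr = max_lr, label_crop = as.integer(label_crop),
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 seed = as.integer(seed), lambda_edge = lambda_edge,
                 val_frac = val_frac),
            class = "train_config")
}

#' Train one stage of the super-resolution network
#'
#' Adam with a one-cycle learning-rate schedule on the edge-weighted L1
#' loss. Inputs are generated inline per batch by random crop + k-space
#' truncation. Per-epoch training loss and validation edge-L1 / NRMSE /
#' SSIM / PSNR are logged, and the returned model is the checkpoint at the
#' epoch of minimum validation edge-L1. Fully reproducible under a fixed
#' `cfg$seed`.
#'
#' @param model an `edsr` model (its scale sets the down-sampling factor).
#' @param labels nonempty list of `gray_image` high-resolution labels.
#' @param cfg a [train_config()].
#' @return An object of class `edsr_fit`: list with `model` (best
#'   checkpoint), `final_model`, `log` (one row per epoch), `best_epoch`
#'   and `config`.
#' @export
train_edsr <- function(model, labels, cfg) {
  stopifnot(inherits(model, "edsr"), inherits(cfg, "train_config"))
  if (length(labels) == 0L) stop("empty dataset", call. = FALSE)
  labels <- lapply(labels, as_gray_image)
  scale <- model$config$scale
  crop <- cfg$label_crop
  if (crop %% scale != 0) stop("label_crop must be divisible by the scale", call. = FALSE)
  mind <- min(vapply(labels, function(l) min(dim(l$pixels)), 0))
  if (mind < crop)
    stop(sprintf("labels (min dim %d) smaller than label_crop %d", mind, crop),
         call. = FALSE)

  set.seed(cfg$seed)
  n <- length(labels)
  n_val <- max(1L, round(cfg$val_frac * n))
  if (n_val >= n) stop("dataset too small for a train/validation split", call. = FALSE)
  val_idx <- sort(sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  val_pairs <- lapply(labels[val_idx], centre_pair, crop = crop, factor = scale)

  steps_per_epoch <- ceiling(length(train_idx) / cfg$batch)
  total_steps <- cfg$epochs * steps_per_epoch
  layers <- model$layers
  opt <- adam_init(layers)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_edge_l1 = numeric(), val_nrmse = numeric(),
                    val_ssim = numeric(), val_psnr = numeric())
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  gstep <- 0L
  lrC <- crop %/% scale

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0
    ep_n <- 0L
    for (b0 in seq(1L, length(ord), by = cfg$batch)) {
      bidx <- ord[b0:min(b0 + cfg$batch - 1L, length(ord))]
      acc <- NULL
      bloss <- 0
      for (ii in bidx) {
        pr <- make_pair(labels[[ii]], crop, scale)
        m <- mean(pr$input$pixels)
        z <- matrix(as.vector(pr$input$pixels) - m, ncol = 1)
        fw <- edsr_forward_raw(list(config = model$config, layers = layers),
                               z, lrC, lrC, keep = TRUE)
        pred <- fw$out + m
        lg <- edge_l1_grad(pred, as.vector(pr$label$pixels), crop, crop,
                           cfg$lambda_edge)
        if (!is.finite(lg$loss))
          stop("training diverged: non-finite loss at epoch ", ep, call. = FALSE)
        bloss <- bloss + lg$loss
        g <- edsr_backward_raw(list(config = model$config, layers = layers),
                               matrix(lg$grad, ncol = 1), fw$cache)
        if (is.null(acc)) acc <- g
        else for (nm in names(acc)) {
          acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
          acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
        }
      }
      nb <- length(bidx)
      for (nm in names(acc)) {
        acc[[nm]]$dW <- acc[[nm]]$dW / nb
        acc[[nm]]$db <- acc[[nm]]$db / nb
      }
      lr <- one_cycle_lr(gstep, total_steps, cfg$max_lr)
      gstep <- gstep + 1L
      upd <- adam_step(layers, acc, opt, lr, gstep)
      layers <- upd$layers
      opt <- upd$state
      ep_loss <- ep_loss + bloss
      ep_n <- ep_n + nb
    }

    cur <- list(config = model$config, layers = layers,
                metadata = model$metadata)
    class(cur) <- "edsr"
    vm <- vapply(val_pairs, function(pr) {
      out <- forward_sr(cur, pr$input)
      c(edge_l1_loss(out, pr$label, cfg$lambda_edge),
        nrmse(out, pr$label),
        if (crop >= 11) ssim(out, pr$label) else NA_real_,
        psnr(out, pr$label))
    }, numeric(4))
    vmean <- rowMeans(vm)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                 val_edge_l1 = vmean[1], val_nrmse = vmean[2],
                                 val_ssim = vmean[3], val_psnr = vmean[4]))
    if (vmean[1] < best$loss)
      best <- list(loss = vmean[1], layers = layers, epoch = ep)
  }

  meta <- c(model$metadata,
            list(stage = cfg$stage, seed = cfg$seed,
                 loss_at_save = best$loss, best_epoch = best$epoch))
  best_model <- structure(list(config = model$config, layers = best$layers,
                               metadata = meta), class = "edsr")
  final_model <- structure(list(config = model$config, layers = layers,
                                metadata = model$metadata), class = "edsr")
  structure(list(model = best_model, final_model = final_model, log = log,
                 best_epoch = best$epoch, config = cfg,
                 val_idx = val_idx),
            class = "edsr_fit")
}

#' @export
print.edsr_fit <- function(x, ...) {
  cat(sprintf("<edsr_fit> stage %s: %d epochs, best epoch %d (val edge-L1 %.6g)\n",
              x$config$stage, nrow(x$log), x$best_epoch,
              x$log$val_edge_l1[x$best_epoch]))
  cat(sprintf("  train loss %.6g -> %.6g, final val NRMSE %.4g, SSIM %.4g\n",
              x$log$train_loss[1], x$log$train_loss[nrow(x$log)],
              x$log$val_nrmse[nrow(x$log)], x$log$val_ssim[nrow(x$log)]))
  invisible(x)
}

#' @export
plot.edsr_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$log$epoch, x$log$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "edge-weighted L1")
  graphics::lines(x$log$epoch, x$log$val_edge_l1, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey")
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  graphics::plot(x$log$epoch, x$log$val_nrmse, type = "l", xlab = "epoch",
                 ylab = "validation NRMSE", main = "validation NRMSE")
  invisible(x)
}

#' Write a per-epoch metric log to CSV
#'
#' @param fit an `edsr_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_log <- function(fit, path) {
  stopifnot(inherits(fit, "edsr_fit"))
  utils::write.csv(fit$log, path, row.names = FALSE)
  invisible(path)
}
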