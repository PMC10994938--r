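#' @title Full-reference evaluation of up-sampling methods
#'
#' @description Reconstructions are compared to the high-resolution
#' reference with range-normalised RMSE, SSIM and PSNR after an optional
#' rigid registration of each reconstruction to the reference and a joint
#' reference-derived brain mask (thresholding plus morphology), mirroring
#' how measured low/high-resolution image pairs must be evaluated when
#' subject motion separates the acquisitions.
#' @name quality
NULL

#' Range-normalised root mean-square error
#'
#' `RMSE(test, ref) / (max(ref) - min(ref))`; zero iff identical.
#'
#' @param test,ref `gray_image`s or matrices of matching shape; `ref` must
#'   not be constant.
#' @return A nonnegative number.
#' @export
nrmse <- function(test, ref) {
  x <- as.matrix(as_gray_image(test))
  y <- as.matrix(as_gray_image(ref))
  if (!identical(dim(x), dim(y))) stop("shape mismatch", call. = FALSE)
  rng <- diff(range(y))
  if (rng == 0) stop("constant reference: degenerate intensity range", call. = FALSE)
  sqrt(mean((x - y)^2)) / rng
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(range(ref)^2 / MSE)`, capped at 100 dB for identical images
#' so logs stay finite.
#'
#' @inheritParams nrmse
#' @return PSNR in dB.
#' @export
psnr <- function(test, ref) {
  x <- as.matrix(as_gray_image(test))
  y <- as.matrix(as_gray_image(ref))
  if (!identical(dim(x), dim(y))) stop("shape mismatch", call. = FALSE)
  rng <- diff(range(y))
  if (rng == 0) stop("constant reference: degenerate intensity range", call. = FALSE)
  mse <- mean((x - y)^2)
  min(100, 10 * log10(rng^2 / mse))
}

# separable valid-mode filtering with a 1D kernel along both axes
filter2_valid <- function(x, g) {
  k <- length(g)
  H <- nrow(x)
  W <- ncol(x)
  out1 <- matrix(0, H - k + 1L, W)
  for (i in seq_len(k)) out1 <- out1 + g[i] * x[i:(H - k + i), , drop = FALSE]
  out <- matrix(0, H - k + 1L, W - k + 1L)
  for (i in seq_len(k)) out <- out + g[i] * out1[, i:(W - k + i), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' Mean local SSIM over an 11 x 11 Gaussian window (sigma 1.5), constants
#' K1 = 0.01, K2 = 0.03, with the data range taken from the reference
#' (`max(ref) - min(ref)`). Windows are valid-mode (no padding). Identical
#' images score exactly 1.
#'
#' @inheritParams nrmse
#' @param win window width (odd, default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @param K1,K2 stabilisation constants.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(test, ref, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  x <- as.matrix(as_gray_image(test))
  y <- as.matrix(as_gray_image(ref))
  if (!identical(dim(x), dim(y))) stop("shape mismatch", call. = FALSE)
  if (any(dim(x) < win)) stop("image smaller than the SSIM window", call. = FALSE)
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  R <- diff(range(y))
  C1 <- (K1 * R)^2
  C2 <- (K2 * R)^2
  mu1 <- filter2_valid(x, g)
  mu2 <- filter2_valid(y, g)
  s11 <- filter2_valid(x * x, g) - mu1^2
  s22 <- filter2_valid(y * y, g) - mu2^2
  s12 <- filter2_valid(x * y, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Reference-derived brain mask
#'
#' Otsu threshold, binary closing (disc radius 2), hole filling, then the
#' largest connected component. The mask is computed once on the reference
#' and applied jointly to every method's reconstruction.
#'
#' @param ref a nonnegative `gray_image`.
#' @return A logical matrix of the reference's shape (all `FALSE` for an
#'   all-zero image).
#' @export
brain_mask <- function(ref) {
  y <- as.matrix(as_gray_image(ref))
  mx <- max(y)
  if (mx <= 0) return(matrix(FALSE, nrow(y), ncol(y)))
  z <- y / mx
  th <- EBImage::otsu(EBImage::Image(z))
  bin <- EBImage::Image(z > th)
  bin <- EBImage::closing(bin, EBImage::makeBrush(5, "disc"))
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  labm <- as.matrix(EBImage::imageData(lab))
  if (max(labm) < 1) return(matrix(FALSE, nrow(y), ncol(y)))
  counts <- tabulate(labm[labm > 0])
  labm == which.max(counts)
}

#' Rigid 2D transform
#'
#' Rotation about the image centre followed by a translation, in pixel
#' units; the angle is wrapped to (-180, 180].
#'
#' @param theta rotation in degrees.
#' @param dx,dy translation in pixels along rows and columns.
#' @param converged `FALSE` flags a registration that failed to improve on
#'   the identity.
#' @return An object of class `rigid_transform_2d`.
#' @export
rigid_transform_2d <- function(theta = 0, dx = 0, dy = 0, converged = TRUE) {
  stopifnot(is.finite(theta), is.finite(dx), is.finite(dy))
  theta <- ((theta + 180) %% 360) - 180
  if (theta == -180) theta <- 180
  structure(list(theta = theta, dx = dx, dy = dy, converged = converged),
            class = "rigid_transform_2d")
}

#' @export
print.rigid_transform_2d <- function(x, ...) {
  cat(sprintf("<rigid_transform_2d> theta %.3f deg, t (%.3f, %.3f) px%s\n",
              x$theta, x$dx, x$dy,
              if (x$converged) "" else " [did not improve on identity]"))
  invisible(x)
}

# vectorised bilinear sampling; coordinates in pixel units (1-based)
bilinear_sample <- function(m, r, cc) {
  H <- nrow(m)
  W <- ncol(m)
  valid <- r >= 1 & r <= H & cc >= 1 & cc <= W
  r0 <- pmin(pmax(floor(r), 1), H - 1)
  c0 <- pmin(pmax(floor(cc), 1), W - 1)
  fr <- pmin(pmax(r - r0, 0), 1)
  fc <- pmin(pmax(cc - c0, 0), 1)
  v00 <- m[cbind(r0, c0)]
  v10 <- m[cbind(r0 + 1, c0)]
  v01 <- m[cbind(r0, c0 + 1)]
  v11 <- m[cbind(r0 + 1, c0 + 1)]
  val <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  list(values = val, valid = valid)
}

#' Resample an image under a rigid transform
#'
#' Applies the transform to `moving` (bilinear interpolation, out-of-bounds
#' filled with 0) so that `apply_rigid(moving, rigid_register_2d(moving,
#' fixed))` is aligned with `fixed`.
#'
#' @param moving a `gray_image`.
#' @param tf a `rigid_transform_2d`.
#' @return A `gray_image` of the same shape.
#' @export
apply_rigid <- function(moving, tf) {
  moving <- as_gray_image(moving)
  m <- moving$pixels
  H <- nrow(m)
  W <- ncol(m)
  cr <- (H + 1) / 2
  ccn <- (W + 1) / 2
  th <- tf$theta * pi / 180
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  # inverse map: subtract translation, rotate back about centre
  ra <- r - tf$dx - cr
  ca <- cc - tf$dy - ccn
  rs <- cos(th) * ra + sin(th) * ca + cr
  cs <- -sin(th) * ra + cos(th) * ca + ccn
  sm <- bilinear_sample(m, rs, cs)
  out <- ifelse(sm$valid, sm$values, 0)
  gray_image(matrix(out, H, W), spacing = moving$spacing)
}

# NCC between fixed and rigidly resampled moving, over in-bounds pixels
ncc_rigid <- function(par, moving, fixed) {
  tf <- list(theta = par[1], dx = par[2], dy = par[3])
  m <- moving
  H <- nrow(m)
  W <- ncol(m)
  cr <- (H + 1) / 2
  ccn <- (W + 1) / 2
  th <- tf$theta * pi / 180
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  ra <- r - tf$dx - cr
  ca <- cc - tf$dy - ccn
  rs <- cos(th) * ra + sin(th) * ca + cr
  cs <- -sin(th) * ra + cos(th) * ca + ccn
  sm <- bilinear_sample(m, rs, cs)
  ok <- sm$valid
  if (sum(ok) < 16) return(-1)
  a <- sm$values[ok]
  b <- as.vector(fixed)[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-1)
  stats::cor(a, b)
}

#' Rigid registration of one image to another
#'
#' Maximises normalised cross-correlation: a coarse stage scans candidate
#' rotations and finds the best integer translation for each by FFT
#' cross-correlation, then a Nelder-Mead refinement polishes (theta, dx,
#' dy) on the bilinear-resampled overlap. If the optimum does not improve
#' on the identity the identity is returned with `converged = FALSE`.
#'
#' @param moving,fixed `gray_image`s of the same shape with overlapping
#'   content.
#' @param rotations candidate rotations (degrees) for the coarse stage.
#' @return A `rigid_transform_2d` mapping `moving` onto `fixed`.
#' @export
rigid_register_2d <- function(moving, fixed, rotations = seq(-6, 6, by = 1.5)) {
  moving <- as_gray_image(moving)
  fixed <- as_gray_image(fixed)
  if (!identical(dim(moving$pixels), dim(fixed$pixels)))
    stop("images must share a shape", call. = FALSE)
  mv <- moving$pixels
  fx <- fixed$pixels
  H <- nrow(mv)
  W <- ncol(mv)
  f0 <- fx - mean(fx)
  Ff <- stats::fft(f0)
  best <- list(score = -Inf, par = c(0, 0, 0))
  for (th in unique(c(0, rotations))) {
    rot <- if (th == 0) mv else apply_rigid(moving, rigid_transform_2d(th))$pixels
    r0 <- rot - mean(rot)
    xc <- Re(stats::fft(Ff * Conj(stats::fft(r0)), inverse = TRUE))
    pk <- arrayInd(which.max(xc), dim(xc))
    sh <- pk - 1L
    sh[1] <- if (sh[1] > H / 2) sh[1] - H else sh[1]
    sh[2] <- if (sh[2] > W / 2) sh[2] - W else sh[2]
    par <- c(th, sh[1], sh[2])
    sc <- ncc_rigid(par, mv, fx)
    if (sc > best$score) best <- list(score = sc, par = par)
  }
  opt <- stats::optim(best$par, function(p) -ncc_rigid(p, mv, fx),
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
  id_score <- ncc_rigid(c(0, 0, 0), mv, fx)
  if (-opt$value <= id_score + 1e-12 &&
      sum(abs(opt$par - c(0, 0, 0))) > 1e-6) {
    warning("registration did not improve on the identity", call. = FALSE)
    return(rigid_transform_2d(0, 0, 0, converged = FALSE))
  }
  rigid_transform_2d(opt$par[1], opt$par[2], opt$par[3])
}

#' Paired two-sided t test on matched metric lists
#'
#' Classical paired t on the differences with `n - 1` degrees of freedom.
#' Zero-variance differences are handled explicitly: all-zero differences
#' give `t = 0, p = 1`; constant nonzero differences are flagged degenerate.
#'
#' @param a,b equal-length numeric vectors paired by subject (`n >= 2`).
#' @return list with `t`, `p`, `df`, `mean_diff` and `degenerate`.
#' @export
paired_comparison <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Evaluate up-sampling methods against high-resolution labels
#'
#' Reproduces the retrospective evaluation pipeline per label: clip at the
#' 99.9th percentile, min-max scale to 0-4096, degrade by k-space
#' truncation, reconstruct with nearest neighbour, bicubic and the network,
#' optionally rigidly register each reconstruction to the label, mask with
#' the reference-derived brain mask, and record NRMSE / SSIM / PSNR.
#'
#' @param labels list of `gray_image` labels at the target matrix size.
#' @param model an `edsr` model (or a function `gray_image -> gray_image`
#'   for plumbing checks).
#' @param factor down/up-sampling factor (default 4).
#' @param register rigidly register reconstructions to the label
#'   (default `FALSE`; the synthetic pipeline is already aligned).
#' @param mask apply the reference brain mask (default `TRUE`).
#' @return A long-format data.frame: `subject`, `method`
#'   (`nearest` / `bicubic` / `edsr`), `nrmse`, `ssim`, `psnr`.
#' @export
evaluate_methods <- function(labels, model, factor = 4, register = FALSE,
                             mask = TRUE) {
  stopifnot(length(labels) >= 1)
  run_model <- if (inherits(model, "edsr")) {
    function(img) forward_sr(model, img)
  } else if (is.function(model)) model
  else stop("`model` must be an `edsr` or a function", call. = FALSE)
  rows <- list()
  for (s in seq_along(labels)) {
    lab <- minmax_scale(clip_to_percentile(as_gray_image(labels[[s]]), 99.9),
                        0, 4096)
    lr <- kspace_downsample(lab, factor)
    recon <- list(nearest = upsample_nearest(lr, factor),
                  bicubic = upsample_bicubic(lr, factor),
                  edsr = run_model(lr))
    msk <- if (mask) brain_mask(lab) else NULL
    for (meth in names(recon)) {
      rc <- recon[[meth]]
      if (!identical(dim(rc$pixels), dim(lab$pixels)))
        stop("reconstruction shape mismatch for method ", meth, call. = FALSE)
      if (register) rc <- apply_rigid(rc, rigid_register_2d(rc, lab))
      tp <- rc$pixels
      rp <- lab$pixels
      if (mask) {
        tp <- tp * msk
        rp <- rp * msk
      }
      rows[[length(rows) + 1L]] <-
        data.frame(subject = s, method = meth,
                   nrmse = nrmse(tp, rp), ssim = ssim(tp, rp),
                   psnr = psnr(tp, rp))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise an evaluation table with paired tests
#'
#' Per-method metric means plus paired two-sided t tests of the network
#' against each baseline, reported per comparison without family-wise
#' correction.
#'
#' @param tab a data.frame from [evaluate_methods()].
#' @return list with `means` (per-method data.frame) and `tests`
#'   (data.frame of paired comparisons on NRMSE and SSIM).
#' @export
summarise_evaluation <- function(tab) {
  means <- do.call(rbind, lapply(split(tab, tab$method), function(d)
    data.frame(method = d$method[1], nrmse = mean(d$nrmse),
               ssim = mean(d$ssim), psnr = mean(d$psnr))))
  rownames(means) <- NULL
  tests <- list()
  for (metric in c("nrmse", "ssim")) {
    sp <- split(tab, tab$method)
    for (base in c("nearest", "bicubic")) {
      pc <- paired_comparison(sp$edsr[[metric]][order(sp$edsr$subject)],
                              sp[[base]][[metric]][order(sp[[base]]$subject)])
      tests[[length(tests) + 1L]] <-
        data.frame(metric = metric, comparison = paste0("edsr_vs_", base),
                   t = pc$t, p = pc$p, mean_diff = pc$mean_diff)
    }
  }
  list(means = means, tests = do.call(rbind, tests))
}
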