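#' Configuration of the single-channel EDSR-style network
#'
#' The network is a residual CNN for single-image super-resolution: a head
#' convolution lifting the grayscale input to `n_feats` feature maps, a chain
#' of residual blocks (two 3x3 convolutions with a ReLU between, no batch
#' normalisation, output scaled by `res_scale` before the skip add), a tail
#' convolution with a global skip from the head, then one convolution +
#' pixel-shuffle stage per doubling of resolution (one stage for 2x, two for
#' 4x), and a final convolution back to one channel. At the
#' "baseline-large" configuration (32 blocks, 256 features) the 4x network
#' has roughly 43 million trainable parameters.
#'
#' @param scale up-sampling factor, 2 or 4.
#' @param n_resblocks number of residual blocks (default 32).
#' @param n_feats feature maps per convolution (default 256).
#' @param res_scale residual scaling multiplier (default 0.1), which keeps
#'   very deep unnormalised residual chains stable.
#' @return An object of class `edsr_config`.
#' @export
edsr_config <- function(scale = 4, n_resblocks = 32, n_feats = 256,
                        res_scale = 0.1) {
  if (!scale %in% c(2, 4)) stop("`scale` must be 2 or 4", call. = FALSE)
  if (n_resblocks < 1 || n_feats < 1)
    stop("`n_resblocks` and `n_feats` must be >= 1", call. = FALSE)
  structure(list(scale = as.integer(scale),
                 n_resblocks = as.integer(n_resblocks),
                 n_feats = as.integer(n_feats),
                 res_scale = res_scale,
                 channels = 1L),
            class = "edsr_config")
}

# layer name -> (cin, cout) plan for a config
edsr_layer_plan <- function(cfg) {
  F <- cfg$n_feats
  plan <- list(head = c(1L, F))
  for (b in seq_len(cfg$n_resblocks)) {
    plan[[sprintf("body%d_conv1", b)]] <- c(F, F)
    plan[[sprintf("body%d_conv2", b)]] <- c(F, F)
  }
  plan$tail <- c(F, F)
  for (s in seq_len(log2(cfg$scale)))
    plan[[sprintf("up%d", s)]] <- c(F, 4L * F)
  plan$final <- c(F, 1L)
  plan
}

#' Build the EDSR-style super-resolution network
#'
#' Weights are Kaiming-uniform initialised from the current RNG state; set a
#' seed for reproducible models.
#'
#' @param cfg an [edsr_config()].
#' @param metadata optional named list of training provenance recorded with
#'   the model (stage, seed, loss at save).
#' @return An object of class `edsr`: the configuration, a named list of
#'   convolution layers, and metadata. Use [predict.edsr()] (or
#'   [forward_sr()]) for inference.
#' @examples
#' m <- build_edsr(edsr_config(scale = 4, n_resblocks = 2, n_feats = 8))
#' count_parameters(m)  # 7745
#' @export
build_edsr <- function(cfg, metadata = list()) {
  stopifnot(inherits(cfg, "edsr_config"))
  plan <- edsr_layer_plan(cfg)
  layers <- lapply(plan, function(io) conv3_init(io[1], io[2]))
  structure(list(config = cfg, layers = layers, metadata = metadata),
            class = "edsr")
}

#' Count trainable parameters of an EDSR model or configuration
#'
#' For a built model the parameters are counted tensor by tensor; for a bare
#' configuration the closed form `sum((3^2 * c_in + 1) * c_out)` over the
#' layer plan is used. The two agree exactly.
#'
#' @param x an `edsr` model or `edsr_config`.
#' @return Integer-valued parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "edsr"))
    return(sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0)))
  if (inherits(x, "edsr_config")) {
    plan <- edsr_layer_plan(x)
    return(sum(vapply(plan, function(io) (9 * io[1] + 1) * io[2], 0)))
  }
  stop("`x` must be an `edsr` or `edsr_config`", call. = FALSE)
}

# full forward pass on a (H*W) x 1 matrix of mean-subtracted intensities;
# keep = TRUE retains every im2col matrix and ReLU mask for backprop
edsr_forward_raw <- function(model, z, H, W, keep = FALSE) {
  cfg <- model$config
  L <- model$layers
  F <- cfg$n_feats
  cache <- if (keep) list(H = H, W = W) else NULL
  fh <- conv3_forward(z, L$head, H, W, keep)
  h0 <- fh$out
  if (keep) cache$head_cols <- fh$cols
  x <- h0
  for (b in seq_len(cfg$n_resblocks)) {
    n1 <- sprintf("body%d_conv1", b)
    n2 <- sprintf("body%d_conv2", b)
    f1 <- conv3_forward(x, L[[n1]], H, W, keep)
    a <- f1$out
    mask <- a > 0
    a[!mask] <- 0
    f2 <- conv3_forward(a, L[[n2]], H, W, keep)
    if (keep) {
      cache[[paste0(n1, "_cols")]] <- f1$cols
      cache[[paste0(n2, "_cols")]] <- f2$cols
      cache[[sprintf("body%d_mask", b)]] <- mask
    }
    x <- x + cfg$res_scale * f2$out
  }
  ft <- conv3_forward(x, L$tail, H, W, keep)
  if (keep) cache$tail_cols <- ft$cols
  g <- ft$out + h0
  h <- H
  w <- W
  for (s in seq_len(log2(cfg$scale))) {
    nm <- sprintf("up%d", s)
    fu <- conv3_forward(g, L[[nm]], h, w, keep)
    if (keep) {
      cache[[paste0(nm, "_cols")]] <- fu$cols
      cache[[paste0(nm, "_hw")]] <- c(h, w)
    }
    g <- pixel_shuffle(fu$out, h, w, F)
    h <- 2L * h
    w <- 2L * w
  }
  ff <- conv3_forward(g, L$final, h, w, keep)
  if (keep) {
    cache$final_cols <- ff$cols
    cache$out_hw <- c(h, w)
  }
  list(out = ff$out, cache = cache)
}

# backprop dL/dout (H2*W2 x 1) -> named list of layer gradients
edsr_backward_raw <- function(model, dout, cache) {
  cfg <- model$config
  L <- model$layers
  F <- cfg$n_feats
  H <- cache$H
  W <- cache$W
  grads <- list()
  hw <- cache$out_hw
  bf <- conv3_backward(dout, L$final, cache$final_cols, hw[1], hw[2])
  grads$final <- bf[c("dW", "db")]
  dg <- bf$dx
  for (s in rev(seq_len(log2(cfg$scale)))) {
    nm <- sprintf("up%d", s)
    hws <- cache[[paste0(nm, "_hw")]]
    dps <- pixel_shuffle_backward(dg, hws[1], hws[2], F)
    bu <- conv3_backward(dps, L[[nm]], cache[[paste0(nm, "_cols")]], hws[1], hws[2])
    grads[[nm]] <- bu[c("dW", "db")]
    dg <- bu$dx
  }
  # g = tail(x_B) + h0
  bt <- conv3_backward(dg, L$tail, cache$tail_cols, H, W)
  grads$tail <- bt[c("dW", "db")]
  dh0 <- dg           # global skip
  dx <- bt$dx
  for (b in rev(seq_len(cfg$n_resblocks))) {
    n1 <- sprintf("body%d_conv1", b)
    n2 <- sprintf("body%d_conv2", b)
    b2 <- conv3_backward(cfg$res_scale * dx, L[[n2]],
                         cache[[paste0(n2, "_cols")]], H, W)
    grads[[n2]] <- b2[c("dW", "db")]
    da <- b2$dx
    da[!cache[[sprintf("body%d_mask", b)]]] <- 0
    b1 <- conv3_backward(da, L[[n1]], cache[[paste0(n1, "_cols")]], H, W)
    grads[[n1]] <- b1[c("dW", "db")]
    dx <- dx + b1$dx
  }
  dh0 <- dh0 + dx
  bh <- conv3_backward(dh0, L$head, cache$head_cols, H, W, need_dx = FALSE)
  grads$head <- bh[c("dW", "db")]
  grads
}

#' Super-resolve an image with an EDSR model
#'
#' The per-image mean intensity is subtracted before the network and added
#' back to its output (the normalisation used for both training and
#' inference), so a zero-weight network is the identity on constants. The
#' whole frame is processed in one forward pass. Field of view is preserved:
#' output spacing is input spacing divided by the scale.
#'
#' @param model an `edsr` model.
#' @param img a `gray_image` with finite values.
#' @return A `gray_image` of size `dim(img) * scale`.
#' @export
forward_sr <- function(model, img) {
  stopifnot(inherits(model, "edsr"))
  img <- as_gray_image(img)
  if (!all(is.finite(img$pixels))) stop("non-finite input", call. = FALSE)
  d <- dim(img$pixels)
  m <- mean(img$pixels)
  z <- matrix(as.vector(img$pixels) - m, ncol = 1)
  out <- edsr_forward_raw(model, z, d[1], d[2])$out + m
  gray_image(matrix(out, d[1] * model$config$scale, d[2] * model$config$scale),
             spacing = img$spacing / model$config$scale)
}

#' @rdname forward_sr
#' @param object an `edsr` model.
#' @param ... unused.
#' @export
predict.edsr <- function(object, img, ...) forward_sr(object, img)

#' @export
print.edsr <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<edsr> %dx super-resolution, %d residual blocks, %d features (res_scale %.3g)\n",
              cfg$scale, cfg$n_resblocks, cfg$n_feats, cfg$res_scale))
  cat(sprintf("  %s trainable parameters\n",
              format(count_parameters(x), big.mark = ",")))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, function(v) paste(format(v), collapse = ","), ""),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.edsr <- function(object, ...) {
  plan <- edsr_layer_plan(object$config)
  df <- data.frame(layer = names(plan),
                   c_in = vapply(plan, `[`, 0L, 1),
                   c_out = vapply(plan, `[`, 0L, 2),
                   params = vapply(plan, function(io) (9 * io[1] + 1) * io[2], 0),
                   row.names = NULL)
  structure(list(config = object$config, layers = df,
                 total = sum(df$params)), class = "summary.edsr")
}

#' @export
print.summary.edsr <- function(x, ...) {
  cat(sprintf("EDSR %dx: %d layers, %s parameters\n", x$config$scale,
              nrow(x$layers), format(x$total, big.mark = ",")))
  print(utils::head(x$layers, 8))
  if (nrow(x$layers) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
coef.edsr <- function(object, ...) {
  lapply(object$layers, function(l)
    list(W = array(l$W, c(3, 3, l$cin, l$cout)), b = l$b))
}

#' Transfer parameters from a 2x model to a 4x configuration
#'
#' All shape-compatible tensors (head, residual blocks, tail, final
#' convolution) are copied bitwise; the up-sampling stages of the target,
#' which have no counterpart shape-compatible history at the lower scale,
#' are freshly Kaiming-uniform initialised from `init_seed` (recorded in the
#' metadata).
#'
#' @param src a trained `edsr` model at scale 2.
#' @param dst_cfg an [edsr_config()] at scale 4 with the same `n_resblocks`
#'   and `n_feats` as `src`.
#' @param init_seed seed for the fresh up-sampler initialisation.
#' @return A new `edsr` model at scale 4.
#' @export
transfer_scale <- function(src, dst_cfg, init_seed = 1L) {
  stopifnot(inherits(src, "edsr"), inherits(dst_cfg, "edsr_config"))
  if (src$config$scale != 2L || dst_cfg$scale != 4L)
    stop("transfer is from a 2x source to a 4x target", call. = FALSE)
  if (src$config$n_resblocks != dst_cfg$n_resblocks ||
      src$config$n_feats != dst_cfg$n_feats)
    stop("source and target must share n_resblocks and n_feats", call. = FALSE)
  dst <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(init_seed)
    build_edsr(dst_cfg)
  })
  copied <- intersect(names(src$layers), names(dst$layers))
  copied <- setdiff(copied, grep("^up", names(dst$layers), value = TRUE))
  for (nm in copied) dst$layers[[nm]] <- src$layers[[nm]]
  dst$metadata <- c(src$metadata,
                    list(transfer_from_scale = 2L, upsampler_init_seed = init_seed))
  dst
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Save / load a model bundle as a single file
#'
#' The bundle is one self-contained binary file: a versioned magic header, a
#' JSON block holding the configuration, metadata and a layer manifest, then
#' the weight tensors as IEEE doubles in manifest order. Serialization is
#' deterministic: saving the same model twice yields byte-identical files,
#' and a round trip reproduces weights bitwise.
#'
#' @param model an `edsr` model.
#' @param path file path.
#' @return `save_bundle`: `path` invisibly; `load_bundle`: the `edsr` model.
#' @export
save_bundle <- function(model, path) {
  stopifnot(inherits(model, "edsr"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MRISR-EDSR-v1\n"), con)
  manifest <- lapply(model$layers, function(l)
    list(cin = l$cin, cout = l$cout, nw = length(l$W), nb = length(l$b)))
  hdr <- jsonlite::toJSON(list(config = unclass(model$config),
                               metadata = model$metadata,
                               layers = manifest),
                          auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(hdr))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (l in model$layers) {
    writeBin(as.vector(l$W), con, size = 8L, endian = "little")
    writeBin(l$b, con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- charToRaw("MRISR-EDSR-v1\n")
  got <- readBin(con, "raw", length(magic))
  if (length(got) != length(magic) || !identical(got, magic))
    stop("corrupt bundle: bad magic header", call. = FALSE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0)
    stop("corrupt bundle: bad header length", call. = FALSE)
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) != hlen) stop("corrupt bundle: truncated header", call. = FALSE)
  hdr <- jsonlite::fromJSON(rawToChar(hraw), simplifyVector = TRUE)
  cfg <- edsr_config(scale = hdr$config$scale,
                     n_resblocks = hdr$config$n_resblocks,
                     n_feats = hdr$config$n_feats,
                     res_scale = hdr$config$res_scale)
  layers <- list()
  for (nm in names(hdr$layers)) {
    li <- hdr$layers[[nm]]
    w <- readBin(con, "double", li$nw, size = 8L, endian = "little")
    b <- readBin(con, "double", li$nb, size = 8L, endian = "little")
    if (length(w) != li$nw || length(b) != li$nb)
      stop("corrupt bundle: truncated weights", call. = FALSE)
    layers[[nm]] <- list(W = matrix(w, 9L * li$cin, li$cout), b = b,
                         cin = li$cin, cout = li$cout)
  }
  expect_names <- names(edsr_layer_plan(cfg))
  if (!identical(names(layers), expect_names))
    stop("corrupt bundle: layer manifest does not match architecture", call. = FALSE)
  structure(list(config = cfg, layers = layers,
                 metadata = as.list(hdr$metadata)), class = "edsr")
}
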