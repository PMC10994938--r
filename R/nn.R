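# Minimal dense 3x3 convolution engine used by the super-resolution network.
#
# Feature maps are stored as (H*W) x C matrices in column-major pixel order,
# so a 3x3 same-padded convolution is one im2col gather plus one BLAS matrix
# multiply; the backward pass is the transposed gather. Index maps are cached
# per (H, W, C) because training re-uses a handful of shapes thousands of
# times.

.nn_cache <- new.env(parent = emptyenv())

# linear indices of the interior of a zero-padded (H+2)x(W+2)xC array
pad_interior_idx <- function(H, W, C) {
  key <- sprintf("int_%d_%d_%d", H, W, C)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + 2L
  Wp <- W + 2L
  r <- rep(seq_len(H) + 1L, times = W * C)
  cc <- rep(rep(seq_len(W) + 1L, each = H), times = C)
  ch <- rep(seq_len(C), each = H * W)
  idx <- (ch - 1L) * Hp * Wp + (cc - 1L) * Hp + r
  .nn_cache[[key]] <- idx
  idx
}

# (H*W) x (9C) gather map: tap order (dr fastest, then dc, then channel)
im2col_idx <- function(H, W, C) {
  key <- sprintf("col_%d_%d_%d", H, W, C)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + 2L
  Wp <- W + 2L
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  q <- 0L
  for (ch in seq_len(C)) {
    base <- (ch - 1L) * Hp * Wp
    for (dc in -1:1) {
      for (dr in -1:1) {
        q <- q + 1L
        idx[, q] <- base + (cc + dc) * Hp + (r + dr + 1L)
      }
    }
  }
  .nn_cache[[key]] <- idx
  idx
}

# x: (H*W) x Cin matrix -> list(out = (H*W) x Cout, cols) for backward
conv3_forward <- function(x, layer, H, W, keep_cols = FALSE) {
  Cin <- layer$cin
  xp <- numeric((H + 2L) * (W + 2L) * Cin)
  xp[pad_interior_idx(H, W, Cin)] <- x
  cols <- matrix(xp[im2col_idx(H, W, Cin)], H * W, 9L * Cin)
  out <- cols %*% layer$W
  out <- out + rep(layer$b, each = H * W)
  list(out = out, cols = if (keep_cols) cols else NULL)
}

# dY: (H*W) x Cout; returns grads and dX
conv3_backward <- function(dY, layer, cols, H, W, need_dx = TRUE) {
  Cin <- layer$cin
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dx <- NULL
  if (need_dx) {
    dcols <- tcrossprod(dY, layer$W)
    idx <- im2col_idx(H, W, Cin)
    dxp <- numeric((H + 2L) * (W + 2L) * Cin)
    for (q in seq_len(ncol(idx))) {
      iq <- idx[, q]
      dxp[iq] <- dxp[iq] + dcols[, q]
    }
    dx <- matrix(dxp[pad_interior_idx(H, W, Cin)], H * W, Cin)
  }
  list(dW = dW, db = db, dx = dx)
}

# pixel shuffle r = 2: (H*W) x 4F -> (2H*2W) x F; returns permutation so
# out_vec = in_vec[perm] on the flattened matrices
pixel_shuffle_perm <- function(H, W, F) {
  key <- sprintf("ps_%d_%d_%d", H, W, F)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  H2 <- 2L * H
  W2 <- 2L * W
  r2 <- rep(seq_len(H2), times = W2 * F)
  c2 <- rep(rep(seq_len(W2), each = H2), times = F)
  f <- rep(seq_len(F), each = H2 * W2)
  i <- (r2 + 1L) %/% 2L
  j <- (c2 + 1L) %/% 2L
  di <- (r2 - 1L) %% 2L
  dj <- (c2 - 1L) %% 2L
  cin <- (f - 1L) * 4L + di * 2L + dj + 1L
  perm <- (cin - 1L) * H * W + (j - 1L) * H + i
  .nn_cache[[key]] <- perm
  perm
}

pixel_shuffle <- function(x, H, W, F) {
  perm <- pixel_shuffle_perm(H, W, F)
  matrix(as.vector(x)[perm], 4L * H * W, F)
}

pixel_shuffle_backward <- function(dout, H, W, F) {
  perm <- pixel_shuffle_perm(H, W, F)
  din <- numeric(4L * H * W * F)
  din[perm] <- as.vector(dout)
  matrix(din, H * W, 4L * F)
}

# Kaiming-uniform initialisation for a 3x3 conv layer
conv3_init <- function(cin, cout) {
  fan_in <- 9 * cin
  bound <- sqrt(6 / fan_in)
  list(W = matrix(stats::runif(9 * cin * cout, -bound, bound), 9 * cin, cout),
       b = stats::runif(cout, -1 / sqrt(fan_in), 1 / sqrt(fan_in)),
       cin = cin, cout = cout)
}

conv3_zero_grad <- function(layer) {
  list(dW = matrix(0, nrow(layer$W), ncol(layer$W)), db = numeric(length(layer$b)))
}

# Adam optimiser state over a flat named list of conv layers
adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(layers)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[nm]]$W <- layers[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[nm]]$b <- layers[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(layers = layers, state = state)
}
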