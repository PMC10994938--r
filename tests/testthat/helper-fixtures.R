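# Shared fixtures, all generated in code.

tiny_model <- function(scale = 4, B = 2, F = 8, seed = 11) {
  set.seed(seed)
  build_edsr(edsr_config(scale, B, F))
}

zeroed_model <- function(scale = 4, B = 2, F = 8) {
  m <- tiny_model(scale, B, F)
  for (nm in names(m$layers)) {
    m$layers[[nm]]$W[] <- 0
    m$layers[[nm]]$b[] <- 0
  }
  m
}

seeded_image <- function(n = 16, seed = 1, lo = 0, hi = 100, spacing = 1) {
  set.seed(seed)
  gray_image(matrix(runif(n * n, lo, hi), n, n), spacing)
}

disk_image <- function(n = 128, radius = 30, value = 1000, spacing = 1) {
  co <- (seq_len(n) - (n + 1) / 2) * spacing
  d <- sqrt(outer(co^2, co^2, "+"))
  gray_image(ifelse(d < radius, value, 0) + 0, spacing)
}

# independent brute-force centered DFT oracle: explicit sums over output
# frequencies, DC at 0-based floor(N/2)
dft_centered_oracle <- function(x) {
  H <- nrow(x)
  W <- ncol(x)
  out <- matrix(0 + 0i, H, W)
  for (u in 0:(H - 1)) {
    ku <- u - floor(H / 2)
    for (v in 0:(W - 1)) {
      kv <- v - floor(W / 2)
      ph <- outer(exp(-2i * pi * ku * (0:(H - 1)) / H),
                  exp(-2i * pi * kv * (0:(W - 1)) / W))
      out[u + 1, v + 1] <- sum(x * ph)
    }
  }
  out / sqrt(H * W)
}

# brute-force k-space crop oracle: centered DFT, central M-block crop with
# the sqrt(prod(m)/prod(n)) rescale, inverse by explicit sums, magnitude
kspace_downsample_oracle <- function(x, factor) {
  H <- nrow(x)
  W <- ncol(x)
  m <- c(H, W) %/% factor
  spec <- dft_centered_oracle(x)
  i <- (floor(H / 2) - floor(m[1] / 2) + 1):(floor(H / 2) - floor(m[1] / 2) + m[1])
  j <- (floor(W / 2) - floor(m[2] / 2) + 1):(floor(W / 2) - floor(m[2] / 2) + m[2])
  crop <- spec[i, j, drop = FALSE] * sqrt(prod(m) / (H * W))
  h <- m[1]; w <- m[2]
  out <- matrix(0 + 0i, h, w)
  for (r in 0:(h - 1)) {
    for (cc in 0:(w - 1)) {
      ku <- (0:(h - 1)) - floor(h / 2)
      kv <- (0:(w - 1)) - floor(w / 2)
      ph <- outer(exp(2i * pi * ku * r / h), exp(2i * pi * kv * cc / w))
      out[r + 1, cc + 1] <- sum(crop * ph)
    }
  }
  Mod(out / sqrt(h * w))
}

# independent per-window SSIM oracle (explicit sliding windows)
ssim_oracle <- function(x, y, win = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  g1 <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  R <- diff(range(y))
  C1 <- (K1 * R)^2
  C2 <- (K2 * R)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in seq_len(H - win + 1)) {
    for (j in seq_len(W - win + 1)) {
      wx <- x[i:(i + win - 1), j:(j + win - 1)]
      wy <- y[i:(i + win - 1), j:(j + win - 1)]
      m1 <- sum(G * wx); m2 <- sum(G * wy)
      s11 <- sum(G * wx * wx) - m1^2
      s22 <- sum(G * wy * wy) - m2^2
      s12 <- sum(G * wx * wy) - m1 * m2
      vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * s12 + C2)) /
                  ((m1^2 + m2^2 + C1) * (s11 + s22 + C2)))
    }
  }
  mean(vals)
}

# direct (definition-level) 3x3 zero-padded convolution on (H,W,Cin) arrays
direct_conv3 <- function(x, Warr, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(Warr)[4]
  out <- array(0, c(H, W, Cout))
  xp <- array(0, c(H + 2, W + 2, Cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  for (o in seq_len(Cout)) {
    acc <- matrix(b[o], H, W)
    for (ci in seq_len(Cin))
      for (dr in 1:3)
        for (dc in 1:3)
          acc <- acc + Warr[dr, dc, ci, o] *
            xp[(dr):(dr + H - 1), (dc):(dc + W - 1), ci]
    out[, , o] <- acc
  }
  out
}
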