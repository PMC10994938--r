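test_that("parameter counts match the closed-form layer sum", {
  expect_equal(count_parameters(edsr_config(4, 2, 8)), 7745)
  m <- tiny_model(4, 2, 8)
  expect_equal(count_parameters(m), 7745)

  # automatic per-tensor count vs closed form across random configs
  set.seed(21)
  for (i in 1:10) {
    B <- sample(1:4, 1); F <- sample(1:16, 1); sc <- sample(c(2, 4), 1)
    cfg <- edsr_config(sc, B, F)
    expect_identical(count_parameters(build_edsr(cfg)), count_parameters(cfg))
  }

  expect_error(edsr_config(3), "scale")
})

test_that("forward pass obeys shape, spacing and mean-shift contracts", {
  m2 <- tiny_model(2, 1, 1)
  out <- forward_sr(m2, seeded_image(8, spacing = 2))
  expect_equal(dim(out$pixels), c(16L, 16L))
  expect_equal(out$spacing, c(1, 1))

  z <- zeroed_model(4, 2, 8)
  o <- forward_sr(z, gray_image(matrix(7, 8, 8), spacing = 4))
  expect_equal(range(o$pixels), c(7, 7))
  expect_equal(o$spacing, c(1, 1))
  expect_equal(field_of_view(o), c(32, 32))

  # mean-shift bookkeeping: output mean minus input mean is the residual mean
  m <- tiny_model(4, 2, 4, seed = 2)
  x <- seeded_image(8, seed = 5, hi = 50)
  mu <- mean(x$pixels)
  raw <- mrisr:::edsr_forward_raw(m, matrix(as.vector(x$pixels) - mu, ncol = 1),
                                  8, 8)$out
  expect_equal(mean(forward_sr(m, x)$pixels) - mu, mean(raw), tolerance = 1e-12)

  expect_error(forward_sr(m, gray_image(matrix(c(1, NA, 1, 1), 2, 2))),
               "finite")
})

test_that("network forward equals a direct-convolution oracle", {
  m <- tiny_model(2, 2, 4, seed = 31)
  cfg <- m$config
  x <- seeded_image(4, seed = 8, hi = 10)
  got <- forward_sr(m, x)$pixels

  # independent re-computation from the definition of each block
  W4 <- function(nm) array(m$layers[[nm]]$W, c(3, 3, m$layers[[nm]]$cin,
                                               m$layers[[nm]]$cout))
  mu <- mean(x$pixels)
  z <- array(x$pixels - mu, c(4, 4, 1))
  h0 <- direct_conv3(z, W4("head"), m$layers$head$b)
  xb <- h0
  for (b in 1:2) {
    a <- direct_conv3(xb, W4(sprintf("body%d_conv1", b)),
                      m$layers[[sprintf("body%d_conv1", b)]]$b)
    a[a < 0] <- 0
    r <- direct_conv3(a, W4(sprintf("body%d_conv2", b)),
                      m$layers[[sprintf("body%d_conv2", b)]]$b)
    xb <- xb + cfg$res_scale * r
  }
  g <- direct_conv3(xb, W4("tail"), m$layers$tail$b) + h0
  u <- direct_conv3(g, W4("up1"), m$layers$up1$b)
  F <- cfg$n_feats
  ps <- array(0, c(8, 8, F))
  for (f in seq_len(F)) for (r2 in 1:8) for (c2 in 1:8) {
    i <- (r2 + 1) %/% 2; j <- (c2 + 1) %/% 2
    di <- (r2 - 1) %% 2; dj <- (c2 - 1) %% 2
    ps[r2, c2, f] <- u[i, j, (f - 1) * 4 + di * 2 + dj + 1]
  }
  y <- direct_conv3(ps, W4("final"), m$layers$final$b)[, , 1] + mu
  expect_lt(max(abs(got - y)), 1e-5)
})

test_that("forward pass is translation-consistent at the pixel level", {
  m <- tiny_model(2, 2, 4, seed = 41)
  set.seed(42)
  base <- matrix(runif(32 * 32, 0, 50), 32, 32)
  x1 <- gray_image(base)
  x2 <- gray_image(base[c(2:32, 1), ])  # circular shift: identical mean
  o1 <- forward_sr(m, x1)$pixels
  o2 <- forward_sr(m, x2)$pixels
  # away from borders and the wrap seam, shifting the input by 1 LR pixel
  # shifts the output by `scale` HR pixels
  a <- o1[19:44, 17:48]
  b <- o2[17:42, 17:48]
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-4)
})

test_that("bicubic baseline reproduces constants, ramps and the kernel sum", {
  cst <- upsample_bicubic(gray_image(matrix(5, 8, 8), spacing = 4), 4)
  expect_equal(range(cst$pixels), c(5, 5), tolerance = 1e-12)
  expect_equal(cst$spacing, c(1, 1))

  rmp <- gray_image(matrix(rep(1:16, each = 16), 16, 16))
  up <- upsample_bicubic(rmp, 2)
  want <- ((seq_len(32) - 0.5) / 2 - 0.5) + 1
  expect_lt(max(abs(up$pixels[16, 5:28] - want[5:28])), 1e-6)

  # one interior output sample against the explicit 16-tap kernel sum
  x <- seeded_image(4, seed = 12)
  up2 <- upsample_bicubic(x, 2)
  ck <- function(t) {
    a <- -0.5; at <- abs(t)
    if (at <= 1) (a + 2) * at^3 - (a + 3) * at^2 + 1
    else if (at < 2) a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a else 0
  }
  i_out <- 5; j_out <- 4                      # 1-based output sample
  sr <- (i_out - 0.5) / 2 - 0.5               # 0-based source coords
  sc <- (j_out - 0.5) / 2 - 0.5
  acc <- 0
  for (dr in -1:2) for (dc in -1:2) {
    r <- min(max(floor(sr) + dr, 0), 3)
    cc <- min(max(floor(sc) + dc, 0), 3)
    acc <- acc + ck(sr - (floor(sr) + dr)) * ck(sc - (floor(sc) + dc)) *
      x$pixels[r + 1, cc + 1]
  }
  expect_equal(up2$pixels[i_out, j_out], acc, tolerance = 1e-12)
})

test_that("nearest-neighbour baseline replicates blocks", {
  x <- gray_image(matrix(c(1, 3, 2, 4), 2, 2))
  up <- upsample_nearest(x, 2)
  expect_equal(up$pixels, matrix(c(1, 1, 3, 3, 1, 1, 3, 3,
                                   2, 2, 4, 4, 2, 2, 4, 4), 4, 4))
  expect_identical(upsample_nearest(x, 1)$pixels, x$pixels)
  y <- seeded_image(6)
  u4 <- upsample_nearest(y, 4)
  expect_equal(as.vector(table(u4$pixels)), rep(16, 36))
  expect_equal(field_of_view(u4), field_of_view(y))
})

test_that("scale transfer copies every non-upsampler tensor and inits the rest", {
  s2 <- tiny_model(2, 2, 8, seed = 6)
  d4 <- transfer_scale(s2, edsr_config(4, 2, 8), init_seed = 9)
  keep <- setdiff(names(s2$layers), "up1")
  for (nm in keep) expect_identical(s2$layers[[nm]], d4$layers[[nm]])
  fresh <- grep("^up", names(d4$layers), value = TRUE)
  expect_identical(fresh, c("up1", "up2"))
  expect_false(identical(d4$layers$up1, s2$layers$up1))

  # constant passes through when the upsampler path is zeroed
  d4$layers$up1$W[] <- 0; d4$layers$up1$b[] <- 0
  d4$layers$up2$W[] <- 0; d4$layers$up2$b[] <- 0
  d4$layers$final$W[] <- 0; d4$layers$final$b[] <- 0
  o <- forward_sr(d4, gray_image(matrix(3, 8, 8)))
  expect_equal(range(o$pixels), c(3, 3))

  expect_error(transfer_scale(tiny_model(2, 1, 8), edsr_config(4, 2, 8)),
               "share")
})

test_that("model bundles round-trip bitwise through one deterministic file", {
  m <- tiny_model(4, 2, 8, seed = 5)
  m$metadata <- list(stage = "scale4_transfer", seed = 5L, loss_at_save = 0.5)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  save_bundle(m, p1)
  save_bundle(m, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  m2 <- load_bundle(p1)
  x <- seeded_image(8, seed = 3)
  expect_identical(forward_sr(m, x)$pixels, forward_sr(m2, x)$pixels)
  expect_equal(m2$metadata$stage, "scale4_transfer")

  r <- readBin(p1, "raw", file.size(p1))
  writeBin(r[seq_len(length(r) - 200)], p2)
  expect_error(load_bundle(p2), "corrupt")
  expect_error(load_bundle(file.path(tempdir(), "nope.bundle")), "not found")
})
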