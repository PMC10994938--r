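test_that("NRMSE and PSNR follow their closed forms", {
  x <- seeded_image(8, seed = 1)
  expect_equal(nrmse(x, x), 0)
  ref <- gray_image(matrix(c(0, 1), 8, 8))
  test <- gray_image(ref$pixels + 0.1)
  expect_equal(nrmse(test, ref), 0.1, tolerance = 1e-12)
  a <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  b <- matrix(c(2, 2, 3, 3, 5, 7, 7, 8, 10), 3, 3)
  expect_equal(nrmse(gray_image(a), gray_image(b)),
               sqrt(mean((a - b)^2)) / (10 - 2), tolerance = 1e-12)

  # MSE = range^2 / 100 -> exactly 20 dB
  r2 <- gray_image(matrix(c(0, 10), 10, 10))
  t2 <- gray_image(r2$pixels + 1)
  expect_equal(psnr(t2, r2), 20, tolerance = 1e-12)
  expect_equal(psnr(x, x), 100)
  p <- matrix(c(0, 4, 2, 6), 2, 2)
  q <- matrix(c(1, 4, 2, 4), 2, 2)
  expect_equal(psnr(gray_image(p), gray_image(q)),
               10 * log10(diff(range(q))^2 / mean((p - q)^2)), tolerance = 1e-12)

  expect_error(nrmse(x, gray_image(matrix(1, 8, 8))), "degenerate")
  expect_error(psnr(x, gray_image(matrix(1, 8, 8))), "degenerate")
})

test_that("SSIM matches an independent sliding-window implementation", {
  x <- seeded_image(20, seed = 5)
  expect_equal(ssim(x, x), 1)
  y <- gray_image(0.5 * x$pixels)
  expect_equal(ssim(y, x), ssim_oracle(y$pixels, x$pixels), tolerance = 1e-8)
  z <- seeded_image(20, seed = 6)
  expect_equal(ssim(z, x), ssim_oracle(z$pixels, x$pixels), tolerance = 1e-8)

  # joint rescaling leaves SSIM invariant when the data range is recomputed
  s1 <- ssim(z, x)
  s2 <- ssim(gray_image(3 * z$pixels), gray_image(3 * x$pixels))
  expect_equal(s1, s2, tolerance = 1e-9)

  expect_error(ssim(seeded_image(8), seeded_image(8)), "window")
})

test_that("metrics degrade monotonically with growing noise and ignore background", {
  ref <- gen_anatomy_phantom(phantom_recipe(seed = 12, matrix = 64))
  rng <- diff(range(ref$pixels))
  set.seed(3)
  res <- sapply(c(0.01, 0.02, 0.04, 0.08), function(s) {
    noisy <- gray_image(pmax(ref$pixels + rnorm(64 * 64, 0, s * rng), 0))
    c(nrmse(noisy, ref), ssim(noisy, ref), psnr(noisy, ref))
  })
  expect_true(all(diff(res[1, ]) > 0))   # NRMSE worsens
  expect_true(all(diff(res[2, ]) < 0))   # SSIM worsens
  expect_true(all(diff(res[3, ]) < 0))   # PSNR worsens

  # masked metrics are unaffected by pixels outside the mask
  msk <- brain_mask(ref)
  test <- gray_image(pmax(ref$pixels + rnorm(64 * 64, 0, 0.02 * rng), 0))
  outside <- test$pixels
  outside[!msk] <- outside[!msk] + 500
  m1 <- c(nrmse(test$pixels * msk, ref$pixels * msk),
          ssim(test$pixels * msk, ref$pixels * msk))
  m2 <- c(nrmse(outside * msk, ref$pixels * msk),
          ssim(outside * msk, ref$pixels * msk))
  expect_equal(m1, m2)
})

test_that("brain mask isolates the object and is idempotent", {
  disk <- disk_image(128, radius = 30, value = 1000)
  msk <- brain_mask(disk)
  co <- (1:128) - 129 / 2
  truth <- sqrt(outer(co^2, co^2, "+")) < 30
  expect_gt(sum(msk & truth) / sum(msk | truth), 0.99)

  expect_identical(brain_mask(gray_image(matrix(0, 16, 16))),
                   matrix(FALSE, 16, 16))

  masked <- gray_image(disk$pixels * msk)
  expect_identical(brain_mask(masked), msk)
})

test_that("rigid registration recovers constructed shifts and rotations", {
  ph <- gen_anatomy_phantom(phantom_recipe(seed = 3, matrix = 128))
  tf0 <- rigid_register_2d(ph, ph)
  expect_lt(abs(tf0$theta), 0.05)
  expect_lt(max(abs(c(tf0$dx, tf0$dy))), 0.05)

  sh <- apply_rigid(ph, rigid_transform_2d(0, 3, -2))
  tf <- rigid_register_2d(sh, ph)
  expect_lt(abs(tf$theta), 0.2)
  expect_lt(abs(tf$dx - (-3)), 0.2)
  expect_lt(abs(tf$dy - 2), 0.2)

  rot <- apply_rigid(ph, rigid_transform_2d(2.0))
  tf2 <- rigid_register_2d(rot, ph)
  expect_lt(abs(tf2$theta - (-2)), 0.2)
})

test_that("registration recovers random rigid perturbations on average", {
  ph <- gen_anatomy_phantom(phantom_recipe(seed = 8, matrix = 96))
  set.seed(14)
  errs <- t(sapply(1:20, function(i) {
    th <- runif(1, -5, 5)
    dx <- runif(1, -5, 5)
    dy <- runif(1, -5, 5)
    mv <- apply_rigid(ph, rigid_transform_2d(th, dx, dy))
    tf <- rigid_register_2d(mv, ph)
    # expected inverse: theta2 = -theta, t2 = -R(-theta) t
    thr <- th * pi / 180
    ex <- -c(cos(thr) * dx + sin(thr) * dy, -sin(thr) * dx + cos(thr) * dy)
    c(abs(tf$theta + th), abs(tf$dx - ex[1]), abs(tf$dy - ex[2]))
  }))
  expect_lt(mean(errs[, 1]), 0.3)          # degrees
  expect_lt(mean(sqrt(errs[, 2]^2 + errs[, 3]^2)), 0.3)  # pixels
})

test_that("paired t test matches hand formula and handles degeneracy", {
  pc <- paired_comparison(c(2, 4, 6), c(1, 2, 3))   # differences 1, 2, 3
  expect_equal(pc$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(pc$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)

  same <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  flip <- paired_comparison(c(1, 2, 3), c(2, 4, 6))
  expect_equal(flip$t, -pc$t, tolerance = 1e-12)
  expect_equal(flip$p, pc$p, tolerance = 1e-12)

  deg <- paired_comparison(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
})

test_that("method evaluation plumbing is deterministic and ranks baselines", {
  labs <- gen_label_set(6, seed = 31, matrix = 64)
  i <- 0
  oracle <- function(lr) {
    i <<- i + 1
    minmax_scale(clip_to_percentile(labs[[i]], 99.9), 0, 4096)
  }
  tab <- evaluate_methods(labs, model = oracle, factor = 4, mask = TRUE)
  ed <- tab[tab$method == "edsr", ]
  expect_equal(ed$nrmse, rep(0, 6))
  expect_equal(ed$ssim, rep(1, 6))

  z <- zeroed_model()
  t1 <- evaluate_methods(labs[1:2], model = z, factor = 4)
  t2 <- evaluate_methods(labs[1:2], model = z, factor = 4)
  expect_equal(t1, t2)

  expect_gt(mean(tab$nrmse[tab$method == "nearest"]),
            mean(tab$nrmse[tab$method == "bicubic"]))

  sm <- summarise_evaluation(tab)
  expect_equal(nrow(sm$means), 3)
  expect_equal(nrow(sm$tests), 4)
})
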