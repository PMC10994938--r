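test_that("sinusoid trace has the stated closed form, mean and RMS", {
  tr <- gen_sinusoid_trace(10, 0.25, 40, 4, phase = 0)
  expect_equal(tr$x[tr$t == 1], 10 * sin(pi / 2))
  expect_lt(abs(mean(tr$x[tr$t < 40])), 1e-9)      # integer periods
  rms <- sqrt(mean(tr$x[tr$t < 40]^2))
  expect_equal(rms, 10 / sqrt(2), tolerance = 1e-3)
  expect_error(gen_sinusoid_trace(10, 3, 10, rate = 4), "aliasing")
})

test_that("breathing trace is seeded, degenerates to a sinusoid, and peaks near 1/period", {
  b1 <- gen_breathing_trace(seed = 5, duration = 60, rate = 4)
  b2 <- gen_breathing_trace(seed = 5, duration = 60, rate = 4)
  expect_identical(b1$x, b2$x)

  b0 <- gen_breathing_trace(seed = 1, duration = 20, rate = 8, period = 4,
                            amplitude = 10, jitter_amp = 0, jitter_period = 0,
                            drift_sd = 0)
  s0 <- gen_sinusoid_trace(10, 0.25, 20, 8)
  expect_equal(b0$x, s0$x, tolerance = 1e-12)

  br <- gen_breathing_trace(seed = 9, duration = 120, rate = 4)
  sp <- Mod(fft(br$x - mean(br$x)))[2:floor(length(br$x) / 2)]
  fpk <- which.max(sp) / (length(br$x) / 4)
  expect_lt(abs(fpk - 0.25) / 0.25, 0.1)
})

test_that("rendered frames have centred, translating, correctly sized discs", {
  spec <- phantom_spec(noise_sd = 0, background = 0)
  f0 <- render_frame(spec, 0, 64)
  n <- 64
  w <- f0$pixels / sum(f0$pixels)
  cy <- sum(w * matrix(1:n, n, n, byrow = TRUE))
  cx <- sum(w * matrix(1:n, n, n))
  expect_lt(abs(cx - (n + 1) / 2), 0.05)
  expect_lt(abs(cy - (n + 1) / 2), 0.05)

  f2 <- render_frame(spec, 2 * 6.25, 64)
  w2 <- f2$pixels / sum(f2$pixels)
  cy2 <- sum(w2 * matrix(1:n, n, n, byrow = TRUE))
  expect_lt(abs(cy2 - cy - 2), 0.05)

  f128 <- render_frame(spec, 0, 128)
  sp <- 400 / 128
  area <- sum(f128$pixels > spec$target_intensity / 2)
  expect_lt(abs(area - pi * 30^2 / sp^2) / (pi * 30^2 / sp^2), 0.02)

  expect_error(render_frame(spec, 180, 64), "field of view")
})

test_that("template matching reports displacements in mm with sub-pixel refinement", {
  spec <- phantom_spec(noise_sd = 0)
  f0 <- render_frame(spec, 0, 64)
  tmpl <- gray_image(f0$pixels[20:45, 20:45], spacing = f0$spacing)
  t0 <- template_match(f0, tmpl, ref_pos = c(20, 20), subpixel = FALSE)
  expect_equal(t0$displacement, c(0, 0))
  expect_false(t0$lost)

  f3 <- render_frame(spec, 3 * 6.25, 64)
  t3 <- template_match(f3, tmpl, ref_pos = c(20, 20), subpixel = FALSE)
  expect_equal(t3$displacement, c(0, 3 * 6.25))

  # analytically rendered half-pixel shift recovered to < 0.2 px
  fh <- render_frame(spec, 0.5 * 6.25, 64)
  th <- template_match(fh, tmpl, ref_pos = c(20, 20), subpixel = TRUE)
  expect_lt(abs(th$displacement[2] - 0.5 * 6.25), 0.2 * 6.25)

  lost <- template_match(gray_image(matrix(runif(64 * 64), 64, 64),
                                    f0$spacing), tmpl, threshold = 0.9)
  expect_true(lost$lost)
})

test_that("MLC response is rate-limited with exact arrival and zero ramp lag", {
  mspec <- mlc_spec(max_leaf_velocity = 25)
  expect_equal(mlc_respond(10, 0, mspec, 0.1), 2.5)
  expect_equal(mlc_respond(1.2, 0, mspec, 0.1), 1.2)

  # ramp slower than the velocity limit: no steady-state lag
  dt <- 0.02
  ts <- seq(0, 10, by = dt)
  cmd <- pmin(5 * ts, 40)       # 5 mm/s ramp
  pos <- 0
  lag <- numeric(length(ts))
  for (i in seq_along(ts)) {
    pos <- mlc_respond(cmd[i], pos, mspec, dt)
    lag[i] <- cmd[i] - pos
  }
  expect_lt(max(abs(lag[ts > 1 & ts < 7])), 5 * dt + 1e-9)
})

test_that("an unconstrained zero-delay chain tracks the target closely", {
  spec <- phantom_spec(noise_sd = 0)
  tim <- chain_timing(frame_period = 0.05, recon_delay = 0, sr_delay = 0,
                      tracking_delay = 0, mlc_delay = 0)
  mlcs <- mlc_spec(max_leaf_velocity = 1e6, control_rate = 200)
  tr <- gen_sinusoid_trace(10, 0.1, 16, 40)
  ch <- run_chain(tr, spec, tim, mlcs, sr_method = "none", track_matrix = 256,
                  seed = 1, subpixel = TRUE)
  expect_lt(geometric_error(ch$target, ch$aperture), 0.35)
  expect_equal(ch$nominal_latency, 0.025)
})

test_that("the chain injects the nominal mid-exposure latency", {
  spec <- phantom_spec(noise_sd = 0)
  # stage delays sum 0.225 s; with the 4 Hz half-frame this is 0.350 s
  tim <- chain_timing(frame_period = 0.25, recon_delay = 0.1,
                      sr_delay = 0.005, tracking_delay = 0.06,
                      mlc_delay = 0.06)
  mlcs <- mlc_spec(max_leaf_velocity = 400)
  tr <- gen_sinusoid_trace(10, 0.25, 40, 32)
  expect_equal(chain_timing()$epid_rate, 3.6)

  ch <- run_chain(tr, spec, tim, mlcs, sr_method = "none", track_matrix = 256,
                  seed = 5, subpixel = TRUE)
  expect_equal(ch$nominal_latency, 0.35)
  expect_lt(abs(estimate_latency(ch$target, ch$aperture) - 0.35), 0.01)

  # quantised 64-grid tracking: pixel-pitch displacement steps
  chq <- run_chain(tr, spec, tim, mlcs, sr_method = "none", seed = 5)
  expect_true(all(abs(chq$displacements / 6.25 -
                        round(chq$displacements / 6.25)) < 1e-9))
  expect_lt(abs(estimate_latency(chq$target, chq$aperture) - 0.35), 0.02)
})

test_that("latency estimation recovers constructed delays and is causal", {
  tg <- gen_sinusoid_trace(10, 0.25, 40, 3.6)
  expect_equal(estimate_latency(tg, tg), 0)

  for (tau in c(0.1, 0.35, 0.5)) for (f in c(0.1, 0.25)) {
    t2 <- gen_sinusoid_trace(10, f, 60, 3.6)
    ap <- motion_trace(t2$t + tau, t2$x)
    est <- estimate_latency(t2, ap)
    expect_lt(abs(est - tau), 0.005)
    expect_gte(est, 0)
  }

  noise <- gen_breathing_trace(seed = 2, duration = 40, rate = 3.6,
                               jitter_amp = 1, jitter_period = 0.5, drift_sd = 3)
  expect_error(estimate_latency(noise, noise), "sinusoidal|overlap")
})

test_that("geometric error follows the delayed-sinusoid closed form", {
  tg <- gen_sinusoid_trace(10, 0.25, 40, 3.6)
  expect_equal(geometric_error(tg, tg), 0)

  off <- motion_trace(tg$t, tg$x + 2)
  expect_equal(geometric_error(tg, off), 2, tolerance = 1e-12)

  tau <- 0.35
  ap <- motion_trace(tg$t, 10 * sin(2 * pi * 0.25 * (tg$t - tau)))
  want <- 10 * sqrt(2) * abs(sin(pi * 0.25 * tau))
  expect_lt(abs(geometric_error(tg, ap) - want) / want, 0.01)
})

test_that("latency correction cancels pure delay and leaves the noise floor", {
  tg <- gen_sinusoid_trace(10, 0.25, 40, 3.6)
  ap <- motion_trace(tg$t + 0.35, tg$x)
  expect_lt(latency_corrected_error(tg, ap, 0.35), 1e-6)
  expect_lte(latency_corrected_error(tg, ap, 0.35),
             geometric_error(tg, ap))

  set.seed(77)
  nz <- rnorm(length(tg$t), 0, 0.5)
  apn <- motion_trace(tg$t + 0.35, tg$x + nz)
  corr <- latency_corrected_error(tg, apn, 0.35)
  expect_lt(abs(corr - sqrt(mean(nz^2))) / sqrt(mean(nz^2)), 0.1)
})

test_that("the experiment suite reports three repeats per method", {
  spec <- phantom_spec(noise_sd = 0)
  tim <- chain_timing(0.25, 0.1, 0.005, 0.06, 0.06)
  rep1 <- experiment_suite(c("none"), spec, tim, mlc_spec(400),
                           n_repeats = 2, seed = 3, duration = 16)
  expect_s3_class(rep1, "tracking_report")
  expect_equal(nrow(rep1$repeats), 2)
  expect_equal(rep1$summary$n_repeats, 2)
  expect_true(all(rep1$repeats$latency > 0))
  rep2 <- experiment_suite(c("none"), spec, tim, mlc_spec(400),
                           n_repeats = 2, seed = 3, duration = 16)
  expect_equal(rep1$repeats, rep2$repeats)
})
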