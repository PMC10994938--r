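#' @title In-silico MLC tracking latency and error experiment
#'
#' @description Replicates the motion-phantom beam-tracking experiment in
#' simulation: a spherical target (radius about 30 mm) moves on a 1-D trace
#' inside the field of view; cine frames are rendered, degraded by k-space
#' truncation to the real-time matrix size, optionally up-sampled, and
#' template-matched; the displacement drives a velocity-limited MLC
#' aperture after the imaging-chain delays. End-to-end latency is the phase
#' shift between sinusoid fits to target and aperture traces; geometric
#' error is the RMSE between the traces, reported raw and after removing
#' the measured latency.
#' @name tracking_sim
NULL

#' Time-stamped 1-D displacement trace
#'
#' @param t strictly increasing timestamps in seconds.
#' @param x displacements in mm, same length as `t`.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(t, x) {
  stopifnot(length(t) == length(x), length(t) >= 2,
            all(is.finite(t)), all(is.finite(x)), all(diff(t) > 0))
  structure(list(t = as.numeric(t), x = as.numeric(x)), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d samples over %.3g s (~%.3g Hz), x in [%.3g, %.3g] mm\n",
              length(x$t), diff(range(x$t)),
              (length(x$t) - 1) / diff(range(x$t)), min(x$x), max(x$x)))
  invisible(x)
}

#' Sinusoidal phantom trace
#'
#' `x(t) = A sin(2 pi f t + phase)`, sampled at `rate` Hz; used to measure
#' latency as a phase shift.
#'
#' @param amplitude amplitude A in mm.
#' @param frequency frequency f in Hz; `rate` must exceed `2 * frequency`.
#' @param duration duration in seconds.
#' @param rate sampling rate in Hz.
#' @param phase phase offset in radians.
#' @return A `motion_trace`.
#' @export
gen_sinusoid_trace <- function(amplitude = 10, frequency = 0.25, duration = 30,
                               rate = 4, phase = 0) {
  if (rate <= 2 * frequency)
    stop("sampling rate must exceed twice the frequency (aliasing)", call. = FALSE)
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  motion_trace(t, amplitude * sin(2 * pi * frequency * t + phase))
}

#' Quasi-periodic breathing-like trace
#'
#' A statistical surrogate for a patient breathing trace: cycle-by-cycle
#' amplitude and period jitter plus a slow baseline drift (random walk at
#' cycle boundaries, linearly interpolated). With zero jitter and zero
#' drift it reduces exactly to [gen_sinusoid_trace()].
#'
#' @param seed RNG seed.
#' @param duration,rate duration (s) and sampling rate (Hz).
#' @param period mean breathing period in seconds (default 4).
#' @param amplitude mean amplitude in mm (default 10).
#' @param jitter_amp,jitter_period relative per-cycle sd of amplitude and
#'   period.
#' @param drift_sd baseline drift per cycle in mm (random-walk step sd).
#' @return A `motion_trace`.
#' @export
gen_breathing_trace <- function(seed = 1L, duration = 60, rate = 4,
                                period = 4, amplitude = 10,
                                jitter_amp = 0.15, jitter_period = 0.08,
                                drift_sd = 0.5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  n_cyc <- ceiling(duration / period) + 2L
  periods <- pmax(period * (1 + jitter_period * stats::rnorm(n_cyc)), period / 4)
  amps <- pmax(amplitude * (1 + jitter_amp * stats::rnorm(n_cyc)), 0)
  drift <- c(0, cumsum(stats::rnorm(n_cyc, 0, drift_sd)))
  bounds <- c(0, cumsum(periods))
  cyc <- findInterval(t, bounds, rightmost.closed = FALSE)
  cyc <- pmin(pmax(cyc, 1L), n_cyc)
  phase_in <- (t - bounds[cyc]) / periods[cyc]
  x <- amps[cyc] * sin(2 * pi * phase_in)
  dr <- stats::approx(bounds, drift[seq_along(bounds)], xout = t, rule = 2)$y
  motion_trace(t, x + dr)
}

#' Geometry and intensities of the moving-sphere phantom
#'
#' @param target_radius sphere radius in mm (default 30, the motion-phantom
#'   target).
#' @param image_fov field of view in mm (default 400).
#' @param matrix_lr,matrix_hr real-time and target matrix sizes (64 / 256).
#' @param target_intensity,background disc and background intensities.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(target_radius = 30, image_fov = 400,
                         matrix_lr = 64, matrix_hr = 256,
                         target_intensity = 3000, background = 200,
                         noise_sd = 0) {
  stopifnot(target_radius > 0, target_radius < image_fov / 2,
            matrix_lr >= 8, matrix_hr %% matrix_lr == 0,
            target_intensity >= 0, background >= 0, noise_sd >= 0)
  structure(list(target_radius = target_radius, image_fov = image_fov,
                 matrix_lr = as.integer(matrix_lr),
                 matrix_hr = as.integer(matrix_hr),
                 target_intensity = target_intensity, background = background,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Imaging-chain timing
#'
#' Frame period of the real-time acquisition (0.25 s for 4 Hz cine), the
#' per-stage processing delays, and the EPID sampling rate used to record
#' target and aperture traces.
#'
#' @param frame_period s per frame (default 0.25).
#' @param recon_delay,sr_delay,tracking_delay,mlc_delay stage delays in s.
#' @param epid_rate EPID sampling rate in Hz (default 3.6).
#' @return An object of class `chain_timing`.
#' @export
chain_timing <- function(frame_period = 0.25, recon_delay = 0.1,
                         sr_delay = 0.005, tracking_delay = 0.06,
                         mlc_delay = 0.06, epid_rate = 3.6) {
  stopifnot(frame_period > 0, recon_delay >= 0, sr_delay >= 0,
            tracking_delay >= 0, mlc_delay >= 0, epid_rate > 0)
  structure(list(frame_period = frame_period, recon_delay = recon_delay,
                 sr_delay = sr_delay, tracking_delay = tracking_delay,
                 mlc_delay = mlc_delay, epid_rate = epid_rate),
            class = "chain_timing")
}

#' MLC aperture dynamics
#'
#' The leaf bank is abstracted to a single aperture centroid moving toward
#' the commanded position at a bounded velocity (25 mm/s at isocentre by
#' default) updated at `control_rate`.
#'
#' @param max_leaf_velocity mm/s (default 25).
#' @param control_rate control-loop rate in Hz (default 50).
#' @return An object of class `mlc_spec`.
#' @export
mlc_spec <- function(max_leaf_velocity = 25, control_rate = 50) {
  stopifnot(max_leaf_velocity > 0, control_rate > 0)
  structure(list(max_leaf_velocity = max_leaf_velocity,
                 control_rate = control_rate), class = "mlc_spec")
}

#' Render one cine frame of the moving sphere
#'
#' The sphere's central cross-section (a disc) is drawn at the displaced
#' centre along the motion (column) axis with linear partial-volume
#' anti-aliasing over one pixel, plus optional additive Gaussian noise
#' (clamped at zero, magnitude-image convention).
#'
#' @param spec a [phantom_spec()].
#' @param displacement target displacement in mm along the motion axis.
#' @param matrix matrix size to render (default `spec$matrix_hr`).
#' @param noise_sd noise sd override (default from `spec`).
#' @return A `gray_image` with spacing `image_fov / matrix` mm.
#' @export
render_frame <- function(spec, displacement, matrix = spec$matrix_hr,
                         noise_sd = spec$noise_sd) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (abs(displacement) + spec$target_radius >= spec$image_fov / 2)
    stop("target leaves the field of view", call. = FALSE)
  n <- as.integer(matrix)
  sp <- spec$image_fov / n
  coord <- (seq_len(n) - (n + 1) / 2) * sp
  dr <- matrix(coord, n, n)                     # row offsets (mm)
  dc <- matrix(coord - displacement, n, n, byrow = TRUE)
  dist <- sqrt(dr^2 + dc^2)
  cov <- pmin(pmax(0.5 + (spec$target_radius - dist) / sp, 0), 1)
  px <- spec$background + (spec$target_intensity - spec$background) * cov
  if (noise_sd > 0)
    px <- pmax(px + stats::rnorm(n * n, 0, noise_sd), 0)
  gray_image(px, spacing = sp)
}

# integral-image local sums over h x w windows; returns (H-h+1) x (W-w+1)
window_sums <- function(m, h, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed double cumsum
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  H <- nrow(m)
  W <- ncol(m)
  r2 <- (h + 1):(H + 1)
  c2 <- (w + 1):(W + 1)
  cs[r2, c2] - cs[r2 - h, c2] - cs[r2, c2 - w] + cs[r2 - h, c2 - w]
}

#' Locate a target by normalised cross-correlation template matching
#'
#' The template is slid over all valid placements; the NCC peak gives the
#' target position, optionally refined to sub-pixel precision by a
#' parabolic fit of the 3 x 3 correlation neighbourhood. The displacement
#' is reported in mm relative to a stored reference placement.
#'
#' @param frame a `gray_image`.
#' @param template a `gray_image` strictly smaller than `frame`, same pixel
#'   spacing.
#' @param ref_pos reference top-left placement (row, col, 1-based); default
#'   the centred placement.
#' @param subpixel parabolic sub-pixel refinement (default `TRUE`).
#' @param threshold minimum peak NCC; below it the target is declared lost.
#' @return list with `displacement` (mm, c(row, col)), `peak` (NCC value),
#'   `position` (placement, possibly fractional) and `lost`.
#' @export
template_match <- function(frame, template, ref_pos = NULL, subpixel = TRUE,
                           threshold = 0.5) {
  frame <- as_gray_image(frame)
  template <- as_gray_image(template)
  Fm <- frame$pixels
  Tm <- template$pixels
  H <- nrow(Fm); W <- ncol(Fm)
  h <- nrow(Tm); w <- ncol(Tm)
  if (h >= H || w >= W) stop("template must be smaller than the frame", call. = FALSE)
  nT <- h * w
  Tbar <- mean(Tm)
  Tss <- sum((Tm - Tbar)^2)
  if (Tss == 0) stop("constant template", call. = FALSE)
  # cross term by FFT correlation with the zero-mean template
  Tz <- matrix(0, H, W)
  Tz[1:h, 1:w] <- Tm - Tbar
  cross <- Re(stats::fft(stats::fft(Fm) * Conj(stats::fft(Tz)), inverse = TRUE)) / (H * W)
  cross <- cross[1:(H - h + 1), 1:(W - w + 1), drop = FALSE]
  S1 <- window_sums(Fm, h, w)
  S2 <- window_sums(Fm^2, h, w)
  varF <- pmax(S2 - S1^2 / nT, 0)
  ncc <- cross / sqrt(varF * Tss)
  ncc[varF <= 1e-12] <- 0
  pk <- arrayInd(which.max(ncc), dim(ncc))
  peak <- ncc[pk]
  if (!is.finite(peak) || peak < threshold)
    return(list(displacement = c(NA_real_, NA_real_), peak = peak,
                position = c(NA_real_, NA_real_), lost = TRUE))
  pos <- as.numeric(pk)
  if (subpixel) {
    for (ax in 1:2) {
      i <- pk[ax]
      if (i > 1 && i < dim(ncc)[ax]) {
        tri <- if (ax == 1) ncc[(i - 1):(i + 1), pk[2]] else ncc[pk[1], (i - 1):(i + 1)]
        den <- tri[1] - 2 * tri[2] + tri[3]
        if (den < 0) pos[ax] <- i + 0.5 * (tri[1] - tri[3]) / den
      }
    }
  }
  if (is.null(ref_pos))
    ref_pos <- c((H - h) / 2 + 1, (W - w) / 2 + 1)
  disp <- (pos - ref_pos) * frame$spacing
  list(displacement = disp, peak = peak, position = pos, lost = FALSE)
}

#' Rate-limited MLC aperture response
#'
#' Moves the aperture toward the commanded position by at most
#' `max_leaf_velocity * dt`, arriving exactly when within reach.
#'
#' @param commanded commanded position (mm).
#' @param state current aperture position (mm).
#' @param spec an [mlc_spec()].
#' @param dt time step in seconds (> 0).
#' @return New aperture position (mm).
#' @export
mlc_respond <- function(commanded, state, spec, dt) {
  stopifnot(dt > 0)
  step <- spec$max_leaf_velocity * dt
  state + pmin(pmax(commanded - state, -step), step)
}

#' Run the simulated frame -> SR -> tracking -> MLC chain
#'
#' Cine frames of the moving sphere are rendered at the high-resolution
#' matrix at each frame's mid-exposure target position, degraded by
#' k-space truncation to `track_matrix` (the real-time matrix), optionally
#' up-sampled by `sr_method` (x4), and template-matched against a reference
#' template built through the identical imaging path. The matched
#' displacement is commanded to the rate-limited aperture once the frame's
#' stage delays have elapsed, and held until the next frame (zero-order
#' hold). Under the mid-exposure convention the injected end-to-end latency
#' is `frame_period / 2 + recon + sr + tracking + mlc` delays (the hold
#' contributes the half frame period on average). Both traces are resampled
#' at the EPID rate.
#'
#' @param trace target `motion_trace` covering the run.
#' @param spec a [phantom_spec()].
#' @param timing a [chain_timing()].
#' @param mlc an [mlc_spec()].
#' @param sr_method one of `"none"`, `"nearest"`, `"bicubic"`, `"model"`.
#' @param model an `edsr` model, required for `sr_method = "model"`.
#' @param track_matrix matrix size the degraded real-time frames are
#'   tracked on when `sr_method = "none"` (default `spec$matrix_lr`).
#' @param seed seed for rendering noise.
#' @param subpixel sub-pixel refinement inside the chain (default `FALSE`:
#'   the deployed tracker reports pixel-grid positions, so displacement is
#'   quantised at the tracking pixel pitch).
#' @param settle start-up transient discarded from the recorded traces, in
#'   seconds (default 2; the aperture starts at rest before the first
#'   command arrives).
#' @return list with `target` and `aperture` (`motion_trace`s at the EPID
#'   rate), `displacements` (per-frame matched displacement, mm),
#'   `n_lost`, `nominal_latency` (s) and `track_spacing` (mm).
#' @export
run_chain <- function(trace, spec, timing, mlc, sr_method = "none",
                      model = NULL, track_matrix = NULL, seed = 1L,
                      subpixel = FALSE, settle = 2) {
  stopifnot(inherits(trace, "motion_trace"), inherits(spec, "phantom_spec"),
            inherits(timing, "chain_timing"), inherits(mlc, "mlc_spec"))
  sr_method <- match.arg(sr_method, c("none", "nearest", "bicubic", "model"))
  if (sr_method == "model" && !inherits(model, "edsr"))
    stop("`model` must be supplied for sr_method = \"model\"", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (is.null(track_matrix))
    track_matrix <- if (sr_method == "none") spec$matrix_lr else spec$matrix_lr
  factor_down <- spec$matrix_hr / track_matrix
  if (factor_down != round(factor_down))
    stop("matrix_hr must be a multiple of track_matrix", call. = FALSE)
  up <- spec$matrix_hr / spec$matrix_lr  # up-sampling factor for SR methods

  process <- function(hr_frame) {
    if (sr_method == "none")
      return(if (factor_down > 1) kspace_downsample(hr_frame, factor_down) else hr_frame)
    lr <- kspace_downsample(hr_frame, up)
    switch(sr_method,
           nearest = upsample_nearest(lr, up),
           bicubic = upsample_bicubic(lr, up),
           model = forward_sr(model, lr))
  }

  # reference template through the identical imaging path, noiseless
  ref_img <- process(render_frame(spec, 0, spec$matrix_hr, noise_sd = 0))
  tsp <- ref_img$spacing[2]
  half <- ceiling((spec$target_radius + 8) / tsp)
  nref <- nrow(ref_img$pixels)
  ctr <- (nref + 1) / 2
  ri <- max(1, floor(ctr - half)):min(nref, ceiling(ctr + half))
  tmpl <- gray_image(ref_img$pixels[ri, ri], spacing = ref_img$spacing)
  ref_pos <- c(ri[1], ri[1])

  T <- timing$frame_period
  D <- timing$recon_delay + timing$sr_delay + timing$tracking_delay +
    timing$mlc_delay
  t0 <- trace$t[1]
  t_end <- trace$t[length(trace$t)]
  frame_t <- seq(t0, t_end - T, by = T)
  content_t <- frame_t + T / 2
  xc <- stats::approx(trace$t, trace$x, xout = content_t, rule = 2)$y

  disp <- numeric(length(frame_t))
  n_lost <- 0L
  last <- 0
  for (k in seq_along(frame_t)) {
    fr <- process(render_frame(spec, xc[k], spec$matrix_hr))
    tm <- template_match(fr, tmpl, ref_pos = ref_pos, subpixel = subpixel)
    if (tm$lost) {
      n_lost <- n_lost + 1L
      disp[k] <- last
    } else {
      disp[k] <- tm$displacement[2]   # motion (column) axis
      last <- disp[k]
    }
  }
  activate_t <- content_t + D

  dt <- 1 / mlc$control_rate
  ctrl_t <- seq(t0, t_end, by = dt)
  cmd_idx <- findInterval(ctrl_t, activate_t)
  ap <- numeric(length(ctrl_t))
  pos <- 0
  for (i in seq_along(ctrl_t)) {
    cmd <- if (cmd_idx[i] >= 1) disp[cmd_idx[i]] else 0
    pos <- mlc_respond(cmd, pos, mlc, dt)
    ap[i] <- pos
  }

  epid_t <- seq(t0 + settle, t_end, by = 1 / timing$epid_rate)
  target <- motion_trace(epid_t, stats::approx(trace$t, trace$x, xout = epid_t,
                                               rule = 2)$y)
  aperture <- motion_trace(epid_t, stats::approx(ctrl_t, ap, xout = epid_t,
                                                 rule = 2)$y)
  list(target = target, aperture = aperture, displacements = disp,
       n_lost = n_lost, nominal_latency = T / 2 + D, track_spacing = tsp)
}

# least-squares sinusoid fit; if f is NULL it is estimated (FFT peak then
# refined); returns A, f, phi, offset, r2
fit_sinusoid <- function(t, x, f = NULL) {
  lsq <- function(f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
    cf <- stats::lm.fit(X, x)$coefficients
    res <- x - X %*% cf
    list(coef = cf, rss = sum(res^2))
  }
  if (is.null(f)) {
    dtm <- stats::median(diff(t))
    xd <- x - mean(x)
    n <- length(xd)
    pw <- Mod(stats::fft(xd))[1:floor(n / 2)]
    pk <- which.max(pw[-1]) + 1L          # skip DC
    f0 <- (pk - 1) / (n * dtm)
    # RSS(f) is multimodal: dense grid around the spectral peak, then a
    # bracketed polish one grid step either side of the best point
    grid <- seq(max(f0 * 0.7, 1e-4), f0 * 1.3, length.out = 200)
    rss <- vapply(grid, function(ff) lsq(ff)$rss, 0)
    i <- which.min(rss)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    f <- stats::optimize(function(ff) lsq(ff)$rss, interval = c(lo, hi))$minimum
  }
  ft <- lsq(f)
  a <- unname(ft$coef[1])
  b <- unname(ft$coef[2])
  list(A = sqrt(a^2 + b^2), f = f, phi = atan2(b, a), offset = unname(ft$coef[3]),
       r2 = 1 - ft$rss / sum((x - mean(x))^2))
}

#' Estimate end-to-end latency as a sinusoid phase shift
#'
#' A sinusoid (amplitude, frequency, phase, offset) is least-squares fitted
#' to the target trace; a second sinusoid with the frequency fixed from the
#' target fit is fitted to the aperture trace. The latency is the phase
#' difference converted to time and wrapped into `[0, 1/f)`.
#'
#' @param target,aperture `motion_trace`s overlapping in time; the target
#'   must be approximately sinusoidal.
#' @return Latency in seconds.
#' @export
estimate_latency <- function(target, aperture) {
  stopifnot(inherits(target, "motion_trace"), inherits(aperture, "motion_trace"))
  if (max(target$t) < min(aperture$t) || max(aperture$t) < min(target$t))
    stop("traces do not overlap in time", call. = FALSE)
  ft <- fit_sinusoid(target$t, target$x)
  if (ft$r2 < 0.5)
    stop("target trace is not approximately sinusoidal (fit residual > 50% of variance)",
         call. = FALSE)
  fa <- fit_sinusoid(aperture$t, aperture$x, f = ft$f)
  lag <- (ft$phi - fa$phi) / (2 * pi * ft$f)
  lag %% (1 / ft$f)
}

#' Geometric tracking error (RMSE between traces)
#'
#' The aperture trace is linearly interpolated onto the target timestamps
#' over their temporal overlap; the root mean-square difference is
#' returned in mm.
#'
#' @param target,aperture `motion_trace`s with temporal overlap.
#' @return RMSE in mm.
#' @export
geometric_error <- function(target, aperture) {
  stopifnot(inherits(target, "motion_trace"), inherits(aperture, "motion_trace"))
  keep <- target$t >= min(aperture$t) & target$t <= max(aperture$t)
  if (!any(keep)) stop("traces do not overlap in time", call. = FALSE)
  ai <- stats::approx(aperture$t, aperture$x, xout = target$t[keep])$y
  sqrt(mean((target$x[keep] - ai)^2))
}

#' Latency-corrected geometric error
#'
#' The aperture timestamps are advanced by the measured latency (removing
#' the pure-delay component) before computing [geometric_error()]; for an
#' aperture that is exactly a delayed copy of the target the corrected
#' error vanishes up to interpolation.
#'
#' @param target,aperture `motion_trace`s.
#' @param latency measured end-to-end latency in seconds (>= 0).
#' @return RMSE in mm after latency removal.
#' @export
latency_corrected_error <- function(target, aperture, latency) {
  stopifnot(latency >= 0)
  shifted <- motion_trace(aperture$t - latency, aperture$x)
  keep <- target$t >= min(shifted$t) & target$t <= max(shifted$t)
  if (!any(keep)) stop("latency shift leaves no temporal overlap", call. = FALSE)
  geometric_error(target, shifted)
}

#' Latency/error experiment over up-sampling methods
#'
#' For each method, sinusoid runs measure the end-to-end latency and
#' breathing-trace runs measure the geometric RMSE and latency-corrected
#' RMSE, each repeated `n_repeats` times (deterministic per seed).
#'
#' @param sr_methods character vector of chain methods
#'   (`"none"`, `"nearest"`, `"bicubic"`, `"model"`).
#' @param spec,timing,mlc chain components (defaults as in the phantom
#'   experiment).
#' @param model optional `edsr` for `"model"`.
#' @param n_repeats repeats per method and trace type (default 3).
#' @param seed base seed; repeat r of method m uses distinct derived seeds.
#' @param sin_amplitude,sin_frequency sinusoid parameters (mm, Hz).
#' @param duration run length in seconds.
#' @return An object of class `tracking_report`: per-repeat long table and
#'   a per-method summary (mean and sd of latency, RMSE, corrected RMSE).
#' @export
experiment_suite <- function(sr_methods = c("none", "bicubic"),
                             spec = phantom_spec(), timing = chain_timing(),
                             mlc = mlc_spec(), model = NULL, n_repeats = 3,
                             seed = 1L, sin_amplitude = 10,
                             sin_frequency = 0.25, duration = 24) {
  rows <- list()
  for (m in seq_along(sr_methods)) {
    meth <- sr_methods[m]
    for (r in seq_len(n_repeats)) {
      sd1 <- seed + 1000L * m + r
      sin_tr <- gen_sinusoid_trace(sin_amplitude, sin_frequency, duration,
                                   rate = 8 / timing$frame_period)
      ch <- run_chain(sin_tr, spec, timing, mlc, sr_method = meth,
                      model = model, seed = sd1)
      lat <- estimate_latency(ch$target, ch$aperture)
      br <- gen_breathing_trace(seed = sd1 + 500L, duration = duration,
                                rate = 8 / timing$frame_period)
      chb <- run_chain(br, spec, timing, mlc, sr_method = meth,
                       model = model, seed = sd1 + 1L)
      rmse <- geometric_error(chb$target, chb$aperture)
      corr <- latency_corrected_error(chb$target, chb$aperture, lat)
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth, repeat_i = r, latency = lat,
                   rmse = rmse, rmse_latency_corrected = corr)
    }
  }
  long <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(long, long$method), function(d)
    data.frame(method = d$method[1], n_repeats = nrow(d),
               latency_mean = mean(d$latency), latency_sd = stats::sd(d$latency),
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
               rmse_corr_mean = mean(d$rmse_latency_corrected),
               rmse_corr_sd = stats::sd(d$rmse_latency_corrected))))
  rownames(summ) <- NULL
  summ <- summ[match(unique(long$method), summ$method), ]
  structure(list(repeats = long, summary = summ), class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat("<tracking_report>\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s latency %.3f +/- %.3f s, RMSE %.2f +/- %.2f mm, corrected %.2f +/- %.2f mm\n",
                s$method[i], s$latency_mean[i], s$latency_sd[i],
                s$rmse_mean[i], s$rmse_sd[i],
                s$rmse_corr_mean[i], s$rmse_corr_sd[i]))
  invisible(x)
}

#' Write a motion trace to CSV / read one back
#'
#' @param trace a `motion_trace`.
#' @param path CSV path with columns `t`, `x`.
#' @return `write_trace`: `path` invisibly; `read_trace`: a `motion_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  utils::write.csv(data.frame(t = trace$t, x = trace$x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  motion_trace(d$t, d$x)
}
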