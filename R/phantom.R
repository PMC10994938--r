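#' @title Synthetic brain-like phantoms and cine fixtures
#'
#' @description Deterministic generators that stand in for anatomical
#' training and test data: 2-D ellipse composites with fine curvilinear
#' structure (edge content for the edge-weighted loss), three contrast
#' palettes emulating T1-like / T2-like / FLAIR-like sequences, and cine
#' series of the moving-sphere phantom. They provide analytic ground truth
#' (masks, centroids) at desk scale; they do not mimic field-strength
#' contrast, coil sensitivity or banding artifacts.
#' @name synthetic_data
NULL

#' Recipe for one anatomy-like phantom
#'
#' @param seed RNG seed; generation is pure given the seed.
#' @param matrix matrix size (>= 32, default 256).
#' @param n_ellipses internal structures (default 6).
#' @param contrast one of `"t1"`, `"t2"`, `"flair"` intensity palettes.
#' @param fine_density number of thin annuli / stripe systems (default 3).
#' @param intensity_max top of the intensity range (default 4096).
#' @return An object of class `phantom_recipe`.
#' @export
phantom_recipe <- function(seed = 1L, matrix = 256, n_ellipses = 6,
                           contrast = c("t1", "t2", "flair"),
                           fine_density = 3, intensity_max = 4096) {
  contrast <- match.arg(contrast)
  stopifnot(matrix >= 32, n_ellipses >= 1, fine_density >= 0,
            intensity_max > 0)
  structure(list(seed = as.integer(seed), matrix = as.integer(matrix),
                 n_ellipses = as.integer(n_ellipses), contrast = contrast,
                 fine_density = as.integer(fine_density),
                 intensity_max = intensity_max),
            class = "phantom_recipe")
}

# soft indicator of an ellipse, anti-aliased over `aa` normalised units
ellipse_soft <- function(u, v, cx, cy, ax, ay, ang, aa) {
  ca <- cos(ang); sa <- sin(ang)
  ur <- (u - cx) * ca + (v - cy) * sa
  vr <- -(u - cx) * sa + (v - cy) * ca
  d <- sqrt((ur / ax)^2 + (vr / ay)^2)
  pmin(pmax((1 - d) / aa + 0.5, 0), 1)
}

#' Generate one brain-like phantom image
#'
#' Nested anti-aliased ellipses inside a head outline, thin elliptical
#' annuli and oriented sinusoidal stripes supplying high-spatial-frequency
#' edge content, and mild smooth texture; intensities lie in
#' `[0, intensity_max]`.
#'
#' @param recipe a [phantom_recipe()].
#' @return A `gray_image` (spacing 400/matrix mm, a thorax-like FOV).
#' @export
gen_anatomy_phantom <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(recipe$seed)
  n <- recipe$matrix
  aa <- 2 / n  # one-pixel anti-aliasing in normalised units
  u <- matrix(seq(-1, 1, length.out = n), n, n)
  v <- t(u)
  pal <- switch(recipe$contrast,
                t1 = list(head = 0.55, inner = c(0.25, 0.95), ring = 0.85, stripe = 0.30),
                t2 = list(head = 0.35, inner = c(0.45, 1.00), ring = 0.95, stripe = 0.40),
                flair = list(head = 0.45, inner = c(0.15, 0.80), ring = 0.70, stripe = 0.35))
  head_ax <- stats::runif(1, 0.62, 0.72)
  head_ay <- stats::runif(1, 0.72, 0.85)
  head <- ellipse_soft(u, v, 0, 0, head_ax, head_ay, stats::runif(1, -0.3, 0.3), aa)
  img <- pal$head * head
  for (k in seq_len(recipe$n_ellipses)) {
    cx <- stats::runif(1, -0.35, 0.35)
    cy <- stats::runif(1, -0.45, 0.45)
    ax <- stats::runif(1, 0.05, 0.28)
    ay <- stats::runif(1, 0.05, 0.28)
    lvl <- stats::runif(1, pal$inner[1], pal$inner[2])
    e <- ellipse_soft(u, v, cx, cy, ax, ay, stats::runif(1, 0, pi), aa)
    img <- img * (1 - e) + lvl * e * head
  }
  for (k in seq_len(recipe$fine_density)) {
    # thin annulus: |ellipse distance - 1| < width
    cx <- stats::runif(1, -0.25, 0.25)
    cy <- stats::runif(1, -0.3, 0.3)
    ax <- stats::runif(1, 0.15, 0.5)
    ay <- stats::runif(1, 0.15, 0.5)
    ang <- stats::runif(1, 0, pi)
    ca <- cos(ang); sa <- sin(ang)
    ur <- (u - cx) * ca + (v - cy) * sa
    vr <- -(u - cx) * sa + (v - cy) * ca
    d <- sqrt((ur / ax)^2 + (vr / ay)^2)
    wdt <- stats::runif(1, 1.5, 3) / n
    ring <- pmin(pmax((wdt - abs(d - 1)) / aa + 0.5, 0), 1)
    img <- pmax(img, pal$ring * ring * head)
    # oriented fine stripes inside a lobe
    lob <- ellipse_soft(u, v, -cx, -cy, ax * 0.8, ay * 0.8, ang, aa)
    fr <- stats::runif(1, 18, 34)
    ph <- stats::runif(1, 0, 2 * pi)
    stripes <- 0.5 + 0.5 * sin(fr * pi * (u * ca + v * sa) + ph)
    img <- img + pal$stripe * 0.35 * (stripes - 0.5) * lob * head
  }
  # mild smooth texture: low-resolution noise bilinearly up-sampled
  nl <- max(8L, n %/% 16L)
  tex <- matrix(stats::rnorm(nl * nl), nl, nl)
  texi <- upsample_bicubic(gray_image(tex, 1), n %/% nl)$pixels
  texi <- texi[seq_len(n), seq_len(n)]
  img <- img * (1 + 0.03 * texi)
  img <- pmin(pmax(img, 0), 1) * recipe$intensity_max
  gray_image(img, spacing = 400 / n)
}

#' Generate a set of distinct multi-contrast labels
#'
#' Phantoms are emitted round-robin across the three contrast palettes
#' (uniform mixing emulates multi-sequence training sets) with per-image
#' seeds derived from `seed`.
#'
#' @param n number of labels.
#' @param seed base seed.
#' @param matrix matrix size (default 256).
#' @return list of `n` `gray_image`s.
#' @export
gen_label_set <- function(n, seed = 1L, matrix = 256) {
  stopifnot(n >= 1)
  contrasts <- c("t1", "t2", "flair")
  lapply(seq_len(n), function(i)
    gen_anatomy_phantom(phantom_recipe(seed = seed * 10000L + i,
                                       matrix = matrix,
                                       contrast = contrasts[(i - 1L) %% 3L + 1L])))
}

#' Render a cine series of the moving sphere along a trace
#'
#' One frame per trace sample, timestamps attached; deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @param trace a `motion_trace`.
#' @param seed seed for the per-frame noise.
#' @param matrix matrix to render (default `spec$matrix_hr`).
#' @return list with `frames` (list of `gray_image`) and `t` (timestamps).
#' @export
gen_cine <- function(spec, trace, seed = 1L, matrix = spec$matrix_hr) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(trace, "motion_trace"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- lapply(trace$x, function(d) render_frame(spec, d, matrix))
  list(frames = frames, t = trace$t)
}
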