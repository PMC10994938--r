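# Conventional up-sampling baselines. The bicubic dialect is pinned to the
# Catmull-Rom kernel (a = -0.5) on a half-pixel-centre grid (aligned corners
# off) so that tests have one normative definition; library bicubics differ.

catmull_rom <- function(t) {
  a <- -0.5
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

# (n_in * f) x n_in interpolation matrix for one axis, border replicated
bicubic_axis_matrix <- function(n_in, f) {
  n_out <- n_in * f
  # output centre i (0-based) lands at source coordinate (i + 0.5)/f - 0.5
  s <- (seq_len(n_out) - 0.5) / f - 0.5
  base <- floor(s)
  M <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k + 1, 1), n_in)  # 1-based, clamped
    w <- catmull_rom(s - (base + k))
    M[cbind(seq_len(n_out), idx)] <- M[cbind(seq_len(n_out), idx)] + w
  }
  M
}

#' Bicubic up-sampling baseline
#'
#' Separable cubic interpolation with the Catmull-Rom kernel (a = -0.5),
#' half-pixel output centres and replicated borders. Reproduces constants and
#' linear ramps (away from borders) exactly; field of view is preserved.
#'
#' @param img a `gray_image`.
#' @param factor integer up-sampling factor (2 or 4 in normal use).
#' @return A `gray_image` of size `dim(img) * factor`, spacing divided by
#'   `factor`.
#' @export
upsample_bicubic <- function(img, factor) {
  img <- as_gray_image(img)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(img)
  d <- dim(img$pixels)
  Mr <- bicubic_axis_matrix(d[1], factor)
  Mc <- bicubic_axis_matrix(d[2], factor)
  gray_image(Mr %*% img$pixels %*% t(Mc), spacing = img$spacing / factor)
}

#' Nearest-neighbour up-sampling baseline
#'
#' Each source pixel is replicated into a `factor` x `factor` block; this is
#' the "no up-sampling" reference that simply re-grids the low-resolution
#' input.
#'
#' @inheritParams upsample_bicubic
#' @return A `gray_image` of size `dim(img) * factor`.
#' @export
upsample_nearest <- function(img, factor) {
  img <- as_gray_image(img)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(img)
  d <- dim(img$pixels)
  px <- img$pixels[rep(seq_len(d[1]), each = factor),
                   rep(seq_len(d[2]), each = factor)]
  gray_image(px, spacing = img$spacing / factor)
}
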