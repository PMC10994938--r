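#' @title Centered orthonormal 2D Fourier transforms and k-space degradation
#'
#' @description MRI acquires data in the spatial-frequency domain (k-space),
#' whose centre carries the coarse image content. Cropping the central block
#' of a high-resolution image's spectrum and inverse-transforming synthesises
#' a low-resolution image with the degradation real undersampled acquisitions
#' exhibit (loss of edges and fine texture), which is how paired
#' low/high-resolution training data are built here.
#'
#' Conventions: transforms are orthonormal (unitary), so a round trip is the
#' identity and Parseval holds without scale factors; after the centre shift
#' the DC coefficient sits at 0-based index `floor(N/2)` per axis (1-based
#' `floor(N/2) + 1`), which keeps DC inside every centred crop for even and
#' odd sizes alike.
#' @name kspace
NULL

fftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq.int(d[1] - floor(d[1] / 2) + 1L, d[1]), seq.int(1L, d[1] - floor(d[1] / 2)))
  j <- c(seq.int(d[2] - floor(d[2] / 2) + 1L, d[2]), seq.int(1L, d[2] - floor(d[2] / 2)))
  m[i, j, drop = FALSE]
}

ifftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq.int(floor(d[1] / 2) + 1L, d[1]), seq.int(1L, floor(d[1] / 2)))
  j <- c(seq.int(floor(d[2] / 2) + 1L, d[2]), seq.int(1L, floor(d[2] / 2)))
  m[i, j, drop = FALSE]
}

#' Centered orthonormal 2D FFT of an image
#'
#' @param img a `gray_image` (or 2D matrix).
#' @return An object of class `spectrum2d`: complex coefficient grid with DC
#'   at 0-based index `floor(N/2)` per axis, plus the source shape and pixel
#'   spacing.
#' @seealso [ifft_centered()], [kspace_downsample()]
#' @examples
#' sp <- fft_centered(gray_image(matrix(3, 8, 8)))
#' Mod(sp$coeffs[5, 5])  # DC of a constant image: 8 * 3
#' @export
fft_centered <- function(img) {
  img <- as_gray_image(img)
  x <- img$pixels
  co <- fftshift2(stats::fft(x) / sqrt(length(x)))
  structure(list(coeffs = co, source_shape = dim(x), spacing = img$spacing),
            class = "spectrum2d")
}

#' Inverse of the centered orthonormal 2D FFT
#'
#' @param spec a `spectrum2d`.
#' @param magnitude return the complex modulus (default; MRI magnitude
#'   convention, guarantees nonnegativity) rather than the real part.
#' @return A `gray_image`.
#' @export
ifft_centered <- function(spec, magnitude = TRUE) {
  stopifnot(inherits(spec, "spectrum2d"))
  co <- ifftshift2(spec$coeffs)
  x <- stats::fft(co, inverse = TRUE) / sqrt(length(co))
  px <- if (magnitude) Mod(x) else Re(x)
  gray_image(px, spacing = spec$spacing)
}

#' @export
print.spectrum2d <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<spectrum2d> %d x %d, DC at (%d, %d) [1-based]\n",
              d[1], d[2], floor(d[1] / 2) + 1L, floor(d[2] / 2) + 1L))
  invisible(x)
}

#' Synthesise a low-resolution image by k-space truncation
#'
#' Transforms the image to k-space, keeps the central
#' `[floor(N/2) - floor(M/2), floor(N/2) + ceiling(M/2))` block per axis
#' (M = N / factor), rescales the retained coefficients by
#' `sqrt(prod(M) / prod(N))` so a constant image maps to the same constant
#' (keeping low- and high-resolution pairs on one intensity scale), and
#' reconstructs the magnitude image. The field of view is preserved: pixel
#' spacing grows by `factor`.
#'
#' @param img a `gray_image` with both dimensions divisible by `factor`.
#' @param factor integer down-sampling factor (>= 1).
#' @return A `gray_image` of size `dim(img) / factor` and spacing
#'   `spacing * factor`.
#' @examples
#' hr <- gray_image(matrix(100, 256, 256), spacing = 400 / 256)
#' lr <- kspace_downsample(hr, 4)
#' dim(lr); lr$spacing  # 64 x 64 at 6.25 mm
#' @export
kspace_downsample <- function(img, factor) {
  img <- as_gray_image(img)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  d <- dim(img$pixels)
  if (any(d %% factor != 0L))
    stop(sprintf("image shape %d x %d not divisible by factor %d",
                 d[1], d[2], factor), call. = FALSE)
  if (factor == 1L) return(img)
  m <- d %/% factor
  spec <- fft_centered(img)
  ctr <- floor(d / 2)
  i <- seq.int(ctr[1] - floor(m[1] / 2) + 1L, length.out = m[1])
  j <- seq.int(ctr[2] - floor(m[2] / 2) + 1L, length.out = m[2])
  crop <- spec$coeffs[i, j, drop = FALSE] * sqrt(prod(m) / prod(d))
  sub <- structure(list(coeffs = crop, source_shape = m,
                        spacing = img$spacing * factor),
                   class = "spectrum2d")
  ifft_centered(sub, magnitude = TRUE)
}

#' Zero pad an image up to a target matrix size
#'
#' The source pixels are centred in the target grid, ties broken toward the
#' top-left; the intensity sum is preserved exactly.
#'
#' @param img a `gray_image`.
#' @param target integer length-2 target shape, >= the source shape.
#' @return A `gray_image` at the target shape with unchanged spacing.
#' @export
zero_pad_to <- function(img, target) {
  img <- as_gray_image(img)
  target <- as.integer(target)
  d <- dim(img$pixels)
  if (length(target) != 2L || any(target < d))
    stop("`target` must be a length-2 shape at least as large as the image",
         call. = FALSE)
  if (all(target == d)) return(img)
  out <- matrix(0, target[1], target[2])
  off <- floor((target - d) / 2)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- img$pixels
  gray_image(out, spacing = img$spacing)
}

#' Clip intensities above a percentile
#'
#' Voxels above the q-th percentile of the whole image are set to that
#' percentile value, removing extreme bright spots before normalisation
#' (q = 99.9 reassigns at most 0.1% of voxels). The percentile is the
#' linear-interpolation quantile of the sorted flattened image
#' (`stats::quantile` type 7).
#'
#' @param img a `gray_image`.
#' @param q percentile in (0, 100].
#' @return A `gray_image` with `max(pixels)` equal to the percentile value.
#' @export
clip_to_percentile <- function(img, q = 99.9) {
  img <- as_gray_image(img)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100)
    stop("`q` must be a single percentile in (0, 100]", call. = FALSE)
  if (length(img$pixels) == 0L) stop("empty image", call. = FALSE)
  cap <- as.numeric(stats::quantile(img$pixels, q / 100, type = 7, names = FALSE))
  gray_image(pmin(img$pixels, cap), spacing = img$spacing)
}

#' Min-max scale an image to a target intensity range
#'
#' Affine map sending the image minimum to `lo` and maximum to `hi`
#' (default 0–4096, the working range of the evaluation pipeline).
#'
#' @param img a `gray_image` with `max > min`.
#' @param lo,hi target range endpoints.
#' @return A `gray_image` with min `lo` and max `hi`.
#' @export
minmax_scale <- function(img, lo = 0, hi = 4096) {
  img <- as_gray_image(img)
  stopifnot(hi > lo)
  rng <- range(img$pixels)
  if (diff(rng) == 0) {
    warning("constant image: degenerate intensity range, returning all-`lo`",
            call. = FALSE)
    return(gray_image(matrix(lo, nrow(img$pixels), ncol(img$pixels)),
                      spacing = img$spacing))
  }
  z <- (img$pixels - rng[1]) / diff(rng) * (hi - lo) + lo
  gray_image(z, spacing = img$spacing)
}

#' Clamp intensities at a maximum value
#'
#' @param img a `gray_image`.
#' @param cap positive cap; values above it are set to `cap`. Idempotent.
#' @return A `gray_image`.
#' @export
clamp_max <- function(img, cap = 4096) {
  img <- as_gray_image(img)
  stopifnot(is.numeric(cap), length(cap) == 1L, cap > 0)
  gray_image(pmin(img$pixels, cap), spacing = img$spacing)
}
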