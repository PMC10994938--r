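#' 2D grayscale image with physical pixel spacing
#'
#' The universal image currency of the package: a real-valued 2D intensity
#' grid (rows x cols) together with its pixel spacing in millimetres.
#' MRI magnitude images are nonnegative; intermediate network quantities may
#' not be, so nonnegativity is a convention of the producing operations
#' (magnitude reconstruction, rendering), not a hard constraint here.
#'
#' @param pixels numeric matrix, at least 2 x 2, all values finite.
#' @param spacing numeric length-1 or length-2, pixel size in mm
#'   (row spacing, column spacing); must be positive.
#' @return An object of class `gray_image`: a list with elements `pixels`
#'   and `spacing`.
#' @examples
#' img <- gray_image(matrix(1:16, 4, 4), spacing = 1.5625)
#' dim(img)
#' @export
gray_image <- function(pixels, spacing = c(1, 1)) {
  if (!is.null(dim(pixels)) && length(dim(pixels)) != 2L)
    stop("`pixels` must be a 2D matrix", call. = FALSE)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image contains non-finite values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be one or two positive finite values (mm)", call. = FALSE)
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, spacing = spacing), class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image> %d x %d, spacing %.4g x %.4g mm, range [%.4g, %.4g]\n",
              d[1], d[2], x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' Coerce to a gray_image
#'
#' @param x a matrix or `gray_image`.
#' @param spacing pixel spacing in mm, used when `x` is a bare matrix.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x, spacing = c(1, 1)) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, spacing)
}

#' Field of view of an image in millimetres
#'
#' @param img a `gray_image`.
#' @return numeric length-2, `dim(img) * spacing` (mm per axis).
#' @export
field_of_view <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  dim(img$pixels) * img$spacing
}

#' Read one slice of a NIfTI volume as a gray_image
#'
#' Volumes are sliced along a stated axis; pixel spacing is taken from the
#' NIfTI header (pixdim) of the two in-plane axes.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param slice 1-based slice index along `axis` (ignored for 2D images).
#' @param axis axis along which to slice a 3D volume (default 3).
#' @return A `gray_image`.
#' @export
read_nifti_slice <- function(path, slice = 1L, axis = 3L) {
  vol <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(vol)
  arr <- array(as.numeric(vol), dim(vol))
  d <- dim(arr)
  if (length(d) == 2L) {
    px <- arr
    sp <- pd[1:2]
  } else if (length(d) == 3L) {
    if (axis < 1L || axis > 3L) stop("`axis` must be 1, 2 or 3", call. = FALSE)
    if (slice < 1L || slice > d[axis]) stop("slice index out of range", call. = FALSE)
    px <- switch(axis, arr[slice, , ], arr[, slice, ], arr[, , slice])
    sp <- pd[setdiff(1:3, axis)]
  } else stop("unsupported NIfTI dimensionality", call. = FALSE)
  gray_image(as.matrix(px), spacing = sp)
}

#' Write a gray_image (or stack of them) to NIfTI
#'
#' Pixel spacing is carried in the header so that resolution bookkeeping of
#' the degrade/super-resolve pipeline is externally visible.
#'
#' @param img a `gray_image` or a list of equally sized `gray_image`s
#'   (written as a 3D stack).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_image <- function(img, path) {
  if (inherits(img, "gray_image")) {
    arr <- img$pixels
    sp <- img$spacing
  } else {
    stopifnot(length(img) >= 1L, all(vapply(img, inherits, TRUE, "gray_image")))
    d <- dim(img[[1]]$pixels)
    arr <- array(0, c(d, length(img)))
    for (i in seq_along(img)) {
      stopifnot(identical(dim(img[[i]]$pixels), d))
      arr[, , i] <- img[[i]]$pixels
    }
    sp <- c(img[[1]]$spacing, 1)
  }
  nif <- RNifti::asNifti(arr)
  RNifti::pixdim(nif) <- sp
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Export a gray_image as 16-bit PNG for inspection
#'
#' Intensities are min-max mapped to the full 16-bit range.
#'
#' @param img a `gray_image`.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  stopifnot(inherits(img, "gray_image"))
  p <- img$pixels
  rng <- range(p)
  z <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0
  png::writePNG(z, path, dpi = NULL)
  invisible(path)
}
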