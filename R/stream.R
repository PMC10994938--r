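#' Frame message of the reconstruction -> tracking hand-off
#'
#' Minimal metadata contract mirroring the deployed reconstruction chain:
#' the image, its acquisition timestamp and index, the pixel spacing
#' (updated when super-resolution changes it), and an optional displacement
#' vector from the initial target position.
#'
#' @param frame a `gray_image`.
#' @param timestamp acquisition time in seconds.
#' @param index monotone frame index.
#' @param displacement optional numeric length-3 displacement (x, y, z) mm.
#' @return An object of class `frame_message`.
#' @export
frame_message <- function(frame, timestamp, index, displacement = NULL) {
  frame <- as_gray_image(frame)
  stopifnot(is.finite(timestamp), index >= 0)
  if (!is.null(displacement))
    stopifnot(is.numeric(displacement), length(displacement) == 3)
  structure(list(frame = frame, timestamp = timestamp,
                 index = as.integer(index), spacing = frame$spacing,
                 displacement = displacement),
            class = "frame_message")
}

#' @export
print.frame_message <- function(x, ...) {
  cat(sprintf("<frame_message> #%d t=%.3fs %dx%d @ %.3g mm\n", x$index,
              x$timestamp, nrow(x$frame$pixels), ncol(x$frame$pixels),
              x$spacing[1]))
  invisible(x)
}

#' Stream frames through a super-resolution method
#'
#' Frames are processed strictly in order; each processed message is
#' delivered to `sink` exactly once and the per-frame processing wall time
#' is logged. A sink failure halts the stream, returning the partial log.
#'
#' @param frames list of `frame_message`s (or `gray_image`s, auto-wrapped)
#'   in acquisition order.
#' @param sr_method `"identity"`, `"nearest"`, `"bicubic"`, an `edsr`
#'   model, or a function `gray_image -> gray_image`.
#' @param sink optional function called with each processed
#'   `frame_message`.
#' @param factor up-sampling factor for the named baselines (default 4).
#' @return list with `messages` (processed `frame_message`s), `timing`
#'   (data.frame index / seconds) and `halted` (logical).
#' @export
stream_process <- function(frames, sr_method = "identity", sink = NULL,
                           factor = 4) {
  stopifnot(length(frames) >= 1)
  msgs <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (inherits(f, "frame_message")) f
    else frame_message(f, timestamp = i - 1, index = i - 1L)
  })
  idx <- vapply(msgs, function(m) m$index, 0L)
  if (is.unsorted(idx, strictly = TRUE))
    stop("frame indices must be strictly increasing", call. = FALSE)
  fun <- if (inherits(sr_method, "edsr")) {
    function(img) forward_sr(sr_method, img)
  } else if (is.function(sr_method)) sr_method
  else switch(match.arg(sr_method, c("identity", "nearest", "bicubic")),
              identity = function(img) img,
              nearest = function(img) upsample_nearest(img, factor),
              bicubic = function(img) upsample_bicubic(img, factor))
  out <- vector("list", length(msgs))
  secs <- numeric(0)
  halted <- FALSE
  for (i in seq_along(msgs)) {
    t0 <- proc.time()[["elapsed"]]
    res <- fun(msgs[[i]]$frame)
    m <- frame_message(res, msgs[[i]]$timestamp, msgs[[i]]$index,
                       msgs[[i]]$displacement)
    secs <- c(secs, max(proc.time()[["elapsed"]] - t0, .Machine$double.eps))
    out[[i]] <- m
    if (!is.null(sink)) {
      ok <- tryCatch({ sink(m); TRUE }, error = function(e) FALSE)
      if (!ok) {
        warning("sink failed at frame index ", m$index,
                "; halting with partial log", call. = FALSE)
        out <- out[seq_len(i)]
        halted <- TRUE
        break
      }
    }
  }
  list(messages = out[!vapply(out, is.null, TRUE)],
       timing = data.frame(index = idx[seq_along(secs)], seconds = secs),
       halted = halted)
}
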