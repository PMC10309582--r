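#' Fluorescence time-lapse stack
#'
#' Container for a single-channel fluorescence movie. Frames are stored as an
#' `H x W x T` numeric array (rows = y, columns = x, third axis = time), the
#' convention used by the image operations in this package.
#'
#' @param frames Numeric `H x W x T` array (a single matrix is treated as a
#'   one-frame stack) of nonnegative, finite intensities in arbitrary
#'   fluorescence units.
#' @param frame_interval_s Seconds between consecutive frames (default 1, the
#'   usual 1 fps confocal time-lapse acquisition).
#' @param stimulus_frame Optional 1-based index of the last pre-stimulus frame:
#'   frames `1..stimulus_frame` were acquired before the stimulus (e.g. ATP
#'   addition) and frame `stimulus_frame + 1` is the first post-stimulus frame.
#'   Must satisfy `0 < stimulus_frame < T`.
#' @param metadata Free-form named list carried along unchanged.
#'
#' @return An object of class `"image_stack"`.
#' @seealso [read_stack()], [write_stack()], [segment_somata()],
#'   [extract_traces()]
#' @export
image_stack <- function(frames, frame_interval_s = 1, stimulus_frame = NULL,
                        metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be an H x W x T array (or a single matrix)")
  if (!all(is.finite(frames)))
    stop("all frame intensities must be finite")
  if (any(frames < 0))
    stop("frame intensities must be nonnegative")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0)
    stop("'frame_interval_s' must be a single positive number")
  n_t <- dim(frames)[3L]
  if (!is.null(stimulus_frame)) {
    stimulus_frame <- as.integer(stimulus_frame)
    if (stimulus_frame <= 0L || stimulus_frame >= n_t)
      stop("'stimulus_frame' must satisfy 0 < stimulus_frame < T (T = ",
           n_t, ")")
  }
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s,
         stimulus_frame = stimulus_frame, metadata = metadata),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d x %d px, %d frames @ %g s/frame\n",
              d[1], d[2], d[3], x$frame_interval_s))
  if (!is.null(x$stimulus_frame))
    cat(sprintf("  stimulus after frame %d\n", x$stimulus_frame))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer number of time frames.
#' @export
n_frames <- function(stack) dim(stack$frames)[3L]

## Storage convention for TIFF files written by this package: integer-valued
## stacks with max <= 65535 are stored as 16-bit unsigned integers (bit-exact
## round trip); anything else is stored as 32-bit float of value/65535 and
## multiplied back on read (~1e-7 relative round trip). The libtiff sample
## format distinguishes the two on read.
.tiff_scale <- 65535

#' Read a multi-page TIFF time-lapse stack
#'
#' Pages become time frames, in stored order. Intensities are read as stored:
#' integer TIFFs yield the raw integer gray levels; 32-bit float TIFFs written
#' by [write_stack()] are rescaled back to their original range.
#'
#' @param path Path to a single-channel multi-page TIFF.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_stack <- function(path, frame_interval_s = 1, stimulus_frame = NULL,
                       metadata = list()) {
  if (!file.exists(path)) stop("cannot read TIFF file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF file contains no pages: ", path)
  ref_dim <- dim(pages[[1L]])
  for (i in seq_along(pages)) {
    d <- dim(pages[[i]])
    if (length(d) != 2L)
      stop(sprintf("page %d is not single-channel (dimensions %s)",
                   i, paste(d, collapse = " x ")))
    if (!identical(d, ref_dim))
      stop(sprintf("page %d has shape %s but page 1 has shape %s",
                   i, paste(d, collapse = " x "),
                   paste(ref_dim, collapse = " x ")))
  }
  frames <- array(0, c(ref_dim, length(pages)))
  for (i in seq_along(pages)) {
    ## this package stores stacks as 16-bit uint or 32-bit float of x/65535;
    ## integer pages are rounded back to their exact gray levels
    pg <- pages[[i]] * .tiff_scale
    if (!identical(attr(pages[[i]], "bits.per.sample"), 32L)) pg <- round(pg)
    frames[, , i] <- pg
  }
  image_stack(frames, frame_interval_s = frame_interval_s,
              stimulus_frame = stimulus_frame, metadata = metadata)
}

#' Write a stack as a multi-page TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  if (max(fr) > .tiff_scale)
    stop("intensities exceed ", .tiff_scale,
         "; rescale before writing to TIFF")
  integral <- all(fr == round(fr))
  pages <- lapply(seq_len(dim(fr)[3L]),
                  function(t) fr[, , t] / .tiff_scale)
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (integral) 16L else 32L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}
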