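#' Per-frame drift track
#'
#' Rigid translation of every frame relative to a reference frame, in pixels.
#' `shifts[t, ]` is the `(dy, dx)` displacement of frame `t`'s content with
#' respect to the reference, so a positive `dy` means the scene moved down.
#'
#' @param shifts `T x 2` numeric matrix of `(dy, dx)` displacements.
#' @param reference_frame 1-based index of the reference frame; its shift must
#'   be exactly `(0, 0)`.
#' @param flagged Logical vector marking frames whose shift could not be
#'   estimated (e.g. zero-variance frames) and was set to `(0, 0)`.
#' @return An object of class `"drift_track"`.
#' @export
drift_track <- function(shifts, reference_frame = 1L,
                        flagged = rep(FALSE, nrow(shifts))) {
  shifts <- as.matrix(shifts)
  if (ncol(shifts) != 2L) stop("'shifts' must be a T x 2 matrix")
  if (!all(is.finite(shifts))) stop("all shifts must be finite")
  reference_frame <- as.integer(reference_frame)
  if (reference_frame < 1L || reference_frame > nrow(shifts))
    stop("'reference_frame' out of range")
  if (any(shifts[reference_frame, ] != 0))
    stop("the reference frame must have shift (0, 0)")
  colnames(shifts) <- c("dy", "dx")
  structure(list(shifts = shifts, reference_frame = reference_frame,
                 flagged = as.logical(flagged)),
            class = "drift_track")
}

#' @export
print.drift_track <- function(x, ...) {
  mags <- sqrt(rowSums(x$shifts^2))
  cat(sprintf(
    "<drift_track> %d frames, reference %d, max |shift| %.2f px%s\n",
    nrow(x$shifts), x$reference_frame, max(mags),
    if (any(x$flagged)) sprintf(" (%d flagged)", sum(x$flagged)) else ""))
  invisible(x)
}

#' Estimate rigid per-frame drift by phase correlation
#'
#' Each frame's translation relative to the reference frame is found at the
#' peak of the spectral cross-correlation of the mean-removed frames
#' (phase-correlation family, computed via FFT), then refined to subpixel
#' precision on an upsampled local cross-correlation grid (matrix-multiply
#' DFT, factor `upsample`). Ties
#' in the correlation peak are broken toward the smaller-magnitude shift.
#' Zero-variance frames cannot be registered; they get shift `(0, 0)`, a
#' warning, and a `flagged` mark.
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @param reference 1-based index of the reference frame (default 1).
#' @param upsample Subpixel upsampling factor (default 10, i.e. 0.1 px grid).
#' @return A [drift_track()].
#' @export
estimate_drift <- function(stack, reference = 1L, upsample = 10L) {
  stopifnot(inherits(stack, "image_stack"))
  n_t <- n_frames(stack)
  if (n_t < 2L) stop("drift estimation needs at least 2 frames")
  reference <- as.integer(reference)
  if (reference < 1L || reference > n_t) stop("'reference' out of range")
  ref <- stack$frames[, , reference]
  if (stats::sd(ref) == 0) stop("reference frame has zero variance")
  f_ref <- stats::fft(ref - mean(ref))
  shifts <- matrix(0, n_t, 2L)
  flagged <- rep(FALSE, n_t)
  for (t in seq_len(n_t)) {
    if (t == reference) next
    frm <- stack$frames[, , t]
    if (stats::sd(frm) == 0) {
      warning("frame ", t, " has zero variance; shift set to (0, 0)")
      flagged[t] <- TRUE
      next
    }
    shifts[t, ] <- .phase_corr_shift(f_ref, stats::fft(frm - mean(frm)),
                                     upsample)
  }
  drift_track(shifts, reference_frame = reference, flagged = flagged)
}

## Shift of frame relative to ref from the FFTs of the mean-removed frames:
## frame(y, x) ~ ref(y - dy, x - dx). The integer stage takes the peak of
## the spectral cross-correlation (mean removal kills the DC pedestal that
## would otherwise flatten the peak); full whitening is deliberately avoided
## because smooth, noise-free scenes carry no usable phase at high
## frequencies.
.phase_corr_shift <- function(f_ref, f_frm, upsample) {
  h <- nrow(f_ref); w <- ncol(f_ref)
  cross <- Conj(f_ref) * f_frm
  pc <- Re(stats::fft(cross, inverse = TRUE)) / (h * w)
  peak <- which.max(pc)
  py <- (peak - 1L) %% h
  px <- (peak - 1L) %/% h
  if (py > h / 2) py <- py - h
  if (px > w / 2) px <- px - w
  if (upsample <= 1L) return(c(py, px))
  .upsampled_peak(cross, c(py, px), upsample)
}

## Refine the integer peak on a +/-1.5 px cross-correlation grid sampled at
## 1/upsample spacing, evaluated by matrix-multiply DFT of the cross spectrum.
.upsampled_peak <- function(cross, int_shift, upsample) {
  h <- nrow(cross); w <- ncol(cross)
  fy <- c(seq.int(0L, floor((h - 1) / 2)), seq.int(-floor(h / 2), -1L)) / h
  fx <- c(seq.int(0L, floor((w - 1) / 2)), seq.int(-floor(w / 2), -1L)) / w
  ay <- int_shift[1L] + seq(-1.5, 1.5, by = 1 / upsample)
  ax <- int_shift[2L] + seq(-1.5, 1.5, by = 1 / upsample)
  ey <- exp(2i * pi * outer(ay, fy))            # |ay| x H
  ex <- exp(2i * pi * outer(fx, ax))            # W x |ax|
  cc <- Re(ey %*% cross %*% ex)
  top <- max(cc)
  cand <- which(cc >= top - 1e-9 * abs(top), arr.ind = TRUE)
  mags <- abs(ay[cand[, 1L]]) + abs(ax[cand[, 2L]])
  best <- cand[which.min(mags), , drop = TRUE]
  c(ay[best[1L]], ax[best[2L]])
}

#' Undo estimated drift
#'
#' Each frame is translated by minus its estimated shift using separable
#' cubic-convolution (Catmull-Rom) interpolation; pixels sampled outside the
#' field of view are filled with that frame's median so that background
#' statistics are minimally perturbed. Output shape equals input shape.
#'
#' @param stack An [image_stack()].
#' @param drift A [drift_track()] of matching length.
#' @return A registered [image_stack()].
#' @export
apply_drift <- function(stack, drift) {
  stopifnot(inherits(stack, "image_stack"), inherits(drift, "drift_track"))
  n_t <- n_frames(stack)
  if (nrow(drift$shifts) != n_t)
    stop("drift track has ", nrow(drift$shifts), " entries but the stack has ",
         n_t, " frames")
  out <- stack$frames
  for (t in seq_len(n_t)) {
    s <- drift$shifts[t, ]
    if (all(s == 0)) next
    frm <- stack$frames[, , t]
    out[, , t] <- .translate_cubic(frm, s[1L], s[2L],
                                   fill = stats::median(frm))
  }
  ## interpolation can only keep values within the frame's range, but clamp
  ## tiny negative overshoots so the nonnegativity invariant holds
  out[out < 0] <- 0
  image_stack(out, frame_interval_s = stack$frame_interval_s,
              stimulus_frame = stack$stimulus_frame,
              metadata = stack$metadata)
}

## Catmull-Rom (cubic convolution, a = -1/2) weights for fractional offset f.
.cubic_weights <- function(f) {
  a <- -0.5
  d <- c(1 + f, f, 1 - f, 2 - f)      # distances to samples at -1, 0, 1, 2
  w <- numeric(4L)
  for (i in 1:4) {
    x <- abs(d[i])
    w[i] <- if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
            else a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a
  }
  w
}

## Sample img at (y + dy, x + dx); out-of-field taps read `fill`.
.translate_cubic <- function(img, dy, dx, fill) {
  img <- .shift_axis_cubic(img, dy, fill, rows = TRUE)
  .shift_axis_cubic(img, dx, fill, rows = FALSE)
}

.shift_axis_cubic <- function(img, delta, fill, rows) {
  if (delta == 0) return(img)
  n <- if (rows) nrow(img) else ncol(img)
  n0 <- floor(delta)
  f <- delta - n0
  grab <- function(pos) {
    inside <- pos >= 1L & pos <= n
    sel <- ifelse(inside, pos, NA_integer_)
    if (rows) {
      block <- matrix(fill, nrow(img), ncol(img))
      block[!is.na(sel), ] <- img[sel[!is.na(sel)], , drop = FALSE]
    } else {
      block <- matrix(fill, nrow(img), ncol(img))
      block[, !is.na(sel)] <- img[, sel[!is.na(sel)], drop = FALSE]
    }
    block
  }
  base <- seq_len(n) + n0
  if (f == 0) return(grab(base))
  w <- .cubic_weights(f)
  w[1L] * grab(base - 1L) + w[2L] * grab(base) +
    w[3L] * grab(base + 1L) + w[4L] * grab(base + 2L)
}
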