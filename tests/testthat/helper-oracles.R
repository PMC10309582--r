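## Independent oracles and small fixture builders used across the suite.
## Everything here is deliberately brute-force / closed-form so it cannot
## share a code path with the implementation it checks.

## Circular roll of a matrix: content moves down by dy and right by dx.
roll_mat <- function(m, dy, dx = 0L) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1L - dy) %% h) + 1L, ((seq_len(w) - 1L - dx) %% w) + 1L]
}

## Integer-shift registration oracle: exhaustive search of the overlap
## cross-correlation between two frames.
brute_int_shift <- function(ref, frm, max_shift = 6L) {
  best <- c(0L, 0L); best_cc <- -Inf
  h <- nrow(ref); w <- ncol(ref)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ys <- max(1, 1 + dy):min(h, h + dy)   # rows of frm overlapping ref
    xs <- max(1, 1 + dx):min(w, w + dx)
    cc <- sum(ref[ys - dy, xs - dx] * frm[ys, xs])
    if (cc > best_cc) { best_cc <- cc; best <- c(dy, dx) }
  }
  best
}

## Li/Lee minimum cross-entropy criterion evaluated exhaustively over a grid
## of candidate thresholds (on the min-shifted image, as the iterative scheme
## defines it).
li_brute <- function(image, n_levels = 256L) {
  y <- as.numeric(image) - min(image)
  cand <- seq(min(y), max(y), length.out = n_levels)
  cand <- cand[-c(1L, n_levels)]          # both classes must be non-empty
  ce <- vapply(cand, function(t) {
    lo <- y[y <= t]; hi <- y[y > t]
    if (!length(lo) || !length(hi) || mean(lo) <= 0) return(Inf)
    -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
  }, numeric(1L))
  cand[which.min(ce)] + min(image)
}

## Nearest-seed tessellation by direct per-pixel argmin (ties: lower index).
nearest_seed_brute <- function(seeds, h, w) {
  lab <- matrix(0L, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    d2 <- (seeds[, 1L] - y)^2 + (seeds[, 2L] - x)^2
    lab[y, x] <- which.min(d2)            # which.min takes the first minimum
  }
  lab
}

## Binary opening by direct set algebra (outside the image = background).
opening_brute <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  ctr <- (dim(se) + 1L) / 2
  offs <- which(se > 0, arr.ind = TRUE)
  offs <- sweep(offs, 2L, ctr)
  inside <- function(y, x) y >= 1 & y <= h & x >= 1 & x <= w
  ero <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    ys <- y + offs[, 1L]; xs <- x + offs[, 2L]
    ero[y, x] <- all(inside(ys, xs)) && all(mask[cbind(ys, xs)])
  }
  dil <- matrix(FALSE, h, w)
  pts <- which(ero, arr.ind = TRUE)
  for (i in seq_len(nrow(pts))) {
    ys <- pts[i, 1L] + offs[, 1L]; xs <- pts[i, 2L] + offs[, 2L]
    ok <- inside(ys, xs)
    dil[cbind(ys[ok], xs[ok])] <- TRUE
  }
  dil
}

## Pairwise IoU between predicted and truth label maps.
iou_matrix <- function(pred, truth) {
  np <- max(pred); nt <- max(truth)
  m <- matrix(0, np, nt)
  for (i in seq_len(np)) {
    pi <- pred == i
    for (j in seq_len(nt)) {
      tj <- truth == j
      inter <- sum(pi & tj)
      if (inter > 0) m[i, j] <- inter / sum(pi | tj)
    }
  }
  m
}

## Image of Gaussian blobs on a flat background.
blob_image <- function(h, w, centers, sigma, peak = 100, bg = 0) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  im <- matrix(bg, h, w)
  sigma <- rep_len(sigma, nrow(centers))
  peak <- rep_len(peak, nrow(centers))
  for (i in seq_len(nrow(centers)))
    im <- im + peak[i] *
      exp(-((yy - centers[i, 1L])^2 + (xx - centers[i, 2L])^2) /
            (2 * sigma[i]^2))
  im
}

## Constant-in-time stack from a single frame.
static_stack <- function(frame, t = 3L, ...) {
  image_stack(array(rep(frame, t), c(dim(frame), t)), ...)
}

## Orthonormalize two shape vectors under quadrature weights w.
orthonormal_shapes <- function(n_t, w) {
  s1 <- sin(seq(0, 2 * pi, length.out = n_t))
  s2 <- cos(seq(0, 2 * pi, length.out = n_t))
  s1 <- s1 / sqrt(sum(w * s1^2))
  s2 <- s2 - s1 * sum(w * s1 * s2)
  s2 <- s2 / sqrt(sum(w * s2^2))
  cbind(s1, s2)
}
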