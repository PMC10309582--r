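#' Segmentation parameters
#'
#' Tunable parameters of the semi-automated soma segmentation. The defaults
#' suit 20x confocal fields of Fluo-4-AM loaded cells at ~1 px/um; they are
#' carried in configuration, never hard-coded in the pipeline stages.
#'
#' @param projection_mode Time projection used for seeding and thresholding:
#'   `"max"` (default; captures cells that only light up after the stimulus)
#'   or `"mean"` (more robust at high noise).
#' @param maxima_min_distance_px Minimum distance between two seed maxima.
#' @param maxima_rel_prominence Required maximum prominence, as a fraction of
#'   the projection's intensity range.
#' @param open_radius_px Disk radius of the morphological opening.
#' @param min_area_px,max_area_px Area filter applied to candidate ROIs.
#' @param exclude_edge_rois Drop ROIs touching the image border.
#' @param connectivity Pixel connectivity for particle labelling: 4 or 8.
#' @return An object of class `"seg_params"`.
#' @export
seg_params <- function(projection_mode = c("max", "mean"),
                       maxima_min_distance_px = 10,
                       maxima_rel_prominence = 0.1,
                       open_radius_px = 2,
                       min_area_px = 50,
                       max_area_px = 5000,
                       exclude_edge_rois = TRUE,
                       connectivity = 8L) {
  projection_mode <- match.arg(projection_mode)
  if (maxima_min_distance_px <= 0 || open_radius_px <= 0)
    stop("distances and radii must be positive")
  if (maxima_rel_prominence <= 0 || maxima_rel_prominence >= 1)
    stop("'maxima_rel_prominence' must lie in (0, 1)")
  if (min_area_px >= max_area_px)
    stop("'min_area_px' must be smaller than 'max_area_px'")
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  structure(list(projection_mode = projection_mode,
                 maxima_min_distance_px = maxima_min_distance_px,
                 maxima_rel_prominence = maxima_rel_prominence,
                 open_radius_px = open_radius_px,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 exclude_edge_rois = exclude_edge_rois,
                 connectivity = as.integer(connectivity)),
            class = "seg_params")
}

#' Time projection of a stack
#'
#' Pixel-wise maximum (default) or mean over all frames. The time axis plays
#' the role of the z axis of a z-projection: the "leaky" indicator
#' fluorescence accumulated over the recording outlines every cell body.
#'
#' @param stack An [image_stack()].
#' @param mode `"max"` or `"mean"`.
#' @return An `H x W` matrix.
#' @export
time_project <- function(stack, mode = c("max", "mean")) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  fr <- stack$frames
  d <- dim(fr)
  flat <- matrix(fr, d[1L] * d[2L], d[3L])
  proj <- switch(mode,
                 max = do.call(pmax, asplit(flat, 2L)),
                 mean = rowMeans(flat))
  matrix(proj, d[1L], d[2L])
}

## Greyscale reconstruction of `marker` under `mask` by iterated 3x3 dilation
## (both matrices, marker <= mask). Converges in at most diam(image) steps.
.reconstruct_dilation <- function(marker, mask) {
  kern <- EBImage::makeBrush(3L, "box")
  cur <- marker
  limit <- nrow(mask) + ncol(mask) + 2L
  for (i in seq_len(limit)) {
    nxt <- pmin(as.matrix(EBImage::dilate(cur, kern)), mask)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

#' Detect seed maxima
#'
#' Finds local intensity maxima whose prominence is at least
#' `rel_prominence x (max - min)` of the image, using the h-maxima transform
#' (greyscale reconstruction), then enforces a minimum mutual distance by
#' greedy suppression in order of decreasing intensity (ties broken in
#' row-major order). In Fluo-4 projections these maxima sit mainly in the
#' cell nuclei, one per soma.
#'
#' @param image Numeric matrix (typically a [time_project()]).
#' @param min_distance_px Minimum Euclidean distance between kept seeds.
#' @param rel_prominence Prominence threshold relative to the intensity range.
#' @return Integer matrix with one row per seed and columns `y`, `x`
#'   (1-based). A constant image yields zero seeds.
#' @export
detect_seeds <- function(image, min_distance_px = 10, rel_prominence = 0.1) {
  image <- as.matrix(image)
  rng <- range(image)
  if (diff(rng) == 0)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("y", "x"))))
  h <- rel_prominence * diff(rng)
  hmax <- .reconstruct_dilation(image - h, image)
  ## regional maxima of the h-maxima transform = prominence-filtered maxima
  delta <- max(1e-6 * diff(rng), 1e-12)
  rmax <- hmax - .reconstruct_dilation(hmax - delta, hmax) >= delta / 2
  comp <- label_components(rmax, connectivity = 8L)
  n <- max(comp)
  seeds <- matrix(0L, n, 2L)
  vals <- numeric(n)
  for (k in seq_len(n)) {
    idx <- which(comp == k)
    best <- idx[which.max(image[idx])]       # row-major tie-break via which.max
    seeds[k, ] <- c((best - 1L) %% nrow(image) + 1L,
                    (best - 1L) %/% nrow(image) + 1L)
    vals[k] <- image[best]
  }
  ## greedy minimum-distance suppression, strongest first
  ord <- order(-vals, seeds[, 1L], seeds[, 2L])
  keep <- integer(0)
  for (k in ord) {
    if (!length(keep) ||
        all((seeds[keep, 1L] - seeds[k, 1L])^2 +
            (seeds[keep, 2L] - seeds[k, 2L])^2 >= min_distance_px^2))
      keep <- c(keep, k)
  }
  out <- seeds[sort(keep), , drop = FALSE]
  colnames(out) <- c("y", "x")
  out
}

#' Tessellation borders around seeds
#'
#' Partitions the plane into nearest-seed (Euclidean) regions — one tile per
#' maximum — and returns the one-pixel-wide border between adjacent tiles
#' (the "inverted tile mask" used to cut touching cells). Pixels equidistant
#' from several seeds belong to the seed with the smaller index, so the
#' construction is deterministic.
#'
#' @param seeds Seed coordinates as returned by [detect_seeds()].
#' @param shape `c(H, W)` of the target image.
#' @return Logical `H x W` matrix marking border pixels. A single seed has no
#'   borders.
#' @export
seed_tiles <- function(seeds, shape) {
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) stop("'seeds' must contain at least one seed")
  h <- shape[1L]; w <- shape[2L]
  lab <- .nearest_seed_labels(seeds, h, w)
  border <- matrix(FALSE, h, w)
  if (nrow(seeds) > 1L) {
    border[-h, ] <- border[-h, ] | (lab[-h, ] != lab[-1L, ])
    border[, -w] <- border[, -w] | (lab[, -w] != lab[, -1L])
  }
  border
}

.nearest_seed_labels <- function(seeds, h, w) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  lab <- matrix(1L, h, w)
  best <- (yy - seeds[1L, 1L])^2 + (xx - seeds[1L, 2L])^2
  for (k in seq_len(nrow(seeds))[-1L]) {
    d <- (yy - seeds[k, 1L])^2 + (xx - seeds[k, 2L])^2
    closer <- d < best                       # strict: ties keep smaller index
    lab[closer] <- k
    best[closer] <- d[closer]
  }
  lab
}

#' Li minimum cross-entropy threshold
#'
#' Computes the background threshold of Li & Lee's minimum cross-entropy
#' criterion with Li & Tam's iterative scheme: starting from the image mean,
#' the threshold is updated to
#' `(mu_bg - mu_fg) / (log(mu_bg) - log(mu_fg))` (means of the two classes it
#' currently separates) until convergence. The scheme is equivariant under
#' positive rescaling of the intensities.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param tol Convergence tolerance on the threshold, relative to the
#'   intensity range.
#' @return The scalar threshold. Foreground is `image > threshold`.
#' @seealso [li_foreground()]
#' @export
li_threshold <- function(image, tol = 1e-7) {
  x <- as.numeric(image)
  rng <- range(x)
  if (diff(rng) == 0)
    stop("cannot threshold a constant image (no threshold exists)")
  y <- x - rng[1L]                    # log needs positive class means
  t_cur <- mean(y)
  eps <- .Machine$double.xmin
  for (i in 1:200) {
    m_bg <- mean(y[y <= t_cur])
    m_fg <- mean(y[y > t_cur])
    if (!is.finite(m_fg)) break       # nothing above: threshold at the top
    m_bg <- max(m_bg, eps)
    t_new <- (m_bg - m_fg) / (log(m_bg) - log(m_fg))
    if (abs(t_new - t_cur) < tol * diff(rng)) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + rng[1L]
}

#' Foreground mask at the Li threshold
#'
#' @inheritParams li_threshold
#' @return Logical matrix, `TRUE` where `image > li_threshold(image)`.
#' @export
li_foreground <- function(image) {
  image > li_threshold(image)
}

#' Remove tessellation borders from a foreground mask
#'
#' Clears the tile-border pixels out of the thresholded foreground
#' (`foreground & !borders`) so that touching cells separate into distinct
#' components. This is the polarity-normalized form of XOR-combining the
#' threshold mask with an inverted tile mask.
#'
#' @param foreground,borders Logical matrices of identical shape.
#' @return Logical matrix.
#' @export
cut_foreground <- function(foreground, borders) {
  foreground <- as.matrix(foreground); borders <- as.matrix(borders)
  if (!identical(dim(foreground), dim(borders)))
    stop("'foreground' and 'borders' must have the same shape")
  (foreground > 0) & !(borders > 0)
}

#' Morphological clean-up of a binary mask
#'
#' Opening (erosion then dilation) with a disk of the given radius removes
#' isolated pixels and smooths object outlines; afterwards every background
#' component not connected to the image border is filled.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param open_radius_px Disk radius of the opening.
#' @return Logical matrix.
#' @export
clean_binary <- function(binary, open_radius_px = 2) {
  m <- (as.matrix(binary) > 0) * 1L
  if (!any(m > 0)) return(m > 0)
  brush <- EBImage::makeBrush(2L * round(open_radius_px) + 1L, "disc")
  opened <- as.matrix(EBImage::opening(m, brush))
  filled <- as.matrix(EBImage::fillHull(opened))
  filled > 0
}

#' Label connected components
#'
#' @param binary Logical (or 0/1) matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal neighbors).
#' @return Integer matrix of component labels (`0` = background), numbered in
#'   first-pixel (column-major) order.
#' @export
label_components <- function(binary, connectivity = 8L) {
  m <- as.matrix(binary) > 0
  h <- nrow(m); w <- ncol(m)
  idx <- which(m)
  out <- matrix(0L, h, w)
  if (!length(idx)) return(out)
  id <- integer(h * w)
  id[idx] <- seq_along(idx)
  rr <- (idx - 1L) %% h + 1L
  cc <- (idx - 1L) %/% h + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    nr <- rr + o[1L]; nc <- cc + o[2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    hit <- id[nidx] > 0L
    edges <- c(edges, rbind(id[idx[ok]][hit], id[nidx][hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  ## renumber in order of first occurrence (column-major scan)
  first <- match(unique(memb), memb)
  renum <- integer(max(memb))
  renum[memb[sort(first)]] <- seq_along(first)
  out[idx] <- renum[memb]
  out
}

#' Particle labelling with area and edge filters
#'
#' Connected components of the mask are filtered by area
#' (`[min_area_px, max_area_px]`) and, optionally, by contact with the image
#' border; survivors are relabelled `1..N` in order of decreasing area (ties:
#' top-left-most centroid first).
#'
#' @param binary Logical (or 0/1) matrix.
#' @param params A [seg_params()].
#' @return A [roi_map()].
#' @export
label_particles <- function(binary, params = seg_params()) {
  comp <- label_components(binary, params$connectivity)
  n <- max(comp)
  if (n == 0L) return(roi_map(comp))
  tab <- .roi_table(comp)
  keep <- tab$area_px >= params$min_area_px & tab$area_px <= params$max_area_px
  if (params$exclude_edge_rois) keep <- keep & !tab$touches_edge
  kept <- tab[keep, , drop = FALSE]
  ord <- kept$label[order(-kept$area_px, kept$centroid_y, kept$centroid_x)]
  renum <- integer(n)
  renum[ord] <- seq_along(ord)
  out <- matrix(0L, nrow(comp), ncol(comp))
  sel <- comp > 0L
  out[sel] <- renum[comp[sel]]
  roi_map(out)
}

#' Semi-automated soma segmentation
#'
#' Reproduces the marker-based mask pipeline on a time projection of the
#' movie: seed maxima -> nearest-seed tile borders -> Li threshold ->
#' border cut -> opening + hole filling -> particle labelling. The same
#' projection is used for seeding and thresholding, exploiting the leaky
#' indicator fluorescence that outlines every cell body. The result is
#' invariant to positive rescaling of the intensities.
#'
#' @param stack An [image_stack()].
#' @param params A [seg_params()].
#' @return A [roi_map()]; zero ROIs is a valid result and raises a warning.
#' @export
segment_somata <- function(stack, params = seg_params()) {
  stopifnot(inherits(stack, "image_stack"))
  proj <- time_project(stack, params$projection_mode)
  seeds <- detect_seeds(proj, params$maxima_min_distance_px,
                        params$maxima_rel_prominence)
  if (nrow(seeds) == 0L) {
    warning("no seed maxima found; returning an empty ROI map")
    return(roi_map(matrix(0L, nrow(proj), ncol(proj))))
  }
  borders <- seed_tiles(seeds, dim(proj))
  fg <- li_foreground(proj)
  cut <- cut_foreground(fg, borders)
  cleaned <- clean_binary(cut, params$open_radius_px)
  rois <- label_particles(cleaned, params)
  if (nrow(rois$table) == 0L)
    warning("segmentation produced no ROIs after filtering")
  rois
}
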