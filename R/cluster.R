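#' k-means clustering of component scores
#'
#' Lloyd's algorithm with k-means++ initialization, keeping the best of
#' `n_init` restarts by total within-cluster sum of squares (WSS). The result
#' is deterministic given `(seed, n_init)`. Cluster labels are renumbered by
#' decreasing cluster size, ties broken by the smaller centroid norm, so the
#' labelling does not depend on the initialization order or on the ordering
#' of the input cells.
#'
#' @param scores Numeric `n x K` matrix (typically truncated FPC scores; a
#'   vector is treated as one column).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed RNG seed (default 2023).
#' @param n_init Number of k-means++ restarts.
#' @param iter_max Lloyd iteration cap per restart.
#' @return An object of class `"kmeans_fit"`: `labels` (1..k), `centers`,
#'   `wss` (total within-cluster sum of squares), `k`, `seed`.
#' @export
kmeans_cluster <- function(scores, k, seed = 2023L, n_init = 10L,
                           iter_max = 100L) {
  x <- as.matrix(scores)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be at least 1")
  if (k > n) stop("'k' cannot exceed the number of cells (", n, ")")
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1L)
    wss <- sum(sweep(x, 2L, ctr)^2)
    return(.kmeans_result(rep(1L, n), ctr, wss, k, seed))
  }
  if (k == n) {
    res <- .renumber_clusters(seq_len(n), x)
    return(.kmeans_result(res$labels, res$centers, 0, k, seed))
  }
  best <- NULL
  with_local_seed(seed, {
    for (i in seq_len(n_init)) {
      init <- x[.kmeanspp_centers(x, k), , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)       # rare empty-cluster failure: skip
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
  })
  if (is.null(best)) stop("k-means failed for every restart")
  res <- .renumber_clusters(best$cluster, x)
  .kmeans_result(res$labels, res$centers, best$tot.withinss, k, seed)
}

.kmeans_result <- function(labels, centers, wss, k, seed) {
  structure(list(labels = as.integer(labels), centers = centers,
                 wss = wss, k = k, seed = seed),
            class = "kmeans_fit")
}

## k-means++ seeding: first center uniform, then proportional to squared
## distance from the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ])^2)
  for (j in seq_len(k)[-1L]) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ])^2))
  }
  idx
}

## Relabel clusters by decreasing size; ties by smaller centroid L2 norm.
.renumber_clusters <- function(labels, x) {
  ids <- sort(unique(labels))
  sizes <- tabulate(match(labels, ids))
  centers <- do.call(rbind, lapply(ids, function(i)
    colMeans(x[labels == i, , drop = FALSE])))
  norms <- sqrt(rowSums(centers^2))
  ord <- order(-sizes, norms)
  renum <- integer(length(ids))
  renum[ord] <- seq_along(ids)
  list(labels = renum[match(labels, ids)],
       centers = centers[ord, , drop = FALSE])
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat(sprintf("<kmeans_fit> k = %d, WSS = %.4g, sizes: %s\n",
              x$k, x$wss, paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Elbow scan over candidate cluster counts
#'
#' Runs [kmeans_cluster()] for every `k` in `k_range` and suggests the elbow
#' as the interior `k` with the largest discrete second difference of the WSS
#' curve (the point of greatest curvature). The full curve is always
#' returned — the suggestion is a starting point that a human is expected to
#' confirm or override against the embedding, so it is never silently final.
#' When the relative WSS drop at the suggested `k` is below 5% the suggestion
#' is additionally flagged low-confidence.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate cluster counts (default `1:8`); needs at least 3
#'   values so an interior point exists.
#' @return An object of class `"elbow_curve"`: `k_range`, `wss`, `k`
#'   (suggested), `low_confidence`, `seed`.
#' @export
elbow_select <- function(scores, k_range = 1:8, seed = 2023L, n_init = 10L) {
  x <- as.matrix(scores)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L)
    stop("'k_range' needs at least 3 values to have an interior point")
  if (max(k_range) > nrow(x))
    stop("max(k_range) cannot exceed the number of cells")
  wss <- vapply(k_range, function(k)
    kmeans_cluster(x, k, seed = seed, n_init = n_init)$wss, numeric(1L))
  interior <- 2:(length(k_range) - 1L)
  d2 <- wss[interior - 1L] - 2 * wss[interior] + wss[interior + 1L]
  pick <- interior[which.max(d2)]
  drop_rel <- if (wss[pick - 1L] > 0)
    (wss[pick - 1L] - wss[pick]) / wss[pick - 1L] else 0
  structure(list(k_range = k_range, wss = wss, k = k_range[pick],
                 low_confidence = drop_rel < 0.05, seed = seed),
            class = "elbow_curve")
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat("<elbow_curve> within-cluster sum of squares:\n")
  print(data.frame(k = x$k_range, wss = signif(x$wss, 5)), row.names = FALSE)
  cat(sprintf("suggested k = %d%s\n", x$k,
              if (x$low_confidence) " (low confidence: <5% WSS drop)" else ""))
  invisible(x)
}

#' UMAP embedding of component scores
#'
#' Two-dimensional uniform manifold approximation and projection of the
#' truncated FPC scores, for display only: clustering always operates on the
#' scores themselves, so the embedding (and its seed) can never change
#' cluster assignments. Runs single-threaded under a fixed seed, so identical
#' calls give identical coordinates.
#'
#' @param scores Numeric `n x K` matrix.
#' @param n_neighbors UMAP neighborhood size (default 15); if `n <=
#'   n_neighbors` it is reduced to `n - 1` with a warning and the adjustment
#'   is recorded.
#' @param min_dist UMAP minimum distance (default 0.1).
#' @param seed RNG seed (default 2023).
#' @return An object of class `"embedding2d"`: `coords` (`n x 2`),
#'   `n_neighbors` (as used), `min_dist`, `seed`, `adjusted`.
#' @export
embed_umap <- function(scores, n_neighbors = 15L, min_dist = 0.1,
                       seed = 2023L) {
  x <- as.matrix(scores)
  n <- nrow(x)
  adjusted <- FALSE
  if (n <= n_neighbors) {
    n_neighbors <- n - 1L
    adjusted <- TRUE
    warning("fewer cells than neighbors; reducing n_neighbors to ", n_neighbors)
  }
  coords <- with_local_seed(seed,
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               n_threads = 1L, n_sgd_threads = 0L))
  if (!all(is.finite(coords))) stop("UMAP produced non-finite coordinates")
  colnames(coords) <- c("umap_1", "umap_2")
  structure(list(coords = coords, n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist, seed = seed, adjusted = adjusted),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf(
    "<embedding2d> %d cells (n_neighbors = %d%s, min_dist = %g, seed = %d)\n",
    nrow(x$coords), x$n_neighbors, if (x$adjusted) ", adjusted" else "",
    x$min_dist, x$seed))
  invisible(x)
}

#' Per-cluster dF/F0 profiles and group composition
#'
#' For each cluster, the pointwise median dF/F0 track (the black median track
#' drawn over the member traces in cluster profile figures) and the breakdown
#' of cluster membership by group.
#'
#' @param norm A [dff_matrix()].
#' @param labels Integer cluster labels, one per cell.
#' @return List with `profiles` (`k x T` matrix of medians, one row per
#'   cluster), `composition` (group x cluster count matrix), and `labels`.
#' @export
cluster_profiles <- function(norm, labels) {
  stopifnot(inherits(norm, "dff_matrix"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(norm$values))
    stop("'labels' must have one entry per cell (",
         nrow(norm$values), " cells, ", length(labels), " labels)")
  ks <- sort(unique(labels))
  profiles <- do.call(rbind, lapply(ks, function(k)
    apply(norm$values[labels == k, , drop = FALSE], 2L, stats::median)))
  rownames(profiles) <- paste0("cluster_", ks)
  comp <- as.matrix(table(group = norm$group, cluster = labels))
  list(profiles = profiles, composition = comp, labels = labels)
}
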