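three_blobs <- function(n_per = 20, sigma = 0.1, seed = 5) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(10, 0), c(5, 10 * sqrt(3) / 2))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * 2, 0, sigma), n_per), 2, centers[k, ], "+")))
  list(x = x, truth = rep(1:3, each = n_per))
}

test_that("k-means recovers well-separated blobs exactly", {
  b <- three_blobs()
  km <- kmeans_cluster(b$x, 3, seed = 2023)
  expect_equal(mclust::adjustedRandIndex(km$labels, b$truth), 1)
  expect_identical(sort(unique(km$labels)), 1:3)

  # degenerate cluster counts
  expect_equal(kmeans_cluster(b$x, nrow(b$x))$wss, 0)
  one <- kmeans_cluster(b$x, 1)
  expect_equal(one$wss, sum(sweep(b$x, 2, colMeans(b$x))^2))
  expect_error(kmeans_cluster(b$x, 0), "at least 1")
  expect_error(kmeans_cluster(b$x, nrow(b$x) + 1), "cannot exceed")
})

test_that("cluster labels are deterministic and ordering-invariant", {
  b <- three_blobs(n_per = 15, seed = 9)
  km1 <- kmeans_cluster(b$x, 3, seed = 1)
  km2 <- kmeans_cluster(b$x, 3, seed = 1)
  expect_identical(km1$labels, km2$labels)

  perm <- sample(nrow(b$x))
  km3 <- kmeans_cluster(b$x[perm, ], 3, seed = 1)
  expect_identical(km3$labels, km1$labels[perm])

  # renumbering: decreasing size, then smaller centroid norm
  x <- rbind(matrix(rnorm(40, 0, 0.05), 20),
             matrix(rnorm(10, 8, 0.05), 5))
  km <- kmeans_cluster(x, 2, seed = 4)
  expect_identical(km$labels[1:20], rep(1L, 20))
  expect_identical(km$labels[21:25], rep(2L, 5))
})

test_that("the elbow scan suggests the knee of the WSS curve", {
  b <- three_blobs()
  el <- elbow_select(b$x, 1:6, seed = 2023)
  expect_identical(el$k, 3L)
  expect_false(el$low_confidence)
  expect_true(all(diff(el$wss) <= 1e-8))

  # a single tight blob in a high-dimensional score space: no split direction
  # dominates, so the relative WSS drop at the suggested k is tiny
  set.seed(2)
  tight <- matrix(rnorm(40 * 200, 0, 0.05), 40)
  el2 <- elbow_select(tight, 1:5, seed = 2023)
  expect_true(el2$low_confidence)

  expect_error(elbow_select(b$x, 1:2), "at least 3")
  expect_error(elbow_select(tight, 1:100), "cannot exceed")
})

test_that("UMAP embedding is reproducible and separates distinct blobs", {
  set.seed(8)
  x <- rbind(matrix(rnorm(120, 0, 0.3), 40),
             matrix(rnorm(120, 6, 0.3), 40))
  truth <- rep(1:2, each = 40)
  e1 <- embed_umap(x, seed = 2023)
  e2 <- embed_umap(x, seed = 2023)
  expect_identical(e1$coords, e2$coords)

  sil <- cluster::silhouette(truth, stats::dist(e1$coords))
  expect_gte(mean(sil[, "sil_width"]), 0.8)
})

test_that("undersized inputs shrink the UMAP neighborhood with a warning", {
  x <- matrix(rnorm(24), 12)
  expect_warning(e <- embed_umap(x, n_neighbors = 13), "n_neighbors")
  expect_identical(e$n_neighbors, 11L)
  expect_true(e$adjusted)
  expect_identical(nrow(e$coords), 12L)
})

test_that("clustering operates on scores, never on the embedding", {
  b <- three_blobs(n_per = 12, seed = 3)
  km <- kmeans_cluster(b$x, 3, seed = 2023)
  for (umap_seed in c(1, 99)) {
    invisible(embed_umap(b$x, seed = umap_seed))
    expect_identical(kmeans_cluster(b$x, 3, seed = 2023)$labels, km$labels)
  }
})

test_that("cluster profiles are pointwise medians with full composition", {
  vals <- rbind(c(0.1, 0), c(0.2, 0), c(0.9, 0), c(5, 5))
  dff <- dff_matrix(vals, f0 = rep(1, 4), stimulus_frame = 1L,
                    n_baseline = 1L, group = c("A", "A", "B", "B"))
  pr <- cluster_profiles(dff, c(1L, 1L, 1L, 2L))
  expect_equal(pr$profiles["cluster_1", 1], 0.2, ignore_attr = TRUE)
  expect_equal(pr$profiles["cluster_2", ], c(5, 5), ignore_attr = TRUE)
  expect_equal(rowSums(pr$composition), c(A = 2, B = 2))
  expect_equal(sum(pr$composition), 4)
  expect_error(cluster_profiles(dff, 1:3), "one entry per cell")
})

test_that("archetype structure is recovered end-to-end from simulated traces", {
  sim <- simulate_traces(sim_config(n_cells = 150, t_total = 240,
                                    stimulus_frame = 60, seed = 11))
  dff <- normalize_dff(sim$traces, 60L, 20L)
  fit <- fpca(dff)
  k95 <- select_k(fit, 0.95)
  scores <- fit$scores[, seq_len(k95), drop = FALSE]
  km <- kmeans_cluster(scores, 3, seed = 2023)
  ari <- mclust::adjustedRandIndex(km$labels, sim$truth$archetype)
  expect_gte(ari, 0.9)
})
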