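test_that("time projection computes pixel-wise max and mean", {
  f1 <- matrix(c(0, 2, 1, 3), 2, 2)        # [[0,1],[2,3]]
  f2 <- matrix(c(3, 0, 0, 5), 2, 2)        # [[3,0],[0,5]]
  stk <- image_stack(array(c(f1, f2), c(2, 2, 2)))
  expect_equal(time_project(stk, "max"), matrix(c(3, 2, 1, 5), 2, 2))
  expect_equal(time_project(stk, "mean"), matrix(c(1.5, 1, 0.5, 4), 2, 2))
  one <- image_stack(f1)
  expect_equal(time_project(one, "max"), f1)
  expect_error(time_project(stk, "median"))
})

test_that("seed detection finds prominent blob maxima", {
  im <- blob_image(64, 64, rbind(c(20, 17), c(20, 47)), sigma = 3)
  seeds <- detect_seeds(im, min_distance_px = 10, rel_prominence = 0.1)
  expect_identical(nrow(seeds), 2L)
  d <- pmin(sqrt((seeds[, 1] - 20)^2 + (seeds[, 2] - 17)^2),
            sqrt((seeds[, 1] - 20)^2 + (seeds[, 2] - 47)^2))
  expect_true(all(d <= 1))

  expect_identical(nrow(detect_seeds(matrix(5, 10, 10))), 0L)

  one <- blob_image(32, 32, rbind(c(16, 16)), sigma = 4)
  expect_identical(nrow(detect_seeds(one, min_distance_px = 100)), 1L)
})

test_that("seed tessellation borders match the brute-force nearest-seed map", {
  # two seeds on a 1 x 19 line: tie at column 10 goes to seed 1, so the
  # border sits between columns 10 and 11 -> marked at column 10
  seeds <- rbind(c(1, 5), c(1, 15))
  b <- seed_tiles(seeds, c(1, 19))
  expect_identical(which(b), 10L)

  expect_true(!any(seed_tiles(rbind(c(3, 3)), c(9, 9))))

  # four corner seeds on a square: border forms a centered cross
  seeds4 <- rbind(c(3, 3), c(3, 13), c(13, 3), c(13, 13))
  b4 <- seed_tiles(seeds4, c(15, 15))
  lab <- nearest_seed_brute(seeds4, 15, 15)
  expect_b4 <- matrix(FALSE, 15, 15)
  expect_b4[-15, ] <- expect_b4[-15, ] | (lab[-15, ] != lab[-1, ])
  expect_b4[, -15] <- expect_b4[, -15] | (lab[, -15] != lab[, -1])
  expect_identical(b4, expect_b4)
  expect_true(all(which(b4, arr.ind = TRUE)[, 1] == 8 |
                    which(b4, arr.ind = TRUE)[, 2] == 8))
  expect_error(seed_tiles(matrix(numeric(), 0, 2), c(5, 5)), "at least one")
})

test_that("Li threshold separates classes and matches the exhaustive oracle", {
  two <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  th <- li_threshold(two)
  expect_gt(th, 10); expect_lt(th, 200)
  expect_identical(unname(li_foreground(two)), unname(two == 200))

  set.seed(5)
  blobs <- blob_image(80, 80, rbind(c(20, 20), c(55, 30), c(35, 60)),
                      sigma = c(4, 6, 5), bg = 10) +
    matrix(runif(6400, 0, 2), 80, 80)
  th2 <- li_threshold(blobs)
  level <- diff(range(blobs)) / 255
  expect_lt(abs(th2 - li_brute(blobs)), level)

  expect_error(li_threshold(matrix(7, 5, 5)), "constant")
})

test_that("border cut separates touching foreground", {
  fg <- matrix(TRUE, 1, 19)
  border <- matrix(FALSE, 1, 19); border[1, 10] <- TRUE
  cut <- cut_foreground(fg, border)
  comp <- label_components(cut, 8L)
  expect_identical(max(comp), 2L)
  expect_identical(tabulate(comp[comp > 0]), c(9L, 9L))

  expect_identical(cut_foreground(fg, matrix(FALSE, 1, 19)), fg)
  expect_error(cut_foreground(fg, matrix(FALSE, 2, 19)), "same shape")
})

test_that("binary clean-up opens and fills holes as the set oracle predicts", {
  sq <- matrix(FALSE, 15, 15); sq[3:13, 3:13] <- TRUE; sq[8, 8] <- FALSE
  cleaned <- clean_binary(sq, 2)
  expect_true(cleaned[8, 8])              # hole filled
  expect_true(all(cleaned[4:12, 4:12]))

  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  expect_true(!any(clean_binary(lone, 1)))

  # rough-edged disk: opening equals direct erosion-then-dilation set algebra
  set.seed(11)
  disk <- blob_image(41, 41, rbind(c(21, 21)), sigma = 9) > 40
  rough <- disk
  edge <- which(disk & !roll_mat(disk, 1) | disk & !roll_mat(disk, -1))
  rough[sample(edge, length(edge) %/% 2)] <- FALSE
  se <- EBImage::makeBrush(5, "disc")
  expect_identical(unname(clean_binary(rough, 2)),
                   unname(opening_brute(rough, se)))
})

test_that("particle labelling filters by area, edge contact and connectivity", {
  m <- matrix(FALSE, 20, 30)
  m[3:7, 3:7] <- TRUE                      # 25 px
  m[3:7, 15:19] <- TRUE                    # 25 px
  m[12:13, 24:25] <- TRUE                  # 4 px
  p <- seg_params(min_area_px = 10, max_area_px = 5000,
                  exclude_edge_rois = FALSE)
  rois <- label_particles(m, p)
  expect_identical(nrow(rois$table), 2L)
  expect_true(all(rois$table$area_px == 25L))

  medge <- matrix(FALSE, 10, 10); medge[1:4, 4:7] <- TRUE
  expect_identical(max(label_particles(
    medge, seg_params(min_area_px = 1, max_area_px = 100,
                      exclude_edge_rois = TRUE))$labels), 0L)
  expect_identical(max(label_particles(
    medge, seg_params(min_area_px = 1, max_area_px = 100,
                      exclude_edge_rois = FALSE))$labels), 1L)

  diagonal <- matrix(FALSE, 8, 8); diag(diagonal) <- TRUE
  expect_identical(max(label_components(diagonal, 8L)), 1L)
  expect_identical(max(label_components(diagonal, 4L)), 8L)
})

test_that("labels are ordered by decreasing area then top-left centroid", {
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE                      # 9 px
  m[10:15, 10:15] <- TRUE                  # 36 px
  rois <- label_particles(m, seg_params(min_area_px = 1, max_area_px = 100,
                                        exclude_edge_rois = FALSE))
  expect_identical(rois$table$area_px, c(36L, 9L))
  expect_identical(rois$labels[11, 11], 1L)
  expect_identical(rois$labels[3, 3], 2L)
})

test_that("somata fused at threshold but with distinct maxima are split", {
  frame <- blob_image(48, 48, rbind(c(24, 16), c(24, 32)), sigma = 5)
  stk <- static_stack(frame, t = 3)
  rois <- segment_somata(stk, seg_params(min_area_px = 30))
  expect_identical(nrow(rois$table), 2L)
  # one ROI on each side of the midline
  expect_identical(sort(unique(rois$labels[24, c(16, 32)])), c(1L, 2L))
})

test_that("a blank noise movie yields zero ROIs with a warning", {
  set.seed(99)
  frames <- array(100 + rnorm(48 * 48 * 5), c(48, 48, 5))
  expect_warning(rois <- segment_somata(image_stack(frames)), "ROI")
  expect_identical(nrow(rois$table), 0L)
})

test_that("segmentation is invariant to positive intensity rescaling", {
  mv <- simulate_movie(sim_config(n_cells = 8, t_total = 30,
                                  stimulus_frame = 10, h = 128, w = 128,
                                  seed = 17))
  base <- segment_somata(mv$stack)
  for (c_scale in c(0.1, 1000)) {
    scaled <- image_stack(mv$stack$frames * c_scale)
    expect_identical(segment_somata(scaled)$labels, base$labels)
  }
})

test_that("ROI count never exceeds seed count and areas respect the filter", {
  mv <- simulate_movie(sim_config(n_cells = 10, t_total = 30,
                                  stimulus_frame = 10, h = 128, w = 128,
                                  seed = 23))
  p <- seg_params()
  proj <- time_project(mv$stack, p$projection_mode)
  seeds <- detect_seeds(proj, p$maxima_min_distance_px,
                        p$maxima_rel_prominence)
  rois <- segment_somata(mv$stack, p)
  expect_lte(nrow(rois$table), nrow(seeds))
  expect_true(all(rois$table$area_px >= p$min_area_px &
                    rois$table$area_px <= p$max_area_px))
})
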