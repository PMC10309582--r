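test_that("trace extraction averages each ROI and is linear in the stack", {
  lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L; lab[3:4, 3:4] <- 2L
  rois <- roi_map(lab)

  stk7 <- static_stack(matrix(7, 4, 4), t = 5)
  tr7 <- extract_traces(stk7, rois)
  expect_true(all(tr7$values == 7))
  expect_identical(tr7$cell_ids, c("roi_1", "roi_2"))

  frame <- matrix(0, 4, 4); frame[1, 1] <- 1; frame[2, 2] <- 3
  frame[1, 2] <- 2; frame[2, 1] <- 2
  tr <- extract_traces(image_stack(frame), rois)
  expect_equal(tr$values[1, 1], 2)        # mean of 1, 2, 2, 3

  set.seed(2)
  s1 <- image_stack(array(runif(4 * 4 * 3), c(4, 4, 3)))
  s2 <- image_stack(array(runif(4 * 4 * 3), c(4, 4, 3)))
  lin <- image_stack(2 * s1$frames + 3 * s2$frames)
  expect_equal(extract_traces(lin, rois)$values,
               2 * extract_traces(s1, rois)$values +
                 3 * extract_traces(s2, rois)$values,
               tolerance = 1e-12)

  expect_error(extract_traces(stk7, roi_map(matrix(0L, 5, 5))), "5 x 5")
  expect_warning(out <- extract_traces(stk7, roi_map(matrix(0L, 4, 4))),
                 "empty")
  expect_identical(nrow(out$values), 0L)
})

test_that("noise-free simulator movies reproduce the soma time courses", {
  # somata far enough apart that tail cross-talk is below double precision
  cfg <- sim_config(n_cells = 3, t_total = 25, stimulus_frame = 10,
                    noise_sd = 0, read_noise_sd = 0, background = 0,
                    f0_cv = 0, h = 192, w = 192, min_separation_px = 80,
                    seed = 31)
  mv <- simulate_movie(cfg)
  tr <- extract_traces(mv$stack, mv$rois)
  # ROI mean = (mean Gaussian weight over the 2-sigma disc) x soma trace
  for (i in 1:3) {
    ratio <- tr$values[i, ] / mv$traces$values[i, ]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
    expect_equal(mean(ratio), (1 - exp(-2)) / 2, tolerance = 0.05)
  }
})

test_that("dF/F0 normalization matches its closed forms", {
  t_n <- 30L
  tm <- trace_matrix(rbind(rep(100, t_n),
                           c(rep(100, 25), 150, rep(100, 4)),
                           rep(c(90, 110), 15)),
                     cell_ids = c("flat", "step", "alt"))
  dff <- normalize_dff(tm, stimulus_frame = 20L, n_baseline = 20L)
  expect_true(all(dff$values[1, ] == 0))
  expect_equal(dff$values[2, 26], 0.5)
  expect_equal(unname(dff$f0), c(100, 100, 100))

  # baseline window mean is zero per cell
  win <- 1:20
  expect_lt(max(abs(rowMeans(dff$values[, win]))), 1e-12)
})

test_that("dF/F0 is invariant to positive gain on the raw fluorescence", {
  sim <- simulate_traces(sim_config(n_cells = 12, t_total = 60,
                                    stimulus_frame = 25, seed = 6))
  base <- normalize_dff(sim$traces, 25L, 20L)
  for (c_gain in c(0.1, 3, 1000)) {
    scaled <- trace_matrix(sim$traces$values * c_gain,
                           cell_ids = sim$traces$cell_ids,
                           group = sim$traces$group,
                           time_s = sim$traces$time_s)
    expect_equal(normalize_dff(scaled, 25L, 20L)$values, base$values,
                 tolerance = 1e-12)
  }
})

test_that("normalization rejects invalid baselines by name", {
  tm <- trace_matrix(rbind(rep(1, 10), rep(0, 10)),
                     cell_ids = c("ok", "dead"))
  expect_error(normalize_dff(tm, 5L, 3L), "dead")
  expect_error(normalize_dff(tm, 5L, 6L), "n_baseline")
  expect_error(normalize_dff(tm, 10L, 2L), "stimulus_frame")
})

test_that("peak amplitudes summarize the post-stimulus window", {
  vals <- rbind(c(rep(0, 5), 0.2, 1.4, 0.3),
                rep(0, 8))
  dff <- dff_matrix(vals, f0 = c(100, 100), stimulus_frame = 5L,
                    n_baseline = 3L, cell_ids = c("a", "b"))
  pk <- peak_amplitudes(dff)
  expect_equal(pk$cells$peak, c(1.4, 0))
  expect_equal(pk$groups$mean, 0.7)
  expect_equal(pk$groups$sd, stats::sd(c(1.4, 0)))

  zero <- dff_matrix(matrix(0, 3, 8), f0 = rep(1, 3), stimulus_frame = 5L,
                     n_baseline = 3L)
  pz <- peak_amplitudes(zero)
  expect_equal(pz$groups$mean, 0)
  expect_equal(pz$groups$sd, 0)

  sim <- simulate_traces(sim_config(n_cells = 20, t_total = 120,
                                    stimulus_frame = 30, noise_sd = 0,
                                    f0_cv = 0, seed = 13))
  dffs <- normalize_dff(sim$traces, 30L, 20L)
  pks <- peak_amplitudes(dffs)$cells$peak
  expect_equal(pks, sim$truth$amplitude, tolerance = 1e-12)
})

test_that("per-group sampling is exact, reproducible and validated", {
  n <- 600L
  vals <- matrix(rnorm(n * 10), n)
  grp <- rep(paste0("line", 1:6), each = 100)
  dff <- dff_matrix(vals, f0 = rep(1, n), stimulus_frame = 5L,
                    n_baseline = 3L, group = grp)
  sub <- sample_cells(dff, 52, seed = 1)
  expect_identical(nrow(sub$values), 312L)
  expect_true(all(table(sub$group) == 52))

  again <- sample_cells(dff, 52, seed = 1)
  expect_identical(sub$cell_ids, again$cell_ids)

  all_of_them <- sample_cells(dff, 100, seed = 9)
  expect_identical(all_of_them$cell_ids, dff$cell_ids)

  expect_error(sample_cells(dff, 101), "line1")
})

test_that("heatmap ordering sorts by group then peak and is a permutation", {
  vals <- rbind(c(0, 0, 0.2), c(0, 0, 1.0))
  dff <- dff_matrix(vals, f0 = c(1, 1), stimulus_frame = 2L, n_baseline = 2L,
                    cell_ids = c("c1", "c2"))
  hm <- heatmap_matrix(dff, "peak")
  expect_identical(hm$meta$cell_id, c("c2", "c1"))
  expect_identical(heatmap_matrix(dff, "input")$meta$cell_id, c("c1", "c2"))

  sim <- simulate_traces(sim_config(n_cells = 30, t_total = 50,
                                    stimulus_frame = 25,
                                    groups = c("A", "B"), seed = 3))
  dff2 <- normalize_dff(sim$traces, 25L, 20L)
  hm2 <- heatmap_matrix(dff2, "peak")
  expect_identical(sort(hm2$meta$cell_id), sort(dff2$cell_ids))
  expect_identical(hm2$values[3, ],
                   dff2$values[match(hm2$meta$cell_id[3], dff2$cell_ids), ])
  expect_error(heatmap_matrix(dff2, "banana"))
})
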